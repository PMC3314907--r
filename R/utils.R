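# Internal helpers for symmetric 3x3 tensors stored as 6-component rows
# (lower-triangular order: xx, xy, yy, xz, yz, zz) and for voxel grids.

# row/column index of each lower-triangular component
.LT_ROW <- c(1L, 1L, 2L, 1L, 2L, 3L)
.LT_COL <- c(1L, 2L, 2L, 3L, 3L, 3L)
# multiplicity of each component in a full contraction B : D
.LT_DUP <- c(1, 2, 1, 2, 2, 1)
.LT_NAMES <- c("xx", "xy", "yy", "xz", "yz", "zz")
.LT_DIAG <- c(1L, 3L, 6L)
.LT_OFFDIAG <- c(2L, 4L, 5L)

lt6_to_mat <- function(v) {
  m <- matrix(0, 3, 3)
  m[cbind(.LT_ROW, .LT_COL)] <- v
  m[cbind(.LT_COL, .LT_ROW)] <- v
  m
}

mat_to_lt6 <- function(m) {
  m[cbind(.LT_ROW, .LT_COL)]
}

# identity tensor as an lt6 row
.LT_EYE <- c(1, 0, 1, 0, 0, 1)

# Frobenius norm^2, trace, MD and FA for an N x 6 matrix of tensors.
lt6_trace <- function(a) a[, 1] + a[, 3] + a[, 6]

lt6_norm2 <- function(a) {
  a[, 1]^2 + a[, 3]^2 + a[, 6]^2 + 2 * (a[, 2]^2 + a[, 4]^2 + a[, 5]^2)
}

lt6_md <- function(a) lt6_trace(a) / 3

lt6_fa <- function(a) {
  n2 <- lt6_norm2(a)
  md <- lt6_md(a)
  dev2 <- pmax(n2 - 3 * md^2, 0)
  fa <- sqrt(1.5) * sqrt(ifelse(n2 > 0, dev2 / n2, 0))
  fa[n2 == 0] <- 0
  fa
}

# symmetrized product sym(A %*% B) for rowwise symmetric tensors (N x 6 each)
lt6_mul_sym <- function(a, b) {
  a11 <- a[, 1]; a12 <- a[, 2]; a22 <- a[, 3]
  a13 <- a[, 4]; a23 <- a[, 5]; a33 <- a[, 6]
  b11 <- b[, 1]; b12 <- b[, 2]; b22 <- b[, 3]
  b13 <- b[, 4]; b23 <- b[, 5]; b33 <- b[, 6]
  p11 <- a11 * b11 + a12 * b12 + a13 * b13
  p22 <- a12 * b12 + a22 * b22 + a23 * b23
  p33 <- a13 * b13 + a23 * b23 + a33 * b33
  p12 <- a11 * b12 + a12 * b22 + a13 * b23
  p21 <- a12 * b11 + a22 * b12 + a23 * b13
  p13 <- a11 * b13 + a12 * b23 + a13 * b33
  p31 <- a13 * b11 + a23 * b12 + a33 * b13
  p23 <- a12 * b13 + a22 * b23 + a23 * b33
  p32 <- a13 * b12 + a23 * b22 + a33 * b23
  cbind(p11, (p12 + p21) / 2, p22, (p13 + p31) / 2, (p23 + p32) / 2, p33,
        deparse.level = 0)
}

# inverse of rowwise symmetric 3x3 tensors via the adjugate
lt6_inv <- function(a) {
  a11 <- a[, 1]; a12 <- a[, 2]; a22 <- a[, 3]
  a13 <- a[, 4]; a23 <- a[, 5]; a33 <- a[, 6]
  c11 <- a22 * a33 - a23^2
  c12 <- a13 * a23 - a12 * a33
  c13 <- a12 * a23 - a13 * a22
  c22 <- a11 * a33 - a13^2
  c23 <- a12 * a13 - a11 * a23
  c33 <- a11 * a22 - a12^2
  det <- a11 * c11 + a12 * c12 + a13 * c13
  cbind(c11, c12, c22, c13, c23, c33, deparse.level = 0) / det
}

# positive definiteness of rowwise symmetric 3x3 tensors (Sylvester minors)
lt6_is_pd <- function(a) {
  m1 <- a[, 1]
  m2 <- a[, 1] * a[, 3] - a[, 2]^2
  m3 <- a[, 1] * (a[, 3] * a[, 6] - a[, 5]^2) -
    a[, 2] * (a[, 2] * a[, 6] - a[, 5] * a[, 4]) +
    a[, 4] * (a[, 2] * a[, 5] - a[, 3] * a[, 4])
  m1 > 0 & m2 > 0 & m3 > 0
}

# world-mm coordinates (N x 3) of all voxel centres of a grid, 0-based indices
voxel_world_coords <- function(dim3, affine) {
  stopifnot(length(dim3) == 3, all(dim(affine) == c(4, 4)))
  idx <- as.matrix(expand.grid(i = seq_len(dim3[1]) - 1,
                               j = seq_len(dim3[2]) - 1,
                               k = seq_len(dim3[3]) - 1))
  xyz <- idx %*% t(affine[1:3, 1:3])
  sweep(xyz, 2, affine[1:3, 4], "+")
}

# centred axis-aligned affine: voxel grid centre maps to the world origin
centered_affine <- function(dim3, voxel_mm) {
  voxel_mm <- rep_len(voxel_mm, 3)
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- -voxel_mm * (dim3 - 1) / 2
  aff
}

# logical sphere mask around a world-space centre
sphere_mask <- function(dim3, affine, radius_mm, center_mm = c(0, 0, 0)) {
  xyz <- voxel_world_coords(dim3, affine)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  array(d2 <= radius_mm^2, dim = dim3)
}

# 6-connectivity binary erosion, `iter` passes
erode_mask <- function(mask, iter = 1) {
  d <- dim(mask)
  for (it in seq_len(iter)) {
    out <- mask
    shift_and <- function(m, axis, by) {
      s <- array(FALSE, dim = d)
      n <- d[axis]
      src <- seq_len(n - abs(by))
      dst <- src + abs(by)
      if (by < 0) { tmp <- src; src <- dst; dst <- tmp }
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ix_src <- ix; ix_src[[axis]] <- src
      ix_dst <- ix; ix_dst[[axis]] <- dst
      s[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
        m[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
      s
    }
    for (axis in 1:3) {
      out <- out & shift_and(mask, axis, 1) & shift_and(mask, axis, -1)
    }
    mask <- out
  }
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a
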