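#' Diffusion gradient scheme
#'
#' Bundles the per-volume diffusion weightings (b-values, s/mm^2) and unit
#' gradient directions of a DWI acquisition. Directions belonging to b > 0
#' volumes must be unit vectors; b = 0 volumes may carry zero vectors.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x N matrix of gradient directions (columns), or N x 3
#'   (auto-transposed when unambiguous).
#' @param normalize if `TRUE` (default), directions of b > 0 volumes whose
#'   norm deviates from 1 by at most `tol` are re-normalized; larger
#'   deviations are an error naming the offending volume.
#' @param tol tolerance on the deviation of |g| from 1 (default 1e-3).
#' @return object of class `gradient_scheme` with elements `bvals`, `bvecs`
#'   (3 x N, unit columns for b > 0), `n_volumes`, `dwi` (logical, b > 0).
#' @export
gradient_scheme <- function(bvals, bvecs, normalize = TRUE, tol = 1e-3) {
  bvals <- as.numeric(bvals)
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3) stop("bvecs must be 3 x N or N x 3")
  if (ncol(bvecs) != length(bvals)) {
    stop(sprintf("bvec count (%d) does not match bval count (%d)",
                 ncol(bvecs), length(bvals)))
  }
  dimnames(bvecs) <- NULL
  dwi <- bvals > 0
  nrm <- sqrt(colSums(bvecs^2))
  bad <- which(dwi & abs(nrm - 1) > tol)
  if (length(bad) > 0) {
    stop(sprintf("non-unit gradient direction for b > 0 volume(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (normalize) {
    fix <- dwi & nrm > 0
    bvecs[, fix] <- sweep(bvecs[, fix, drop = FALSE], 2, nrm[fix], "/")
  }
  structure(list(bvals = bvals, bvecs = bvecs,
                 n_volumes = length(bvals), dwi = dwi),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("<gradient_scheme> ", x$n_volumes, " volumes: ",
      sum(x$dwi), " diffusion-weighted (b = ",
      paste(unique(x$bvals[x$dwi]), collapse = ", "), " s/mm^2), ",
      sum(!x$dwi), " b=0\n", sep = "")
  invisible(x)
}

# fitting requires >= 6 non-collinear DW directions and >= 1 b=0 volume
assert_fittable <- function(scheme) {
  if (sum(!scheme$dwi) < 1) stop("at least one b=0 volume is required")
  if (sum(scheme$dwi) < 6) {
    stop("at least 6 diffusion-weighted directions are required")
  }
  invisible(scheme)
}

#' Build the B-matrix of one diffusion-weighting direction
#'
#' `B = b * g %*% t(g)`: the rank-one experimental design matrix whose
#' contraction with the diffusion tensor gives the apparent diffusion
#' coefficient along `g`. Its trace equals the b-value.
#'
#' @param b diffusion weighting (s/mm^2), non-negative.
#' @param g gradient direction; must be a unit vector when `b > 0`.
#' @return symmetric 3x3 matrix (s/mm^2).
#' @export
build_b_matrix <- function(b, g) {
  if (b < 0) stop("b must be non-negative")
  g <- as.numeric(g)
  if (length(g) != 3) stop("g must be a 3-vector")
  if (b > 0 && abs(sqrt(sum(g^2)) - 1) > 1e-6) {
    stop("g must be a unit vector when b > 0")
  }
  if (b == 0) return(matrix(0, 3, 3))
  b * tcrossprod(g)
}

# N_dw x 6 design matrix mapping lower-triangular tensor components to ADCs:
# row i is b_i * (gx^2, 2 gx gy, gy^2, 2 gx gz, 2 gy gz, gz^2)
b_design <- function(scheme) {
  g <- scheme$bvecs[, scheme$dwi, drop = FALSE]
  b <- scheme$bvals[scheme$dwi]
  d <- cbind(g[1, ]^2, 2 * g[1, ] * g[2, ], g[2, ]^2,
             2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ], g[3, ]^2)
  d * b
}

#' Apparent diffusion coefficient from a signal pair
#'
#' `ADC = log(s0 / s_dw) / b`. Non-positive signals yield `NA` (an invalid
#' voxel to be excluded from fits) rather than an error, so whole volumes
#' can be processed at once.
#'
#' @param s0 non-diffusion-weighted signal(s).
#' @param s_dw diffusion-weighted signal(s).
#' @param b diffusion weighting (s/mm^2), > 0.
#' @return ADC in mm^2/s (vectorized over signals).
#' @export
adc_from_signals <- function(s0, s_dw, b) {
  if (any(b <= 0)) stop("b must be positive for ADC computation")
  adc <- suppressWarnings(log(s0 / s_dw) / b)
  adc[!(s0 > 0) | !(s_dw > 0)] <- NA_real_
  adc
}

#' Least-squares diffusion tensor fit from per-direction ADCs
#'
#' Solves `ADC_i = B_i : D` for the six unique elements of the symmetric
#' tensor `D` by (optionally weighted) linear least squares. The solution is
#' exact when the system is consistent.
#'
#' @param adcs numeric vector of ADCs, one per direction.
#' @param b_matrices list of symmetric 3x3 B-matrices, same length.
#' @param weights optional non-negative per-direction weights.
#' @return symmetric 3x3 tensor with attribute `residual_var`, the residual
#'   variance of the fit (0 for consistent systems).
#' @export
fit_tensor <- function(adcs, b_matrices, weights = NULL) {
  n <- length(adcs)
  stopifnot(length(b_matrices) == n)
  design <- t(vapply(b_matrices, function(B) mat_to_lt6(B) * .LT_DUP,
                     numeric(6)))
  if (n < 6) stop("at least 6 directions are required")
  w <- weights %||% rep(1, n)
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sqrt(w)
  qrd <- qr(design * sw)
  if (qrd$rank < 6) {
    stop(sprintf("rank-deficient design: rank %d < 6 (directions do not span the space of symmetric tensors)",
                 qrd$rank))
  }
  coef <- qr.coef(qrd, adcs * sw)
  resid <- adcs - design %*% coef
  dof <- max(sum(w > 0) - 6, 1)
  structure(lt6_to_mat(coef),
            residual_var = sum(w * resid^2) / dof)
}

# Vectorized tensor fit for many voxels sharing one design.
# adc_mat: Nvox x Ndw (may contain NA); returns list(tensors = Nvox x 6,
# residual_var = Nvox, valid = Nvox logical).
fit_tensor_rows <- function(adc_mat, design, weights = NULL) {
  n_dir <- ncol(adc_mat)
  stopifnot(nrow(design) == n_dir)
  w <- weights %||% rep(1, n_dir)
  sw <- sqrt(w)
  qrd <- qr(design * sw)
  if (qrd$rank < 6) stop("rank-deficient design: directions do not span the space of symmetric tensors")
  valid <- rowSums(is.na(adc_mat)) == 0
  tensors <- matrix(NA_real_, nrow(adc_mat), 6)
  resid_var <- rep(NA_real_, nrow(adc_mat))
  if (any(valid)) {
    rhs <- t(adc_mat[valid, , drop = FALSE]) * sw
    coef <- qr.coef(qrd, rhs)            # 6 x Nvalid
    fitted <- design %*% coef
    resid <- t(adc_mat[valid, , drop = FALSE]) - fitted
    dof <- max(sum(w > 0) - 6, 1)
    tensors[valid, ] <- t(coef)
    resid_var[valid] <- colSums(resid^2 * w) / dof
  }
  list(tensors = tensors, residual_var = resid_var, valid = valid)
}

#' Scalar and directional indices of a diffusion tensor
#'
#' Mean diffusivity `MD = trace/3`, fractional anisotropy
#' `FA = sqrt(3/2) * ||D - MD I||_F / ||D||_F` (0 for the zero tensor),
#' eigenvalues sorted descending and the principal axis (eigenvector of the
#' largest eigenvalue, sign fixed so its first nonzero component is
#' positive).
#'
#' @param D symmetric 3x3 tensor.
#' @return list with `md`, `fa`, `trace`, `eigenvalues`, `principal_axis`.
#' @export
tensor_indices <- function(D) {
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    stop("D must be symmetric")
  }
  D <- (D + t(D)) / 2
  e <- eigen(D, symmetric = TRUE)
  v <- e$vectors[, 1]
  nz <- which(abs(v) > 1e-12)
  if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
  row <- matrix(mat_to_lt6(D), 1)
  list(md = lt6_md(row), fa = lt6_fa(row), trace = lt6_trace(row),
       eigenvalues = e$values, principal_axis = v)
}

#' Fit a diffusion tensor field from a 4-D DWI array
#'
#' Computes per-direction ADC maps against the mean of all b=0 volumes and
#' performs a voxelwise least-squares tensor fit.
#'
#' @param dwi 4-D array `[nx, ny, nz, n_volumes]`.
#' @param scheme a [gradient_scheme] matching the 4th dimension.
#' @param affine 4x4 voxel-to-world affine.
#' @param mask optional logical 3-D array; voxels with invalid (non-positive)
#'   signals are additionally excluded.
#' @param weights optional per-direction weights passed to the fit.
#' @return list with `tensors` (a [tensor_field] of `D`), `residual_var`
#'   (3-D array, `NA` outside the mask).
#' @export
fit_tensor_field <- function(dwi, scheme, affine, mask = NULL, weights = NULL) {
  stopifnot(length(dim(dwi)) == 4)
  if (dim(dwi)[4] != scheme$n_volumes) {
    stop(sprintf("DWI has %d volumes but scheme lists %d",
                 dim(dwi)[4], scheme$n_volumes))
  }
  assert_fittable(scheme)
  dim3 <- dim(dwi)[1:3]
  nvox <- prod(dim3)
  vols <- matrix(dwi, nrow = nvox)
  s0 <- rowMeans(vols[, !scheme$dwi, drop = FALSE])
  dw <- vols[, scheme$dwi, drop = FALSE]
  b <- scheme$bvals[scheme$dwi]
  # fit the attenuation log(s0/s) = B : D; the per-direction ADC is the
  # attenuation divided by b, so this is the same linear system rescaled
  bb <- rep(b, each = nvox)
  attn <- adc_from_signals(s0, dw, bb) * bb
  dim(attn) <- dim(dw)
  if (is.null(mask)) mask <- array(TRUE, dim = dim3)
  sel <- as.vector(mask)
  fit <- fit_tensor_rows(attn[sel, , drop = FALSE], b_design(scheme), weights)
  final_mask <- array(FALSE, dim = dim3)
  final_mask[sel][fit$valid] <- TRUE
  rows <- fit$tensors
  rows[!fit$valid, ] <- 0
  field <- field_from_rows(rows, dim3, affine, array(sel, dim3))
  field$mask <- final_mask
  rv <- array(NA_real_, dim = dim3)
  rv[sel] <- fit$residual_var
  list(tensors = field, residual_var = rv)
}

#' Scalar index maps of a tensor field
#'
#' @param field a [tensor_field].
#' @return list of 3-D arrays `md`, `fa`, `trace` (`NA` outside the mask).
#' @export
index_maps <- function(field) {
  rows <- field_rows(field, masked = FALSE)
  sel <- as.vector(field$mask)
  mk <- function(v) {
    v[!sel] <- NA_real_
    array(v, dim = field$dim)
  }
  list(md = mk(lt6_md(rows)), fa = mk(lt6_fa(rows)),
       trace = mk(lt6_trace(rows)))
}
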