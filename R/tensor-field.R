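#' Voxel field of symmetric 3x3 tensors
#'
#' Container for a grid of symmetric second-order tensors: diffusion tensors
#' `D` (mm^2/s), local-perturbation-field (LPF) ellipsoids `L = I + 2*Sigma+`
#' or symmetric LPF matrices `Sigma+` (dimensionless). Components are stored
#' as a 4-D array whose last dimension holds the six unique elements in
#' lower-triangular order (xx, xy, yy, xz, yz, zz).
#'
#' @param data 4-D numeric array `[nx, ny, nz, 6]` of tensor components.
#' @param affine 4x4 voxel-to-world (mm) affine; must be invertible.
#' @param mask optional logical 3-D array of valid voxels; defaults to all.
#' @return An object of class `tensor_field` with elements `data`, `affine`,
#'   `mask` and `dim` (the spatial grid dimensions).
#' @export
tensor_field <- function(data, affine, mask = NULL) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] == 6)
  dim3 <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = dim3)
  stopifnot(all(dim(mask) == dim3), all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine is not invertible")
  }
  structure(list(data = data, affine = affine, mask = mask, dim = dim3),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(x$dim, collapse = " x "),
      " grid, ", sum(x$mask), " voxels in mask\n", sep = "")
  invisible(x)
}

# N x 6 matrix of components for the masked voxels (or all voxels)
field_rows <- function(field, masked = TRUE) {
  m <- matrix(field$data, ncol = 6)
  if (masked) m[as.vector(field$mask), , drop = FALSE] else m
}

# build a tensor_field from an N x 6 matrix over masked voxels
field_from_rows <- function(rows, dim3, affine, mask, fill = 0) {
  data <- array(fill, dim = c(dim3, 6))
  full <- matrix(fill, prod(dim3), 6)
  full[as.vector(mask), ] <- rows
  array(full, dim = c(dim3, 6)) -> data
  tensor_field(data, affine, mask)
}

#' Extract a single tensor from a field
#'
#' @param field a [tensor_field].
#' @param i,j,k voxel indices (1-based).
#' @return symmetric 3x3 matrix.
#' @export
field_tensor_at <- function(field, i, j, k) {
  lt6_to_mat(field$data[i, j, k, ])
}
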