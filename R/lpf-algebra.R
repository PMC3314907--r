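# Algebra of the linear perturbation model: the LPF matrix Sigma describes
# the fractional deviation of the effective diffusion gradient from the
# nominal one, g* = (I + Sigma) g. Only its symmetric part Sigma+ enters the
# first-order perturbation of B-matrices and tensors, through the LPF
# ellipsoid L = I + 2 Sigma+.

sym_part <- function(m) (m + t(m)) / 2

#' LPF ellipsoid from a perturbation matrix
#'
#' `L = I + 2 * Sigma+` where `Sigma+ = (Sigma + t(Sigma))/2`. Symmetric by
#' construction and positive definite for small perturbations.
#'
#' @param sigma 3x3 perturbation matrix (dimensionless), need not be
#'   symmetric.
#' @return symmetric 3x3 matrix.
#' @export
ellipsoid_from_sigma <- function(sigma) {
  stopifnot(all(is.finite(sigma)), all(dim(sigma) == c(3, 3)))
  diag(3) + sigma + t(sigma)
}

#' Symmetric perturbation matrix from an LPF ellipsoid
#'
#' Inverts [ellipsoid_from_sigma]: `Sigma+ = (L - I)/2`. Asymmetric input is
#' symmetrized with a warning.
#'
#' @param L 3x3 matrix, expected symmetric.
#' @return symmetric 3x3 matrix `Sigma+`.
#' @export
sigma_sym_from_ellipsoid <- function(L) {
  stopifnot(all(dim(L) == c(3, 3)))
  if (max(abs(L - t(L))) > 1e-10 * max(1, max(abs(L)))) {
    warning("asymmetric ellipsoid input; symmetrizing")
  }
  (sym_part(L) - diag(3)) / 2
}

#' Effective (perturbed) gradient direction
#'
#' `g* = (I + Sigma) g`. The result is deliberately not re-normalized: the
#' perturbation changes both the magnitude (hence the effective b-value) and
#' the direction of the diffusion gradient.
#'
#' @param g unit 3-vector.
#' @param sigma 3x3 perturbation matrix.
#' @return 3-vector.
#' @export
perturb_gradient <- function(g, sigma) {
  g <- as.numeric(g)
  stopifnot(length(g) == 3)
  if (abs(sqrt(sum(g^2)) - 1) > 1e-6) stop("g must be a unit vector")
  as.numeric((diag(3) + sigma) %*% g)
}

#' First-order perturbed B-matrix
#'
#' Symmetric first-order form `B + Sigma+ B + B Sigma+`, whose contraction
#' with any symmetric tensor equals that of `L %*% B` (trace cyclicity), so
#' only the symmetric part of `Sigma` enters.
#'
#' @param B symmetric 3x3 B-matrix.
#' @param sigma 3x3 perturbation matrix.
#' @return symmetric 3x3 matrix.
#' @export
perturb_b_matrix_linear <- function(B, sigma) {
  sp <- sym_part(sigma)
  B + sp %*% B + B %*% sp
}

# exact perturbed B-matrix b * g* g*^T (used by the simulator and by
# first-order-accuracy checks; not linearized)
perturb_b_matrix_exact <- function(b, g, sigma) {
  gs <- perturb_gradient(g, sigma)
  b * tcrossprod(gs)
}

#' First-order perturbed diffusion tensor
#'
#' The measured tensor under a perturbation with ellipsoid `L` is `L %*% D`
#' to first order; since that product is not generally symmetric the
#' symmetrized form `(LD + DL)/2` is returned, which leaves every scalar
#' observable `B : D*` unchanged and is itself a valid tensor.
#'
#' @param D symmetric 3x3 diffusion tensor.
#' @param L symmetric 3x3 LPF ellipsoid.
#' @return symmetric 3x3 tensor.
#' @export
perturbed_tensor <- function(D, L) {
  stopifnot(max(abs(L - t(L))) < 1e-10 * max(1, max(abs(L))))
  (L %*% D + D %*% L) / 2
}

#' Index maps of an LPF ellipsoid field
#'
#' Applies the standard tensor indices voxelwise to `L`. In the
#' isotropic-diffusion limit the measured tensor is proportional to `L`, so
#' the trace map of `L` marks regions of MD bias and the FA map of `L` marks
#' regions of FA bias in human index maps.
#'
#' @param field a [tensor_field] holding `L` per voxel.
#' @param principal_axis if `TRUE`, also compute the (slower, voxel-loop)
#'   principal-axis map.
#' @return list of 3-D arrays `trace`, `fa`, and optionally `principal_axis`
#'   (`[dim, 3]`).
#' @export
ellipsoid_index_maps <- function(field, principal_axis = FALSE) {
  maps <- index_maps(field)
  out <- list(trace = maps$trace, fa = maps$fa)
  if (principal_axis) {
    pa <- array(NA_real_, dim = c(field$dim, 3))
    idx <- which(field$mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
      pa[i, j, k, ] <- tensor_indices(field_tensor_at(field, i, j, k))$principal_axis
    }
    out$principal_axis <- pa
  }
  out
}
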