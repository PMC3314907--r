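# Correction of measured diffusion tensors for local-perturbation-field
# bias. Two modes mirror the two assessments of the off-diagonal elements:
# "diag" builds the ellipsoid from the diagonal of Sigma only (perturbation
# gradients parallel to the applied gradient), "full" uses the whole
# symmetric matrix.

correction_modes <- c("full", "diag")

# ellipsoid rows (N x 6) from Sigma+ rows under a correction mode
ellipsoid_rows_for_mode <- function(sigma_rows, mode) {
  L <- 2 * sigma_rows
  if (mode == "diag") L[, .LT_OFFDIAG] <- 0
  sweep(L, 2, .LT_EYE, "+")
}

#' Correct one measured diffusion tensor
#'
#' Inverts the first-order perturbation: `D = sym(solve(L) %*% D*)` with
#' `L = I + 2*diag(Sigma)` (mode `"diag"`) or `L = I + 2*Sigma+` (mode
#' `"full"`). If `L` is not positive definite the linear model is out of its
#' regime; the tensor is returned unchanged with a warning.
#'
#' @param d_star measured (perturbed) symmetric 3x3 tensor.
#' @param sigma 3x3 perturbation matrix at the voxel.
#' @param mode `"full"` (default) or `"diag"`.
#' @return corrected symmetric 3x3 tensor.
#' @export
correct_tensor <- function(d_star, sigma, mode = c("full", "diag")) {
  mode <- match.arg(mode)
  sp <- sym_part(sigma)
  if (mode == "diag") sp <- diag(diag(sp))
  L <- diag(3) + 2 * sp
  if (min(eigen(L, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    warning("LPF ellipsoid not positive definite; tensor passed through uncorrected")
    return(d_star)
  }
  Li <- solve(L)
  sym_part(Li %*% d_star)
}

#' Correct a tensor field for LPF bias
#'
#' Voxelwise [correct_tensor], vectorized. Voxels where the ellipsoid is not
#' positive definite are passed through uncorrected and counted.
#'
#' @param field a [tensor_field] of measured tensors `D*`.
#' @param sigma_field a [tensor_field] of `Sigma+` on the same grid.
#' @param mode `"full"` or `"diag"`.
#' @return a [tensor_field] of corrected tensors, with attribute
#'   `n_flagged` (count of passed-through voxels).
#' @export
correct_tensor_field <- function(field, sigma_field,
                                 mode = c("full", "diag")) {
  mode <- match.arg(mode)
  stopifnot(all(field$dim == sigma_field$dim))
  if (max(abs(field$affine - sigma_field$affine)) > 1e-6) {
    stop("tensor field and perturbation field are on different grids")
  }
  mask <- field$mask & sigma_field$mask
  sel <- as.vector(mask)
  d_rows <- matrix(field$data, ncol = 6)[sel, , drop = FALSE]
  s_rows <- matrix(sigma_field$data, ncol = 6)[sel, , drop = FALSE]
  L <- ellipsoid_rows_for_mode(s_rows, mode)
  pd <- lt6_is_pd(L)
  out <- d_rows
  if (any(pd)) {
    out[pd, ] <- lt6_mul_sym(lt6_inv(L[pd, , drop = FALSE]),
                             d_rows[pd, , drop = FALSE])
  }
  res <- field_from_rows(out, field$dim, field$affine, mask)
  attr(res, "n_flagged") <- sum(!pd)
  res
}

#' Correct a DWI dataset or tensor field with an LPF model
#'
#' Evaluates the model's `Sigma+` field on the data grid (in world/scanner
#' coordinates), fits tensors if raw DWI is given, applies the voxelwise
#' correction and recomputes index maps. With `refit = TRUE` the correction
#' is instead performed by perturbing each voxel's B-matrices
#' ([perturb_b_matrix_linear]) and refitting the tensor, an equivalent (to
#' first order) cross-validation route.
#'
#' @param data a [tensor_field] of measured tensors, or a 4-D DWI array.
#' @param scheme a [gradient_scheme]; required when `data` is a DWI array
#'   or when `refit = TRUE`.
#' @param affine 4x4 affine; required when `data` is a DWI array.
#' @param model an `lpf_model`.
#' @param mode `"full"` or `"diag"`.
#' @param mask optional logical 3-D array (DWI input only).
#' @param refit logical; use the B-matrix refit route.
#' @param dwi 4-D DWI array, required with `refit = TRUE` when `data` is a
#'   tensor field is not given (ADCs are needed).
#' @return list: `tensors` (corrected [tensor_field]), `fa`, `md` (3-D
#'   arrays), `report` (mode, flagged-voxel count, grid info).
#' @export
correct_dataset <- function(data, model, mode = c("full", "diag"),
                            scheme = NULL, affine = NULL, mask = NULL,
                            refit = FALSE, dwi = NULL) {
  mode <- match.arg(mode)
  if (is.array(data) && length(dim(data)) == 4) {
    if (is.null(scheme) || is.null(affine)) {
      stop("scheme and affine are required for DWI input")
    }
    dwi <- data
    fit <- fit_tensor_field(dwi, scheme, affine, mask)
    field <- fit$tensors
  } else if (inherits(data, "tensor_field")) {
    field <- data
  } else {
    stop("data must be a tensor_field or a 4-D DWI array")
  }
  sigma_field <- evaluate_lpf(model, field$dim, field$affine, field$mask)
  if (refit) {
    if (is.null(dwi) || is.null(scheme)) {
      stop("refit route requires the DWI volumes and the gradient scheme")
    }
    corrected <- refit_corrected_field(dwi, scheme, field, sigma_field, mode)
  } else {
    corrected <- correct_tensor_field(field, sigma_field, mode)
  }
  maps <- index_maps(corrected)
  list(tensors = corrected, fa = maps$fa, md = maps$md,
       report = list(mode = mode, refit = refit,
                     n_flagged = attr(corrected, "n_flagged") %||% 0L,
                     n_voxels = sum(corrected$mask)))
}

# correction by voxelwise perturbed-B-matrix refit (cross-validation route)
refit_corrected_field <- function(dwi, scheme, field, sigma_field, mode) {
  assert_fittable(scheme)
  dim3 <- field$dim
  nvox <- prod(dim3)
  vols <- matrix(dwi, nrow = nvox)
  s0 <- rowMeans(vols[, !scheme$dwi, drop = FALSE])
  dw <- vols[, scheme$dwi, drop = FALSE]
  b <- scheme$bvals[scheme$dwi]
  g <- scheme$bvecs[, scheme$dwi, drop = FALSE]
  n_dir <- sum(scheme$dwi)
  bb <- rep(b, each = nvox)
  attn <- adc_from_signals(s0, dw, bb) * bb
  dim(attn) <- dim(dw)
  mask <- field$mask & sigma_field$mask
  idx <- which(as.vector(mask))
  s_rows <- matrix(sigma_field$data, ncol = 6)
  out <- matrix(0, length(idx), 6)
  n_flagged <- 0L
  B0 <- lapply(seq_len(n_dir), function(i) build_b_matrix(b[i], g[, i]))
  for (r in seq_along(idx)) {
    v <- idx[r]
    sp <- lt6_to_mat(s_rows[v, ])
    if (mode == "diag") sp <- diag(diag(sp))
    Bp <- lapply(B0, function(B) perturb_b_matrix_linear(B, sp))
    D <- tryCatch(fit_tensor(attn[v, ], Bp), error = function(e) NULL)
    if (is.null(D)) {
      n_flagged <- n_flagged + 1L
      D <- lt6_to_mat(matrix(field$data, ncol = 6)[v, ])
    }
    out[r, ] <- mat_to_lt6(D)
  }
  res <- field_from_rows(out, dim3, field$affine, mask)
  attr(res, "n_flagged") <- n_flagged
  res
}

#' Grey-to-white-matter FA contrast
#'
#' Mean FA over the white-matter mask minus mean FA over the grey-matter
#' mask, optionally restricted to a region of interest. Perturbations bias
#' small (grey-matter) FA values towards greater anisotropy, which lowers
#' this contrast; correction should raise it.
#'
#' @param fa_map 3-D FA array.
#' @param wm_mask,gm_mask logical 3-D arrays; must be disjoint.
#' @param roi optional logical 3-D array restricting both masks.
#' @return scalar contrast (WM mean FA - GM mean FA).
#' @export
fa_contrast <- function(fa_map, wm_mask, gm_mask, roi = NULL) {
  if (any(wm_mask & gm_mask)) stop("WM and GM masks must be disjoint")
  if (!is.null(roi)) {
    wm_mask <- wm_mask & roi
    gm_mask <- gm_mask & roi
  }
  if (sum(wm_mask, na.rm = TRUE) == 0 || sum(gm_mask, na.rm = TRUE) == 0) {
    stop("empty WM or GM mask within the ROI")
  }
  mean(fa_map[wm_mask], na.rm = TRUE) - mean(fa_map[gm_mask], na.rm = TRUE)
}
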