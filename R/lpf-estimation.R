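# Two-step estimation of the local perturbation field from water-phantom
# DWI. Step 1: the phantom's diffusion is isotropic with coefficient D_w, so
# a voxelwise tensor fit of the phantom ADCs returns D_w * L(r) where L is
# the LPF ellipsoid. Step 2: each unique element of Sigma+ = (L - I)/2 is
# fitted spatially with 3rd-order solid harmonics by weighted least squares,
# down-weighting voxels with a large tensor-fit residual (the footprint of
# artefacts not described by the perturbation model).

#' Voxelwise LPF ellipsoid fit from phantom DWI
#'
#' Fits a diffusion tensor per voxel of an isotropic-phantom dataset. Under
#' the perturbation model the fitted tensor equals `D_w * L(r)`; the result
#' is returned un-normalized together with the per-voxel residual variance.
#'
#' @param dwi 4-D phantom DWI array.
#' @param scheme a [gradient_scheme].
#' @param affine 4x4 voxel-to-world affine.
#' @param mask logical 3-D array of phantom voxels.
#' @return list: `ellipsoid_raw` (a [tensor_field], `D_w * L`),
#'   `residual_var` (3-D array).
#' @export
voxelwise_ellipsoid <- function(dwi, scheme, affine, mask) {
  fit <- fit_tensor_field(dwi, scheme, affine, mask)
  list(ellipsoid_raw = fit$tensors, residual_var = fit$residual_var)
}

#' Water diffusion coefficient from the phantom centre
#'
#' The perturbation field is minimal at the isocentre, so the median mean
#' diffusivity over a small central region of interest estimates the
#' phantom's true diffusion coefficient `D_w`. A user-supplied
#' (temperature-calibrated) value can be passed instead.
#'
#' @param ellipsoid_raw un-normalized ellipsoid field (`D_w * L`).
#' @param roi_radius_mm radius of the central spherical ROI (default 15).
#' @param center_mm world-space ROI centre (default the origin/isocentre).
#' @return `D_w` in mm^2/s.
#' @export
estimate_dw <- function(ellipsoid_raw, roi_radius_mm = 15,
                        center_mm = c(0, 0, 0)) {
  roi <- sphere_mask(ellipsoid_raw$dim, ellipsoid_raw$affine,
                     roi_radius_mm, center_mm) & ellipsoid_raw$mask
  if (sum(roi) < 10) {
    stop(sprintf("central ROI contains only %d valid voxels (>= 10 required)",
                 sum(roi)))
  }
  rows <- matrix(ellipsoid_raw$data, ncol = 6)[as.vector(roi), , drop = FALSE]
  stats::median(lt6_md(rows))
}

#' Spatially constrained LPF model fit
#'
#' Converts the ellipsoid field to `Sigma+ = (L - I)/2` with
#' `L = ellipsoid_raw / D_w` and fits each of the six unique elements with a
#' 3rd-order solid-harmonic expansion by weighted least squares, weights
#' `1/(residual_var + eps)`.
#'
#' @param ellipsoid_raw un-normalized ellipsoid field (`D_w * L`).
#' @param residual_var 3-D array of voxelwise tensor-fit residual variances.
#' @param D_w water diffusion coefficient (mm^2/s).
#' @param order harmonic order (default 3).
#' @param frame an [sh_frame]; defaults to origin 0 (isocentre), R_ref 150.
#' @param eps regularizer added to the residual variance (default 1e-12).
#' @return an `lpf_model`: six [sh_coefficients] sets (one per unique
#'   element of `Sigma+`, in lower-triangular order), `D_w`, and provenance
#'   (voxel count, residual summary).
#' @export
fit_lpf_field <- function(ellipsoid_raw, residual_var, D_w, order = 3,
                          frame = sh_frame(), eps = 1e-12) {
  stopifnot(D_w > 0)
  mask <- ellipsoid_raw$mask & is.finite(residual_var)
  n <- sum(mask)
  k <- (order + 1)^2
  if (n < k) stop(sprintf("only %d valid voxels; >= %d required", n, k))
  rows <- matrix(ellipsoid_raw$data, ncol = 6)[as.vector(mask), , drop = FALSE]
  sigma_rows <- sweep(rows / D_w, 2, .LT_EYE) / 2
  xyz <- voxel_world_coords(ellipsoid_raw$dim, ellipsoid_raw$affine)
  xyz <- xyz[as.vector(mask), , drop = FALSE]
  design <- sh_design_matrix(xyz, order, frame)
  w <- 1 / (residual_var[mask] + eps)
  coefs <- vector("list", 6)
  rv <- numeric(6)
  for (e in 1:6) {
    fit <- wls_fit(design, sigma_rows[, e], w)
    rv[e] <- attr(fit, "residual_var")
    coefs[[e]] <- sh_coefficients(as.numeric(fit), order, frame)
  }
  names(coefs) <- .LT_NAMES
  structure(list(elements = coefs, order = order, frame = frame, D_w = D_w,
                 provenance = list(n_voxels = n,
                                   residual_var = stats::setNames(rv, .LT_NAMES))),
            class = "lpf_model")
}

#' Construct an LPF model from coefficient sets
#'
#' Assembles the six per-element harmonic expansions into an `lpf_model`,
#' e.g. to turn a simulated ground-truth field into a model usable by
#' [evaluate_lpf] and [correct_dataset].
#'
#' @param elements named list of six [sh_coefficients] (names `xx`, `xy`,
#'   `yy`, `xz`, `yz`, `zz`), sharing order and frame.
#' @param D_w water diffusion coefficient associated with the model
#'   (mm^2/s).
#' @return an `lpf_model`.
#' @export
lpf_model <- function(elements, D_w = NA_real_) {
  stopifnot(all(.LT_NAMES %in% names(elements)))
  elements <- elements[.LT_NAMES]
  ref <- elements[[1]]
  for (cf in elements) {
    stopifnot(inherits(cf, "sh_coefficients"))
    if (cf$order != ref$order || !frames_equal(cf$frame, ref$frame)) {
      stop("all six elements must share order and frame")
    }
  }
  structure(list(elements = elements, order = ref$order, frame = ref$frame,
                 D_w = D_w, provenance = list(source = "constructed")),
            class = "lpf_model")
}

#' @export
print.lpf_model <- function(x, ...) {
  cat("<lpf_model> order-", x$order, " solid-harmonic expansion of Sigma+ (",
      length(x$elements[[1]]$coefficients), " coefficients x 6 elements)\n",
      "  D_w = ", format(x$D_w, digits = 4), " mm^2/s; fitted from ",
      x$provenance$n_voxels %||% NA, " voxels\n", sep = "")
  invisible(x)
}

#' Evaluate an LPF model on a voxel grid
#'
#' @param model an `lpf_model`.
#' @param dim3 grid dimensions.
#' @param affine 4x4 voxel-to-world affine of the target grid (the model
#'   lives in world/scanner coordinates, so a shifted grid samples a shifted
#'   part of the field).
#' @param mask optional logical 3-D array.
#' @return a [tensor_field] of symmetric `Sigma+` matrices.
#' @export
evaluate_lpf <- function(model, dim3, affine, mask = NULL) {
  stopifnot(inherits(model, "lpf_model"))
  xyz <- voxel_world_coords(dim3, affine)
  design <- sh_design_matrix(xyz, model$order, model$frame)
  rows <- vapply(model$elements,
                 function(cf) {
                   if (!frames_equal(cf$frame, model$frame)) {
                     stop("element frame differs from model frame")
                   }
                   as.numeric(design %*% cf$coefficients)
                 },
                 numeric(nrow(xyz)))
  mask <- mask %||% array(TRUE, dim3)
  field_from_rows(rows[as.vector(mask), , drop = FALSE], dim3, affine, mask)
}

#' Automatic phantom mask from the mean b=0 image
#'
#' Threshold at a fraction of the robust maximum (99th percentile) of the
#' mean non-DW image, then erode to exclude edge and ringing voxels where
#' the smoothness assumption fails.
#'
#' @param b0_mean 3-D array.
#' @param threshold_frac intensity threshold as a fraction of the robust
#'   maximum (default 0.3).
#' @param erode_voxels erosion passes (default 2).
#' @return logical 3-D array.
#' @export
auto_phantom_mask <- function(b0_mean, threshold_frac = 0.3,
                              erode_voxels = 2) {
  rmax <- stats::quantile(b0_mean, 0.99, na.rm = TRUE, names = FALSE)
  erode_mask(b0_mean > threshold_frac * rmax, erode_voxels)
}

#' Full two-step LPF estimation pipeline from phantom DWI
#'
#' Optionally smooths the phantom data (5-mm FWHM Gaussian by default),
#' masks it, performs the voxelwise ellipsoid fit, determines `D_w`, and
#' fits the constrained spatial model.
#'
#' @param dwi 4-D phantom DWI array.
#' @param scheme a [gradient_scheme].
#' @param affine 4x4 voxel-to-world affine.
#' @param mask `"auto"` (default) for [auto_phantom_mask], or a logical
#'   3-D array.
#' @param dw `"auto"` (default) to estimate `D_w` via [estimate_dw], or a
#'   numeric value.
#' @param order harmonic order (default 3).
#' @param smooth_fwhm_mm Gaussian pre-smoothing FWHM in mm (default 5; 0
#'   disables).
#' @param frame an [sh_frame].
#' @return list of class `lpf_fit`: `model` (the `lpf_model`),
#'   `ellipsoid_raw`, `residual_var`, `mask`, `D_w`.
#' @export
estimate_lpf <- function(dwi, scheme, affine, mask = "auto", dw = "auto",
                         order = 3, smooth_fwhm_mm = 5, frame = sh_frame()) {
  voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (smooth_fwhm_mm > 0) {
    dwi <- gaussian_smooth(dwi, smooth_fwhm_mm, voxel_mm)
  }
  if (identical(mask, "auto")) {
    nvox <- prod(dim(dwi)[1:3])
    b0 <- rowMeans(matrix(dwi, nvox)[, !scheme$dwi, drop = FALSE])
    mask <- auto_phantom_mask(array(b0, dim(dwi)[1:3]))
  }
  step1 <- voxelwise_ellipsoid(dwi, scheme, affine, mask)
  D_w <- if (identical(dw, "auto")) {
    estimate_dw(step1$ellipsoid_raw, center_mm = frame$origin_mm)
  } else {
    as.numeric(dw)
  }
  model <- fit_lpf_field(step1$ellipsoid_raw, step1$residual_var, D_w,
                         order = order, frame = frame)
  structure(list(model = model, ellipsoid_raw = step1$ellipsoid_raw,
                 residual_var = step1$residual_var,
                 mask = step1$ellipsoid_raw$mask, D_w = D_w),
            class = "lpf_fit")
}

#' Serialize an LPF model to JSON
#'
#' @param model an `lpf_model`.
#' @param path output file path.
#' @export
write_lpf_model <- function(model, path) {
  stopifnot(inherits(model, "lpf_model"))
  obj <- list(
    order = model$order,
    frame = list(origin_mm = model$frame$origin_mm,
                 R_ref_mm = model$frame$R_ref_mm),
    lm_order = "l ascending, m = -l..l; real solid harmonics, unnormalized",
    element_order = .LT_NAMES,
    D_w = model$D_w,
    coefficients = lapply(model$elements, function(cf) cf$coefficients),
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an LPF model from JSON
#'
#' @param path file written by [write_lpf_model].
#' @return an `lpf_model`.
#' @export
read_lpf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame <- sh_frame(obj$frame$origin_mm, obj$frame$R_ref_mm)
  elements <- lapply(.LT_NAMES, function(nm) {
    sh_coefficients(obj$coefficients[[nm]], obj$order, frame)
  })
  names(elements) <- .LT_NAMES
  structure(list(elements = elements, order = obj$order, frame = frame,
                 D_w = obj$D_w, provenance = obj$provenance),
            class = "lpf_model")
}
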