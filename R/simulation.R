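# Synthetic isotropic-phantom generator and Monte-Carlo precision study.
# The simulated conditions: a spherical water phantom with a single
# diffusion coefficient chosen so the DW/non-DW signal ratio is 1/5 at
# b = 1000 s/mm^2, perturbed by a random 3rd-order solid-harmonic LPF
# normalized to 0.1 peak-to-peak, Gaussian noise at SNR 50 (b=0) and 10
# (DW), and 5-mm-FWHM smoothing before re-estimation.

#' Simulation configuration
#'
#' Defaults reproduce the reference phantom conditions. The forward signal
#' model is exact (not linearized): the effective gradient `g* = (I+Sigma)g`
#' scales the b-value by `|g*|^2`, so the estimator's linearization error is
#' part of what the simulation measures.
#'
#' @param grid_dim isotropic grid size (default 48).
#' @param voxel_mm isotropic voxel size in mm (default 2.3).
#' @param sphere_frac phantom sphere radius as a fraction of half the field
#'   of view (default 0.8).
#' @param b b-value in s/mm^2 (default 1000).
#' @param n_directions number of DW directions (default 60).
#' @param n_b0 number of b=0 volumes (default 6).
#' @param D_sim phantom diffusion coefficient, mm^2/s (default `log(5)/b`,
#'   giving a DW/non-DW signal ratio of 1/5).
#' @param amplitude peak-to-peak LPF normalization (default 0.1).
#' @param snr_b0 SNR of the b=0 volumes (default 50; `Inf` for noiseless).
#' @param snr_dw SNR of the DW volumes (default 10; `Inf` for noiseless).
#' @param fwhm_mm Gaussian smoothing FWHM in mm applied before
#'   re-estimation (default 5; 0 disables).
#' @param s0 noiseless non-DW signal level inside the phantom (default 100).
#' @param ptp_per_element normalize peak-to-peak per element instead of
#'   globally (default `FALSE`).
#' @param sh_order harmonic order of the simulated field (default 3).
#' @param R_ref_mm harmonic scaling radius (default 150).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(grid_dim = 48, voxel_mm = 2.3, sphere_frac = 0.8,
                       b = 1000, n_directions = 60, n_b0 = 6,
                       D_sim = log(5) / b, amplitude = 0.1,
                       snr_b0 = 50, snr_dw = 10, fwhm_mm = 5, s0 = 100,
                       ptp_per_element = FALSE, sh_order = 3,
                       R_ref_mm = 150) {
  stopifnot(grid_dim >= 8, voxel_mm > 0, sphere_frac > 0, sphere_frac <= 1,
            b > 0, n_directions >= 6, n_b0 >= 1, D_sim > 0,
            amplitude >= 0, amplitude < 1, snr_b0 > 0, snr_dw > 0,
            fwhm_mm >= 0, s0 > 0)
  cfg <- list(grid_dim = grid_dim, voxel_mm = voxel_mm,
              sphere_frac = sphere_frac, b = b,
              n_directions = n_directions, n_b0 = n_b0, D_sim = D_sim,
              amplitude = amplitude, snr_b0 = snr_b0, snr_dw = snr_dw,
              fwhm_mm = fwhm_mm, s0 = s0,
              ptp_per_element = ptp_per_element, sh_order = sh_order,
              R_ref_mm = R_ref_mm)
  cfg$dim3 <- rep(grid_dim, 3)
  cfg$affine <- centered_affine(cfg$dim3, voxel_mm)
  cfg$radius_mm <- sphere_frac * grid_dim * voxel_mm / 2
  class(cfg) <- "sim_config"
  cfg
}

# deterministic quasi-uniform unit directions (Fibonacci sphere)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  rbind(r * cos(phi), r * sin(phi), z)
}

# gradient scheme of a simulated acquisition: n_b0 b=0 volumes first
sim_scheme <- function(config) {
  g <- cbind(matrix(0, 3, config$n_b0),
             fibonacci_directions(config$n_directions))
  bv <- c(rep(0, config$n_b0), rep(config$b, config$n_directions))
  gradient_scheme(bv, g)
}

#' Draw a random 3rd-order solid-harmonic perturbation field
#'
#' Coefficients of the six unique `Sigma+` elements are drawn uniformly
#' from `[-1, 1]` on a basis whose columns are normalized to unit maximum
#' magnitude over the phantom mask (so every harmonic order contributes
#' comparably over the phantom), and the field is then rescaled so that the
#' peak-to-peak variation over the mask equals the configured amplitude
#' (the maximum over elements, or per element with `ptp_per_element`).
#' Stored coefficients are re-expressed in the standard evaluation basis.
#'
#' @param config a [sim_config].
#' @param seed optional integer seed (uses the current RNG state if `NULL`).
#' @return list: `sigma` (a [tensor_field] of `Sigma+`, full grid with the
#'   phantom-sphere mask), `coefficients` (list of six [sh_coefficients]),
#'   `mask`.
#' @export
random_lpf <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- sphere_mask(config$dim3, config$affine, config$radius_mm)
  frame <- sh_frame(R_ref_mm = config$R_ref_mm)
  xyz <- voxel_world_coords(config$dim3, config$affine)
  design <- sh_design_matrix(xyz, config$sh_order, frame)
  k <- (config$sh_order + 1)^2
  col_scale <- apply(abs(design[as.vector(mask), , drop = FALSE]), 2, max)
  repeat {
    coefs <- matrix(stats::runif(6 * k, -1, 1), k, 6) / col_scale
    fields <- design %*% coefs              # Nvox x 6
    masked <- fields[as.vector(mask), , drop = FALSE]
    ptp <- apply(masked, 2, function(v) diff(range(v)))
    if (config$amplitude == 0) {
      coefs[] <- 0
      fields[] <- 0
      break
    }
    if (all(ptp > 0)) {
      if (config$ptp_per_element) {
        scale <- config$amplitude / ptp
        coefs <- sweep(coefs, 2, scale, "*")
        fields <- sweep(fields, 2, scale, "*")
      } else {
        scale <- config$amplitude / max(ptp)
        coefs <- coefs * scale
        fields <- fields * scale
      }
      break
    }
  }
  sigma <- field_from_rows(fields[as.vector(mask), , drop = FALSE],
                           config$dim3, config$affine, mask)
  coefficients <- lapply(seq_len(6), function(e) {
    sh_coefficients(coefs[, e], config$sh_order, frame)
  })
  names(coefficients) <- .LT_NAMES
  list(sigma = sigma, coefficients = coefficients, mask = mask)
}

#' Synthesize phantom DWI volumes under a perturbation field
#'
#' Exact Stejskal-Tanner forward model: inside the phantom the DW signal is
#' `s0 * exp(-b * |g*|^2 * D_sim)` with `g* = (I + Sigma) g` (the
#' un-normalized effective gradient carries the b-value error), b=0 volumes
#' are `s0`, outside voxels are zero signal. Additive Gaussian noise with
#' `sd = s0 / snr_b0` on b=0 volumes and `sd` set so that the mean
#' in-phantom noiseless DW signal over `sd` equals `snr_dw`.
#'
#' @param sigma_field a [tensor_field] of `Sigma+` (e.g. from [random_lpf]).
#' @param config a [sim_config].
#' @param seed optional integer seed for the noise.
#' @param forward `"exact"` (default) for the full quadratic signal model,
#'   or `"linear"` for the first-order perturbed B-matrix (under which the
#'   full-matrix correction with the true field is exact; useful for
#'   cross-checks of the estimator without its linearization error).
#' @return list: `dwi` (4-D array), `scheme`, `affine`, `mask`, `config`.
#' @export
synthesize_phantom <- function(sigma_field, config, seed = NULL,
                               forward = c("exact", "linear")) {
  forward <- match.arg(forward)
  if (!is.null(seed)) set.seed(seed)
  scheme <- sim_scheme(config)
  dim3 <- config$dim3
  nvox <- prod(dim3)
  mask <- sigma_field$mask
  sel <- as.vector(mask)
  s_rows <- matrix(sigma_field$data, ncol = 6)[sel, , drop = FALSE]
  s11 <- s_rows[, 1]; s12 <- s_rows[, 2]; s22 <- s_rows[, 3]
  s13 <- s_rows[, 4]; s23 <- s_rows[, 5]; s33 <- s_rows[, 6]
  g <- scheme$bvecs
  vols <- matrix(0, nvox, scheme$n_volumes)
  for (i in seq_len(scheme$n_volumes)) {
    if (!scheme$dwi[i]) {
      vols[sel, i] <- config$s0
      next
    }
    gx <- g[1, i]; gy <- g[2, i]; gz <- g[3, i]
    if (forward == "exact") {
      gsx <- gx + s11 * gx + s12 * gy + s13 * gz
      gsy <- gy + s12 * gx + s22 * gy + s23 * gz
      gsz <- gz + s13 * gx + s23 * gy + s33 * gz
      beff <- scheme$bvals[i] * (gsx^2 + gsy^2 + gsz^2)
    } else {
      gLg <- 1 + 2 * (s11 * gx^2 + s22 * gy^2 + s33 * gz^2 +
                        2 * (s12 * gx * gy + s13 * gx * gz + s23 * gy * gz))
      beff <- scheme$bvals[i] * gLg
    }
    vols[sel, i] <- config$s0 * exp(-beff * config$D_sim)
  }
  if (is.finite(config$snr_b0) || is.finite(config$snr_dw)) {
    mean_dw <- mean(vols[sel, scheme$dwi])
    sd_b0 <- if (is.finite(config$snr_b0)) config$s0 / config$snr_b0 else 0
    sd_dw <- if (is.finite(config$snr_dw)) mean_dw / config$snr_dw else 0
    noise_sd <- ifelse(scheme$dwi, sd_dw, sd_b0)
    vols <- vols + matrix(stats::rnorm(length(vols)), nvox) *
      rep(noise_sd, each = nvox)
  }
  list(dwi = array(vols, dim = c(dim3, scheme$n_volumes)), scheme = scheme,
       affine = config$affine, mask = mask, config = config)
}

#' Separable Gaussian smoothing of a 3-D or 4-D volume
#'
#' Kernel standard deviation `fwhm / (2*sqrt(2*log(2)))` per axis in mm,
#' truncated at 4 sd, reflect-mode boundaries (rows of the smoothing
#' operator sum to 1, so total intensity is conserved). `fwhm = 0` is the
#' identity.
#'
#' @param volume 3-D array, or 4-D array (each sub-volume smoothed).
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_mm voxel size in mm (scalar or length 3).
#' @return array of the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_mm) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume)
  voxel_mm <- rep_len(voxel_mm, 3)
  nd <- length(dim(volume))
  if (nd == 4) {
    out <- volume
    for (t in seq_len(dim(volume)[4])) {
      out[, , , t] <- gaussian_smooth(volume[, , , t], fwhm_mm, voxel_mm)
    }
    return(out)
  }
  stopifnot(nd == 3)
  d <- dim(volume)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    sig <- sigma_mm / voxel_mm[axis]
    half <- max(1L, ceiling(4 * sig))
    taps <- exp(-0.5 * ((-half):half / sig)^2)
    taps <- taps / sum(taps)
    n <- d[axis]
    K <- matrix(0, n, n)
    for (o in (-half):half) {
      idx <- seq_len(n) + o
      idx <- ifelse(idx < 1, 2 - idx, idx)          # reflect low edge
      idx <- ifelse(idx > n, 2 * n - idx, idx)      # reflect high edge
      K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] +
        taps[o + half + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    v <- aperm(volume, perm)
    dv <- dim(v)
    v <- K %*% matrix(v, nrow = n)
    dim(v) <- dv
    volume <- aperm(v, order(perm))
  }
  volume
}

#' Normalized mean difference between two perturbation fields
#'
#' Elementwise precision metric: per voxel, the modulus of the difference
#' between true and estimated `Sigma` elements divided by the average of
#' the two moduli, then averaged over the mask (the symmetric normalized
#' mean difference). Voxels where both fields vanish contribute zero; an
#' element that is identically zero in both fields yields 0.
#'
#' @param sigma_true,sigma_est [tensor_field]s on the same grid.
#' @param mask logical 3-D array (default: intersection of field masks).
#' @return 3x3 matrix of `delta_epsilon` values (dimensionless fractions).
#' @export
delta_epsilon <- function(sigma_true, sigma_est, mask = NULL) {
  stopifnot(all(sigma_true$dim == sigma_est$dim))
  mask <- mask %||% (sigma_true$mask & sigma_est$mask)
  if (sum(mask) == 0) stop("empty mask")
  sel <- as.vector(mask)
  tr_ <- matrix(sigma_true$data, ncol = 6)[sel, , drop = FALSE]
  es_ <- matrix(sigma_est$data, ncol = 6)[sel, , drop = FALSE]
  num <- abs(tr_ - es_)
  den <- (abs(tr_) + abs(es_)) / 2
  ratio <- num / den
  ratio[den == 0] <- 0      # both elements vanish at the voxel
  lt6_to_mat(colMeans(ratio))
}

#' Monte-Carlo study of LPF estimation precision
#'
#' Per trial: draw a random perturbation field, synthesize noisy phantom
#' DWI, smooth, re-estimate the field with the two-step phantom pipeline
#' (true `D_sim` supplied as `D_w`), and compute the elementwise
#' [delta_epsilon] against the truth over the estimation mask.
#'
#' @param n_trials number of trials (>= 1).
#' @param config a [sim_config].
#' @param seed integer seed governing all randomness.
#' @return list of class `lpf_monte_carlo`: `per_trial` (data.frame with
#'   `trial`, `element`, `delta_epsilon`), `summary` (pooled medians for
#'   diagonal and off-diagonal elements), `failures` (indices of failed
#'   trials, if any).
#' @export
monte_carlo <- function(n_trials, config = sim_config(), seed = 1) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  rows <- vector("list", n_trials)
  failures <- integer(0)
  elem_lab <- c("xx", "xy", "yy", "xz", "yz", "zz")
  for (trial in seq_len(n_trials)) {
    res <- tryCatch({
      truth <- random_lpf(config)
      phantom <- synthesize_phantom(truth$sigma, config)
      fit <- estimate_lpf(phantom$dwi, phantom$scheme, phantom$affine,
                          mask = "auto", dw = config$D_sim,
                          order = config$sh_order,
                          smooth_fwhm_mm = config$fwhm_mm,
                          frame = sh_frame(R_ref_mm = config$R_ref_mm))
      sigma_est <- evaluate_lpf(fit$model, config$dim3, config$affine,
                                fit$mask)
      de <- delta_epsilon(truth$sigma, sigma_est, fit$mask & truth$mask)
      data.frame(trial = trial, element = elem_lab,
                 delta_epsilon = mat_to_lt6(de))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, trial)
    } else {
      rows[[trial]] <- res
    }
  }
  per_trial <- do.call(rbind, rows)
  diag_el <- per_trial$element %in% c("xx", "yy", "zz")
  summary <- c(
    diagonal = stats::median(per_trial$delta_epsilon[diag_el]),
    off_diagonal = stats::median(per_trial$delta_epsilon[!diag_el])
  )
  structure(list(per_trial = per_trial, summary = summary,
                 failures = failures, config = config, seed = seed),
            class = "lpf_monte_carlo")
}

#' @export
print.lpf_monte_carlo <- function(x, ...) {
  n <- length(unique(x$per_trial$trial))
  cat("<lpf_monte_carlo> ", n, " trials\n",
      "  pooled median delta-epsilon: diagonal ",
      sprintf("%.1f%%", 100 * x$summary[["diagonal"]]),
      ", off-diagonal ",
      sprintf("%.1f%%", 100 * x$summary[["off_diagonal"]]), "\n", sep = "")
  if (length(x$failures) > 0) {
    cat("  failed trials:", paste(x$failures, collapse = ", "), "\n")
  }
  invisible(x)
}
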