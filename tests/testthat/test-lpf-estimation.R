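test_that("a zero-perturbation phantom fits D_w * I in every voxel", {
  cfg <- small_config(amplitude = 0, snr_b0 = Inf, snr_dw = Inf, fwhm_mm = 0)
  truth <- random_lpf(cfg, seed = 1)
  ph <- synthesize_phantom(truth$sigma, cfg)
  step1 <- voxelwise_ellipsoid(ph$dwi, ph$scheme, ph$affine, truth$mask)
  rows <- lpfdti:::field_rows(step1$ellipsoid_raw)
  target <- cfg$D_sim * c(1, 0, 1, 0, 0, 1)
  expect_lt(max(abs(sweep(rows, 2, target))), 1e-12 * cfg$D_sim + 1e-18)
})

test_that("voxelwise ellipsoid matches I + 2 Sigma to first order", {
  cfg <- small_config(snr_b0 = Inf, snr_dw = Inf, fwhm_mm = 0,
                      amplitude = 0.04)
  truth <- random_lpf(cfg, seed = 2)
  ph <- synthesize_phantom(truth$sigma, cfg)
  step1 <- voxelwise_ellipsoid(ph$dwi, ph$scheme, ph$affine, truth$mask)
  L_rows <- lpfdti:::field_rows(step1$ellipsoid_raw) / cfg$D_sim
  target <- sweep(2 * lpfdti:::field_rows(truth$sigma), 2,
                  c(1, 0, 1, 0, 0, 1), "+")
  # residual is the quadratic Sigma^T Sigma term
  expect_lt(max(abs(L_rows - target)), 3 * (cfg$amplitude)^2)
})

test_that("D_w estimation is a robust central-ROI median", {
  dim3 <- c(16, 16, 16)
  aff <- lpfdti:::centered_affine(dim3, 3)
  D0 <- 2.0e-3
  rows <- matrix(rep(D0 * c(1, 0, 1, 0, 0, 1), each = prod(dim3)), ncol = 6)
  f <- tensor_field(array(rows, c(dim3, 6)), aff)
  expect_equal(estimate_dw(f), D0)
  # 10% corrupted voxels barely move the median
  set.seed(4)
  bad <- sample(prod(dim3), round(0.1 * prod(dim3)))
  rows2 <- rows
  rows2[bad, c(1, 3, 6)] <- rows2[bad, c(1, 3, 6)] * 5
  f2 <- tensor_field(array(rows2, c(dim3, 6)), aff)
  expect_lt(abs(estimate_dw(f2) - D0) / D0, 0.01)
  # empty ROI errors
  expect_error(estimate_dw(f, roi_radius_mm = 0.1), "ROI")
})

test_that("noiseless fields in the harmonic span are recovered", {
  cfg <- small_config(snr_b0 = Inf, snr_dw = Inf, fwhm_mm = 0)
  truth <- random_lpf(cfg, seed = 5)
  ph <- synthesize_phantom(truth$sigma, cfg, forward = "linear")
  fit <- estimate_lpf(ph$dwi, ph$scheme, ph$affine, mask = truth$mask,
                      dw = cfg$D_sim, smooth_fwhm_mm = 0)
  est <- evaluate_lpf(fit$model, cfg$dim3, cfg$affine, truth$mask)
  err <- max(abs(lpfdti:::field_rows(est) - lpfdti:::field_rows(truth$sigma)))
  # linear forward model: recovery to numerical precision
  expect_lt(err, 1e-3 * cfg$amplitude)
})

test_that("down-weighting suppresses corrupted voxels", {
  cfg <- small_config(snr_b0 = Inf, snr_dw = Inf, fwhm_mm = 0)
  truth <- random_lpf(cfg, seed = 6)
  ph <- synthesize_phantom(truth$sigma, cfg, forward = "linear")
  step1 <- voxelwise_ellipsoid(ph$dwi, ph$scheme, ph$affine, truth$mask)
  # corrupt 5% of voxels and give them large residual variance
  set.seed(7)
  idx <- which(step1$ellipsoid_raw$mask)
  bad <- sample(idx, round(0.05 * length(idx)))
  data <- step1$ellipsoid_raw$data
  flat <- matrix(data, ncol = 6)
  flat[bad, ] <- flat[bad, ] + cfg$D_sim * 0.5
  corrupted <- tensor_field(array(flat, dim(data)),
                            step1$ellipsoid_raw$affine,
                            step1$ellipsoid_raw$mask)
  rv <- step1$residual_var
  rv_flagged <- rv
  rv_flagged[bad] <- rv_flagged[bad] + 1e3 * max(rv, na.rm = TRUE) + 1
  m_weighted <- fit_lpf_field(corrupted, rv_flagged, cfg$D_sim)
  m_flat <- fit_lpf_field(corrupted, rv * 0, cfg$D_sim)
  truth_coef <- vapply(truth$coefficients, `[[`, numeric(16), "coefficients")
  err_w <- max(abs(vapply(m_weighted$elements, `[[`, numeric(16),
                          "coefficients") - truth_coef))
  err_f <- max(abs(vapply(m_flat$elements, `[[`, numeric(16),
                          "coefficients") - truth_coef))
  expect_lt(err_w, err_f / 10)
})

test_that("single-slice spatial sampling is rejected", {
  cfg <- small_config(snr_b0 = Inf, snr_dw = Inf, fwhm_mm = 0)
  truth <- random_lpf(cfg, seed = 8)
  ph <- synthesize_phantom(truth$sigma, cfg)
  slice_mask <- truth$mask
  slice_mask[, , -10] <- FALSE
  step1 <- voxelwise_ellipsoid(ph$dwi, ph$scheme, ph$affine, slice_mask)
  expect_error(fit_lpf_field(step1$ellipsoid_raw, step1$residual_var,
                             cfg$D_sim),
               "deficient")
})

test_that("the model is invariant to signal scale and to D_w", {
  cfg <- small_config(snr_b0 = Inf, snr_dw = Inf, fwhm_mm = 0)
  truth <- random_lpf(cfg, seed = 9)
  ph <- synthesize_phantom(truth$sigma, cfg)
  fit1 <- estimate_lpf(ph$dwi, ph$scheme, ph$affine, mask = truth$mask,
                       dw = cfg$D_sim, smooth_fwhm_mm = 0)
  fit2 <- estimate_lpf(ph$dwi * 7.3, ph$scheme, ph$affine,
                       mask = truth$mask, dw = cfg$D_sim,
                       smooth_fwhm_mm = 0)
  c1 <- vapply(fit1$model$elements, `[[`, numeric(16), "coefficients")
  c2 <- vapply(fit2$model$elements, `[[`, numeric(16), "coefficients")
  expect_equal(c1, c2, tolerance = 1e-9)

  # doubling the true water diffusivity (and regenerating) leaves Sigma+
  cfg2 <- small_config(snr_b0 = Inf, snr_dw = Inf, fwhm_mm = 0)
  cfg2$D_sim <- 2 * cfg$D_sim
  ph2 <- synthesize_phantom(truth$sigma, cfg2)
  fit3 <- estimate_lpf(ph2$dwi, ph2$scheme, ph2$affine, mask = truth$mask,
                       dw = cfg2$D_sim, smooth_fwhm_mm = 0)
  c3 <- vapply(fit3$model$elements, `[[`, numeric(16), "coefficients")
  expect_equal(c1, c3, tolerance = 1e-6)
})

test_that("evaluation on a shifted grid samples the shifted field", {
  # constant + linear-in-z element: analytic shift oracle
  frame <- sh_frame(R_ref_mm = 150)
  cf_z <- rep(0, 16); cf_z[1] <- 0.01; cf_z[3] <- 0.3  # l1m0 column is z
  elements <- lapply(1:6, function(e) sh_coefficients(rep(0, 16),
                                                      frame = frame))
  names(elements) <- c("xx", "xy", "yy", "xz", "yz", "zz")
  elements$zz <- sh_coefficients(cf_z, frame = frame)
  model <- lpf_model(elements, 1.6e-3)
  dim3 <- c(8, 8, 8)
  aff1 <- lpfdti:::centered_affine(dim3, 4)
  aff2 <- aff1; aff2[3, 4] <- aff2[3, 4] + 30
  f1 <- evaluate_lpf(model, dim3, aff1)
  f2 <- evaluate_lpf(model, dim3, aff2)
  # zz element at shifted grid = original + 0.3 * 30/150
  expect_equal(f2$data[, , , 6], f1$data[, , , 6] + 0.3 * 30 / 150,
               tolerance = 1e-12)
  expect_equal(f2$data[, , , 1], f1$data[, , , 1])
})

test_that("LPF models survive a JSON round trip", {
  cfg <- small_config(snr_b0 = Inf, snr_dw = Inf, fwhm_mm = 0)
  truth <- random_lpf(cfg, seed = 10)
  model <- lpf_model(truth$coefficients, cfg$D_sim)
  path <- withr::local_tempfile(fileext = ".json")
  write_lpf_model(model, path)
  back <- read_lpf_model(path)
  expect_equal(back$order, model$order)
  expect_equal(back$D_w, model$D_w)
  expect_equal(back$frame$R_ref_mm, model$frame$R_ref_mm)
  for (nm in names(model$elements)) {
    expect_equal(back$elements[[nm]]$coefficients,
                 model$elements[[nm]]$coefficients)
  }
  pts <- matrix(runif(30, -50, 50), 10, 3)
  expect_equal(evaluate_field(back$elements$xy, pts),
               evaluate_field(model$elements$xy, pts))
})
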