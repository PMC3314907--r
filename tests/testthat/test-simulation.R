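test_that("random fields honour the peak-to-peak normalization", {
  cfg <- small_config()
  truth <- random_lpf(cfg, seed = 61)
  rows <- lpfdti:::field_rows(truth$sigma)
  ptp <- apply(rows, 2, function(v) diff(range(v)))
  expect_equal(max(ptp), cfg$amplitude, tolerance = 1e-12)
  expect_true(all(ptp <= cfg$amplitude + 1e-12))

  cfg_pe <- small_config(ptp_per_element = TRUE)
  rows_pe <- lpfdti:::field_rows(random_lpf(cfg_pe, seed = 61)$sigma)
  ptp_pe <- apply(rows_pe, 2, function(v) diff(range(v)))
  expect_equal(ptp_pe, rep(cfg$amplitude, 6), tolerance = 1e-12)

  zero <- random_lpf(small_config(amplitude = 0), seed = 61)
  expect_true(all(lpfdti:::field_rows(zero$sigma) == 0))
})

test_that("the field draw is deterministic under a seed", {
  cfg <- small_config()
  a <- random_lpf(cfg, seed = 63)
  b <- random_lpf(cfg, seed = 63)
  expect_identical(a$sigma$data, b$sigma$data)
  expect_identical(vapply(a$coefficients, `[[`, numeric(16), "coefficients"),
                   vapply(b$coefficients, `[[`, numeric(16), "coefficients"))
})

test_that("noiseless signals follow the perturbed Stejskal-Tanner form", {
  cfg <- small_config(amplitude = 0, snr_b0 = Inf, snr_dw = Inf)
  truth <- random_lpf(cfg, seed = 65)
  ph <- synthesize_phantom(truth$sigma, cfg)
  inside <- which(truth$mask, arr.ind = TRUE)[1, ]
  dwi_idx <- which(ph$scheme$dwi)
  s0 <- ph$dwi[inside[1], inside[2], inside[3], 1]
  sdw <- ph$dwi[inside[1], inside[2], inside[3], dwi_idx[1]]
  expect_equal(sdw / s0, 1 / 5, tolerance = 1e-12)

  # uniform Sigma = 0.05 I scales the b-value by |g*|^2 = 1.05^2
  sig_rows <- matrix(rep(0.05 * c(1, 0, 1, 0, 0, 1), each = prod(cfg$dim3)),
                     ncol = 6)
  sfield <- tensor_field(array(sig_rows, c(cfg$dim3, 6)), cfg$affine,
                         truth$mask)
  ph2 <- synthesize_phantom(sfield, cfg)
  s2 <- ph2$dwi[inside[1], inside[2], inside[3], dwi_idx[1]]
  expect_equal(s2 / s0, (1 / 5)^(1.05^2), tolerance = 1e-12)

  # outside the phantom: zero signal without noise
  expect_equal(ph$dwi[1, 1, 1, ], rep(0, ph$scheme$n_volumes))
  # with noise, outside voxels are pure noise at the configured sd
  cfgn <- small_config(amplitude = 0)
  phn <- synthesize_phantom(truth$sigma, cfgn, seed = 66)
  outside <- phn$dwi[1, 1, 1:3, 1:cfgn$n_b0]
  expect_true(sd(outside) > 0)
})

test_that("Gaussian smoothing has the right width and conserves intensity", {
  vx <- 2.3
  vol <- array(0, c(31, 31, 31))
  expect_identical(gaussian_smooth(vol + 2.5, 5, vx), vol + 2.5)
  vol[16, 16, 16] <- 1
  sm <- gaussian_smooth(vol, 5, vx)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  profile <- sm[, 16, 16]
  half <- max(profile) / 2
  above <- which(profile >= half)
  fwhm_vox <- (max(above) - min(above) + 1)
  expect_lt(abs(fwhm_vox * vx - 5), vx)   # measured FWHM within one voxel
  expect_identical(gaussian_smooth(vol, 0, vx), vol)
  # 4-D smoothing applies per volume
  v4 <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  s4 <- gaussian_smooth(v4, 5, vx)
  expect_equal(s4[, , , 1], gaussian_smooth(v4[, , , 1], 5, vx))
})

test_that("delta-epsilon follows its closed forms", {
  cfg <- small_config()
  truth <- random_lpf(cfg, seed = 67)
  expect_true(all(delta_epsilon(truth$sigma, truth$sigma) == 0))
  alpha <- 0.3
  scaled <- tensor_field(truth$sigma$data * (1 + alpha),
                         truth$sigma$affine, truth$sigma$mask)
  de <- delta_epsilon(truth$sigma, scaled)
  expect_equal(max(abs(de - alpha / (1 + alpha / 2))), 0, tolerance = 1e-12)
  # scale-free: multiplying both fields leaves it unchanged
  t2 <- tensor_field(truth$sigma$data * 5, truth$sigma$affine,
                     truth$sigma$mask)
  s2 <- tensor_field(scaled$data * 5, scaled$affine, scaled$mask)
  expect_equal(delta_epsilon(t2, s2), de, tolerance = 1e-12)
  # both-zero elements give 0
  z <- tensor_field(truth$sigma$data * 0, truth$sigma$affine,
                    truth$sigma$mask)
  expect_true(all(delta_epsilon(z, z) == 0))
})

test_that("the per-voxel metric reads higher than the ratio-of-means form", {
  # sensitivity of the precision metric to its normalization: the
  # ratio-of-means alternative down-weights zero-crossing regions and
  # reads substantially lower on the same estimates
  cfg <- small_config()
  truth <- random_lpf(cfg, seed = 69)
  ph <- synthesize_phantom(truth$sigma, cfg)
  fit <- estimate_lpf(ph$dwi, ph$scheme, ph$affine, mask = "auto",
                      dw = cfg$D_sim)
  est <- evaluate_lpf(fit$model, cfg$dim3, cfg$affine, fit$mask)
  m <- fit$mask & truth$mask
  t_ <- lpfdti:::field_rows(truth$sigma, masked = FALSE)[as.vector(m), ]
  e_ <- lpfdti:::field_rows(est, masked = FALSE)[as.vector(m), ]
  per_voxel <- colMeans(abs(t_ - e_) / ((abs(t_) + abs(e_)) / 2))
  ratio_of_means <- colMeans(abs(t_ - e_)) / colMeans((abs(t_) + abs(e_)) / 2)
  expect_true(all(per_voxel > ratio_of_means))
  expect_gt(median(per_voxel / ratio_of_means), 1.5)
  # and delta_epsilon() reports the per-voxel form
  de <- delta_epsilon(truth$sigma, est, m)
  expect_equal(lpfdti:::mat_to_lt6(de), per_voxel, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the Monte-Carlo study is seed-deterministic", {
  cfg <- small_config()
  mc1 <- monte_carlo(2, cfg, seed = 71)
  mc2 <- monte_carlo(2, cfg, seed = 71)
  expect_identical(mc1$per_trial, mc2$per_trial)
  expect_equal(nrow(mc1$per_trial), 2 * 6)
  expect_length(mc1$failures, 0)
})

test_that("estimation error shrinks as the DW signal-to-noise ratio rises", {
  de_at <- function(snr) {
    monte_carlo(3, small_config(snr_dw = snr), seed = 73)$summary
  }
  lo <- de_at(10); hi <- de_at(40)
  expect_lt(hi[["diagonal"]], lo[["diagonal"]])
  expect_lt(hi[["off_diagonal"]], lo[["off_diagonal"]])
})

test_that("noiseless unsmoothed error scales quadratically with amplitude", {
  floor_at <- function(amp) {
    cfg <- small_config(amplitude = amp, snr_b0 = Inf, snr_dw = Inf,
                        fwhm_mm = 0)
    truth <- random_lpf(cfg, seed = 77)
    ph <- synthesize_phantom(truth$sigma, cfg)
    fit <- estimate_lpf(ph$dwi, ph$scheme, ph$affine, mask = truth$mask,
                        dw = cfg$D_sim, smooth_fwhm_mm = 0)
    est <- evaluate_lpf(fit$model, cfg$dim3, cfg$affine, truth$mask)
    max(abs(lpfdti:::field_rows(est) - lpfdti:::field_rows(truth$sigma)))
  }
  e1 <- floor_at(0.1)
  e2 <- floor_at(0.05)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})
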