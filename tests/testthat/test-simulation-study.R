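test_that("the parametric AIF is a plausible input function", {
  tt <- default_time_grid()
  cp <- generate_aif(aif_params(), tt)
  expect_true(all(cp$value >= 0))
  peak_i <- which.max(cp$value)
  expect_lt(tt[peak_i], 2)                      # bolus peak in the first 2 min
  expect_lt(cp$value[1] / max(cp$value), 0.1)   # near zero at t = 0
  expect_lt(cp$value[length(tt)] / max(cp$value), 0.1)  # mostly washed out
  # single global maximum: non-increasing after the peak
  expect_true(all(diff(cp$value[peak_i:length(tt)]) <= 1e-9 * max(cp$value)))

  # linear in the amplitudes
  p <- aif_params()
  p2 <- aif_params(bolus_amp = 2 * p$bolus_amp,
                   washout_amp1 = 2 * p$washout_amp1,
                   washout_amp2 = 2 * p$washout_amp2)
  expect_equal(generate_aif(p2, tt)$value, 2 * cp$value, tolerance = 1e-12)

  zero <- aif_params(bolus_amp = 0, washout_amp1 = 0, washout_amp2 = 0)
  expect_true(all(generate_aif(zero, tt)$value == 0))

  expect_error(aif_params(bolus_amp = -1), "negative")
})

test_that("volume-fraction sampling respects ranges and the closure", {
  vfs <- sample_volume_fractions(1e5, seed = 0)
  expect_true(all(vfs$vb >= 0.04 & vfs$vb <= 0.12))
  expect_true(all(vfs$vEES >= 0.25 & vfs$vEES <= 0.45))
  expect_true(all(vfs$vEIS >= 0.43 & vfs$vEIS <= 0.71))
  expect_equal(rowSums(vfs), rep(1, nrow(vfs)))
  # law of large numbers against the uniform means
  expect_lt(abs(mean(vfs$vb) - 0.08), 0.002)
  expect_lt(abs(mean(vfs$vEES) - 0.35), 0.002)
  expect_error(sample_volume_fractions(2), "at least 3")
  expect_error(sample_volume_fractions(10, vb_range = c(0.5, 0.6),
                                       vees_range = c(0.5, 0.6)), "vEIS")
})

test_that("sqrt-scaled noise has the stated per-point standard deviation", {
  tt <- test_grid(5, 0.5)
  x <- tac(tt, rep(100, length(tt)))
  expect_identical(add_tissue_noise(x, 0), x)

  # zero concentration -> zero noise SD -> sample unchanged
  xz <- tac(tt, c(0, rep(100, length(tt) - 1)))
  noisy <- add_tissue_noise(xz, 10, seed = 3)
  expect_equal(noisy$value[1], 0)

  # m * sqrt(100) = 100: sample SD of many draws within 1%
  big <- tac(seq(0, 1e5 - 1), rep(100, 1e5))
  noisy_big <- add_tissue_noise(big, 10, seed = 1)
  expect_lt(abs(stats::sd(noisy_big$value - 100) - 100) / 100, 0.01)

  expect_error(add_tissue_noise(x, -1), ">= 0")
  expect_error(add_tissue_noise(tac(tt, rep(-1, length(tt))), 1),
               "non-negative")
})

test_that("volume-fraction perturbation honours the 95% CI and the closure", {
  vfs <- sample_volume_fractions(25, seed = 2)
  expect_equal(perturb_volume_fractions(vfs, 0), vfs)

  one <- data.frame(vb = rep(0.08, 1e5), vEES = rep(0.35, 1e5))
  pert <- perturb_volume_fractions(one, 10, seed = 4)
  # ~95% of draws within +/-10% of the assigned vb
  cover <- mean(abs(pert$vb - 0.08) <= 0.1 * 0.08)
  expect_lt(abs(cover - 0.95), 0.01)
  expect_equal(pert$vb + pert$vEES + pert$vEIS, rep(1, 1e5))
  expect_true(all(pert$vb > 0 & pert$vEES > 0 & pert$vEIS > 0))

  expect_error(perturb_volume_fractions(vfs, 100), "error_pct")
})

test_that("zero-noise sweep cells are exact end-to-end", {
  cfg <- study_config(n_realizations = 3, noise_multipliers = 0, seed = 5)
  res <- run_noise_sweep(cfg)
  expect_equal(nrow(res), 3)
  expect_true(all(abs(res$ccc_cb - 1) < 1e-9))
  expect_true(all(abs(res$ccc_cees - 1) < 1e-9))
  expect_true(all(abs(res$ccc_ceis - 1) < 1e-9))
  expect_true(all(res[, c("err_K1_pct", "err_k2_pct",
                          "err_k3_pct", "err_k4_pct")] < 0.5))
})

test_that("sweeps have the expected shape and are bit-reproducible", {
  cfg <- study_config(n_realizations = 4, noise_multipliers = c(1, 20),
                      fit = FALSE, seed = 17)
  res1 <- run_noise_sweep(cfg)
  res2 <- run_noise_sweep(cfg)
  expect_equal(nrow(res1), 2 * 4)
  expect_identical(as.data.frame(res1), as.data.frame(res2))

  cfg_d <- study_config(n_realizations = 3, dce_error_levels = c(0, 5, 10, 15),
                        fit = FALSE, seed = 18)
  resd <- run_dce_error_sweep(cfg_d)
  expect_equal(nrow(resd), 4 * 3)
  # different seed -> different noise draws
  resd2 <- run_dce_error_sweep(study_config(n_realizations = 3,
                                            dce_error_levels = c(0, 5, 10, 15),
                                            fit = FALSE, seed = 19))
  expect_false(identical(resd$ccc_cb, resd2$ccc_cb))
})

test_that("realization truth is shared across conditions within a sweep", {
  cfg <- study_config(n_realizations = 3, noise_multipliers = c(0, 30),
                      fit = FALSE, seed = 23)
  res <- run_noise_sweep(cfg)
  a <- res[res$noise_multiplier == 0, c("K1_true", "k2_true", "k3_true", "k4_true")]
  b <- res[res$noise_multiplier == 30, c("K1_true", "k2_true", "k3_true", "k4_true")]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("mean CCC degrades monotonically with the noise multiplier", {
  cfg <- study_config(n_realizations = 30,
                      noise_multipliers = c(0, 1, 10, 20, 50),
                      fit = FALSE, seed = 29)
  res <- run_noise_sweep(cfg)
  for (col in c("ccc_cb", "ccc_cees", "ccc_ceis")) {
    m <- tapply(res[[col]], res$noise_multiplier, mean)
    m <- m[order(as.numeric(names(m)))]
    # one-sided slack for Monte-Carlo jitter
    expect_true(all(diff(m) < 0.02))
  }
})

test_that("the DCE-error sweep at 0% matches a noise-sweep cell", {
  cfg_n <- study_config(n_realizations = 10, noise_multipliers = 1,
                        fit = FALSE, seed = 31)
  cfg_d <- study_config(n_realizations = 10, dce_error_levels = 0,
                        noise_multiplier_fixed = 1, fit = FALSE, seed = 31)
  res_n <- run_noise_sweep(cfg_n)
  res_d <- run_dce_error_sweep(cfg_d)
  # same master seed, same stream layout: identical cells
  expect_equal(res_n$ccc_cb, res_d$ccc_cb)
  expect_equal(res_n$ccc_ceis, res_d$ccc_ceis)
})

test_that("increasing DCE error degrades the blood-curve CCC", {
  cfg <- study_config(n_realizations = 40, dce_error_levels = c(0, 15),
                      fit = FALSE, seed = 37)
  res <- run_dce_error_sweep(cfg)
  m0 <- mean(res$ccc_cb[res$dce_error_pct == 0])
  m15 <- mean(res$ccc_cb[res$dce_error_pct == 15])
  expect_lt(m15, m0)
})

test_that("the EIS curve is the least noise-affected compartment", {
  cfg <- study_config(n_realizations = 40, noise_multipliers = 20,
                      fit = FALSE, seed = 41)
  res <- run_noise_sweep(cfg)
  expect_gt(mean(res$ccc_ceis), mean(res$ccc_cb))
})

test_that("single-realization runner returns a coherent record", {
  cfg <- study_config(n_realizations = 1, seed = 43)
  out <- run_single_realization(cfg, noise_multiplier = 1, dce_error_pct = 5)
  expect_s3_class(out$separated, "compartment_tacs")
  expect_true(all(abs(out$ccc) <= 1))
  expect_s3_class(out$fit, "fit_result")
  # reproducible
  out2 <- run_single_realization(cfg, noise_multiplier = 1, dce_error_pct = 5)
  expect_identical(out$ccc, out2$ccc)
})

test_that("the eight reference parameter combinations are a 2^3 factorial", {
  pc <- param_combinations()
  expect_equal(nrow(pc), 8)
  expect_equal(nrow(unique(pc)), 8)
  expect_setequal(unique(pc$K1), c(0.15, 0.4))
  expect_setequal(unique(pc$k2), c(0.25, 0.75))
  expect_setequal(unique(pc$k3), c(0.08, 0.2))
  expect_equal(unique(pc$k4), 0.1)
  # every combination is a valid parameter set exercised by the sweeps
  for (i in seq_len(8)) {
    expect_s3_class(pet_params(pc$K1[i], pc$k2[i], pc$k3[i], pc$k4[i]),
                    "pet_params")
  }
})
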