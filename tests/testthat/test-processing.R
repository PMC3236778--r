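test_that("windowed BM reproduces hand-computed variances", {
  # alternating 0,1 nm in x over each 20-frame window, constant y:
  # population variance 0.25 nm^2, BM = sqrt(0.25/2)
  n <- 100
  tr <- structure(list(bead_id = "hand", times = (0:(n - 1)) / 30,
                       x = rep(c(0, 1), n / 2), y = rep(5, n),
                       recorded = rep(TRUE, n), frame_rate = 30,
                       duration = n / 30, truth = NULL),
                  class = "tpm_trajectory")
  s <- bm_series(tr, window_frames = 20, stride = 20)
  expect_equal(s$bm, rep(sqrt(0.25 / 2), 5), tolerance = 1e-12)
  # constant positions give zero BM
  tr$x <- rep(2, n); tr$y <- rep(-3, n)
  expect_equal(bm_series(tr, 20, 20)$bm, rep(0, 5), tolerance = 1e-12)
  expect_error(bm_series(tr, window_frames = 1), ">= 2")
})

test_that("BM is invariant to rigid translation and axis exchange", {
  cfg <- quiet_config(duration = 40, seed = 13, p_unwind = 0)
  tr <- simulate_trajectory(cfg, unwind = FALSE)
  s0 <- bm_series(tr, stride = 20)
  tr_shift <- tr; tr_shift$x <- tr$x + 100; tr_shift$y <- tr$y - 50
  expect_equal(bm_series(tr_shift, stride = 20)$bm, s0$bm)
  tr_swap <- tr; tr_swap$x <- tr$y; tr_swap$y <- tr$x
  expect_equal(bm_series(tr_swap, stride = 20)$bm, s0$bm)
})

test_that("windows touching unrecorded frames are skipped", {
  cfg <- quiet_config(duration = 40, seed = 21, p_unwind = 0, dead_time = 10)
  tr <- simulate_trajectory(cfg, unwind = FALSE)
  s <- bm_series(tr, stride = 1)
  expect_true(min(s$times) >= 10)
  # puncture a hole mid-trace: windows overlapping it must vanish
  hole <- tr$times >= 20 & tr$times < 21
  tr$recorded[hole] <- FALSE; tr$x[hole] <- NA; tr$y[hole] <- NA
  s2 <- bm_series(tr, stride = 1)
  expect_false(any(s2$times > 19.8 & s2$times < 21.1))
})

test_that("drift correction removes linear drift without touching BM", {
  cfg <- quiet_config(duration = 80, seed = 17, p_unwind = 0)
  clean <- simulate_trajectory(cfg, unwind = FALSE)
  cfg_d <- cfg; cfg_d$drift_nm_s <- 0.5
  cfg_d$seed <- 17 # same noise stream, drift added on top
  drifted <- simulate_trajectory(cfg_d, unwind = FALSE)
  bm_clean <- mean(bm_series(clean, stride = 20)$bm)
  bm_raw <- mean(bm_series(drifted, stride = 20)$bm)
  bm_corr <- mean(bm_series(correct_drift(drifted), stride = 20)$bm)
  expect_equal(bm_corr, bm_clean, tolerance = 0.03)
  # near-identity on drift-free data
  bm_corr0 <- mean(bm_series(correct_drift(clean), stride = 20)$bm)
  expect_equal(bm_corr0, bm_clean, tolerance = 0.01)
  # pure deterministic motion is removed almost entirely
  pure <- clean
  pure$x <- 0.5 * pure$times; pure$y <- -0.2 * pure$times
  pure$x[!pure$recorded] <- NA; pure$y[!pure$recorded] <- NA
  bm_pure <- mean(bm_series(correct_drift(pure), stride = 20)$bm)
  expect_lt(bm_pure, 0.05)
  expect_error(correct_drift(clean, drift_window_s = 1000), "shorter")
})

test_that("symmetry filter applies the closed 0.9-1.1 ratio interval", {
  cfg <- quiet_config(duration = 60, seed = 23, p_unwind = 0)
  tr <- simulate_trajectory(cfg, unwind = FALSE)
  # engineered exact ratios via scaling of one axis
  q0 <- qc_symmetry(tr, 1000)
  tr_edge <- tr
  tr_edge$x <- tr$x * sqrt(1.1 / q0$ratio)
  expect_true(qc_symmetry(tr_edge, 1000)$symmetric)   # ratio exactly 1.1
  tr_out <- tr
  tr_out$x <- tr$x * sqrt(1.15 / q0$ratio)
  expect_false(qc_symmetry(tr_out, 1000)$symmetric)   # ratio 1.15
  expect_error(qc_symmetry(tr, 1e6), "recorded frames")
})

test_that("anisotropic beads are rejected far more often than isotropic", {
  iso <- 0; aniso <- 0; n <- 60
  for (i in seq_len(n)) {
    cfg <- quiet_config(duration = 55, seed = 400 + i, p_unwind = 0)
    iso <- iso + qc_symmetry(simulate_trajectory(cfg, unwind = FALSE,
                                                 asym = FALSE), 1000)$symmetric
    aniso <- aniso + qc_symmetry(simulate_trajectory(cfg, unwind = FALSE,
                                                     asym = TRUE), 1000)$symmetric
  }
  expect_equal(aniso, 0)  # 2:1 variance ratio always fails
  expect_gt(iso / n, 0.5)      # isotropic beads mostly pass
})

test_that("population BM recovers the cohort Gaussian parameters", {
  # intact fork cohort conditions
  cfgF <- tpm_config(duration = 55, sigma0 = 9.90, sigma0_sd = 2.18,
                     p_unwind = 0, p_pause = 0, seed = 61)
  pf <- population_bm(simulate_cohort(cfgF, 66))
  expect_lt(abs(pf$mean - 9.90), 2 * 2.18 / sqrt(66))
  # mimicked-unwound cohort conditions
  cfgM <- tpm_config(duration = 55, sigma0 = 15.00, sigma0_sd = 4.23,
                     p_unwind = 0, p_pause = 0, seed = 62)
  pm <- population_bm(simulate_cohort(cfgM, 57))
  expect_lt(abs(pm$mean - 15.00), 2 * 4.23 / sqrt(57))
  expect_gt(pm$sd, pf$sd) # the unwound-state distribution is broader
})

test_that("identical beads give a degenerate population", {
  cfg <- quiet_config(duration = 55, seed = 71, p_unwind = 0)
  tr <- simulate_trajectory(cfg, unwind = FALSE)
  p <- population_bm(list(tr, tr), qc = FALSE)
  expect_true(p$degenerate)
  expect_identical(p$sd, 0)
  expect_error(population_bm(list(tr)), "at least 2")
})

test_that("calibration is the BM difference over the duplex difference", {
  cal <- bm_calibration(9.90, 15.00, 71)
  expect_equal(cal$c, (15.00 - 9.90) / 71, tolerance = 1e-12)
  expect_equal(round(cal$c, 4), 0.0718)
  expect_equal(bm_calibration(10.0, 17.1, 71)$c, 0.1, tolerance = 1e-12)
  expect_identical(bm_calibration(12, 12, 71)$c, 0)
  expect_error(bm_calibration(9.9, 15.0, 0), "delta_bp")
  expect_warning(bm_calibration(15.0, 9.9, 71), "negative")
})
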