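test_that("a noiseless step is localized to one window", {
  tt <- seq(20, 220, by = 2 / 3)
  bm <- ifelse(tt < 150, 5, 10)
  s <- make_series(tt, bm)
  d <- detect_unwind_start(s)
  expect_true(d$detected)
  expect_lt(abs(d$t_start - 150), 2 / 3 + 1e-9)
})

test_that("a noiseless ramp onset is recovered exactly", {
  tt <- seq(20, 320, by = 2 / 3)
  bm <- 9.9 + 0.0718 * 3.58 * pmax(tt - 250, 0)
  s <- make_series(tt, bm)
  d <- detect_unwind_start(s)
  expect_true(d$detected)
  expect_lt(abs(d$t_start - 250), 2 / 3 + 1e-9)
})

test_that("onset detection is accurate on simulated unwinding traces", {
  errs <- c()
  for (i in 1:10) {
    cfg <- quiet_config(v_bp_s = 3.58, seed = 900 + i, p_unwind = 1)
    tr <- simulate_trajectory(cfg, unwind = TRUE)
    s <- bm_series(correct_drift(tr), stride = 20)
    d <- detect_unwind_start(s)
    expect_true(d$detected)
    errs <- c(errs, d$t_start - tr$truth$t_start)
  }
  expect_lt(mean(abs(errs)), 5)
  # error well below 10 windows (6.7 s) on average
  expect_lt(mean(abs(errs)) * 30 / 20, 10)
})

test_that("flat noisy series rarely trigger and short series error", {
  fp <- 0
  for (i in 1:40) {
    cfg <- tpm_config(p_unwind = 0, seed = 1200 + i, asym_frac = 0)
    tr <- simulate_trajectory(cfg, unwind = FALSE)
    fp <- fp + detect_unwind_start(bm_series(correct_drift(tr),
                                             stride = 20))$detected
  }
  expect_lte(fp / 40, 0.10)
  s <- make_series(seq(0, 10, by = 2 / 3), rep(5, 16))
  expect_error(detect_unwind_start(s), "too short")
})

test_that("slope fitting converts nm/s to bp/s via the calibration factor", {
  # ramp constructed directly at slope 0.257 nm/s
  tt <- seq(100, 130, by = 2 / 3)
  s <- make_series(tt, 9.9 + 0.257 * (tt - 100))
  sl <- fit_velocity_slope(s, 100, 130, 0.0718)
  expect_equal(sl$slope, 0.257, tolerance = 1e-9)
  expect_equal(sl$v_slope, 0.257 / 0.0718, tolerance = 1e-9)
  expect_equal(sl$v_slope, 3.58, tolerance = 0.005)
  # zero slope
  s0 <- make_series(tt, rep(9.9, length(tt)))
  expect_equal(fit_velocity_slope(s0, 100, 130, 0.0718)$v_slope, 0,
               tolerance = 1e-12)
  # noiseless synthetic ramp at the helicase-primase velocity
  s2 <- make_series(tt, 9.9 + 0.0718 * 7.44 * (tt - 100))
  expect_equal(fit_velocity_slope(s2, 100, 130, 0.0718)$v_slope, 7.44,
               tolerance = 0.01)
  expect_error(fit_velocity_slope(s, 100, 130, 0), "c_nm_bp")
  expect_error(fit_velocity_slope(s, 100, 101, 0.0718), "fewer than 5")
})

test_that("dwell velocity is duplex length over dwell time", {
  expect_equal(velocity_dwell(90, 100, 125), 3.6)
  expect_equal(velocity_dwell(90, 100, 112.1), 90 / 12.1)
  expect_equal(round(velocity_dwell(90, 0, 12.1), 2), 7.44)
  expect_error(velocity_dwell(90, 100, 100), "t_max")
})

test_that("pauses are flagged and monotone ramps are not", {
  flagged <- 0; n_detected <- 0; mono <- 0; mono_n <- 0
  for (i in 1:15) {
    cfg <- quiet_config(v_bp_s = 3.58, seed = 1500 + i, p_unwind = 1)
    trp <- simulate_trajectory(cfg, unwind = TRUE, pause = TRUE)
    fp <- unwind_fit(bm_series(correct_drift(trp), stride = 20))
    if (fp$detected && fp$qualifies) {
      n_detected <- n_detected + 1
      flagged <- flagged + fp$paused
    }
    trm <- simulate_trajectory(cfg, unwind = TRUE, pause = FALSE)
    fm <- unwind_fit(bm_series(correct_drift(trm), stride = 20))
    if (fm$detected && fm$qualifies) {
      mono_n <- mono_n + 1
      mono <- mono + fm$paused
    }
  }
  expect_gt(flagged / n_detected, 0.6)  # inserted 30 s pauses are caught
  expect_lt(mono / mono_n, 0.2)         # monotone ramps stay unflagged
})

test_that("qualification requires dissociation with increasing BM", {
  # unwinding trace qualifies
  cfg <- quiet_config(v_bp_s = 3.58, seed = 1601, p_unwind = 1)
  tr <- simulate_trajectory(cfg, unwind = TRUE)
  expect_true(qualify_event(bm_series(correct_drift(tr), stride = 20)))
  # persisting bead does not
  trs <- simulate_trajectory(cfg, unwind = FALSE)
  expect_false(qualify_event(bm_series(correct_drift(trs), stride = 20)))
  # abrupt detachment with flat BM does not
  trd <- simulate_trajectory(cfg, unwind = FALSE)
  cut <- trd$times > 300
  trd$x[cut] <- NA; trd$y[cut] <- NA; trd$recorded[cut] <- FALSE
  expect_false(qualify_event(bm_series(correct_drift(trd, 10), stride = 20)))
})

test_that("slope and dwell estimators agree on simulated molecules", {
  vs <- c(); vd <- c()
  for (i in 1:20) {
    cfg <- quiet_config(v_bp_s = 7.44, seed = 1700 + i, p_unwind = 1)
    tr <- simulate_trajectory(cfg, unwind = TRUE)
    f <- unwind_fit(bm_series(correct_drift(tr), stride = 20))
    if (f$detected && f$qualifies && is.finite(f$v_slope)) {
      vs <- c(vs, f$v_slope); vd <- c(vd, f$v_dwell)
    }
  }
  expect_gt(length(vs), 15)
  expect_lt(abs(mean(vs) / mean(vd) - 1), 0.1)
  expect_lt(abs(mean(vs) / 7.44 - 1), 0.15)
})

test_that("unwind_fit methods are coherent", {
  cfg <- quiet_config(v_bp_s = 3.58, seed = 1801, p_unwind = 1)
  tr <- simulate_trajectory(cfg, unwind = TRUE)
  s <- bm_series(correct_drift(tr), stride = 20)
  f <- unwind_fit(s)
  expect_s3_class(f, "unwind_fit")
  cf <- coef(f)
  expect_named(cf, c("t_start", "t_max", "slope", "v_slope", "v_dwell"))
  expect_true(cf["t_max"] > cf["t_start"])
  # prediction is the baseline before onset, the ramp after
  pr <- predict(f, times = c(f$t_start - 50, f$t_start + 5))
  expect_equal(pr[1], f$baseline_bm)
  expect_gt(pr[2], pr[1])
  expect_length(residuals(f), length(s$bm))
  expect_output(print(f), "v\\(slope\\)")
  expect_output(summary(f), "dwell method")
})

test_that("event tables and velocity extraction respect exclusions", {
  cfg <- tpm_config(v_bp_s = 3.58, p_unwind = 0.5, seed = 1901,
                    duration = 450, t_bind_range = c(130, 280))
  co <- simulate_cohort(cfg, 10)
  ev <- unwind_events(co)
  expect_named(ev, c("bead_id", "t_start_s", "t_max_s", "slope_nm_s",
                     "v_slope_bp_s", "v_dwell_bp_s", "paused", "qualifies"))
  expect_identical(nrow(ev), 10L)
  v <- cohort_velocities(ev)
  expect_true(all(v > 0))
  expect_lte(length(v), sum(ev$qualifies))
})
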