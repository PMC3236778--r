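#' Simulation settings for synthetic smTPM recordings
#'
#' Collects the parameters of the tethered-bead simulator. Defaults reproduce
#' the recording conditions of the smTPM unwinding experiments: 30 Hz imaging,
#' a ~20 s recording dead time after solution exchange, a fork substrate whose
#' intact Brownian-motion (BM) amplitude is 9.90 nm on average with a
#' bead-to-bead spread of 2.18 nm, a BM-per-base-pair conversion of
#' 0.0718 nm/bp over a 90 bp unwindable duplex, unwinding initiating uniformly
#' 100-300 s after the dead time (the baseline stays flat for >100 s), a 17%
#' chance that a given tether is unwound during the recording, and a <10%
#' chance of a pre-release pause.
#'
#' @param frame_rate Frames per second (Hz).
#' @param duration Recording length (s).
#' @param sigma0 Mean per-axis baseline fluctuation amplitude (nm) of the
#'   intact substrate; equals the baseline scalar BM amplitude.
#' @param sigma0_sd Bead-to-bead standard deviation of the baseline amplitude
#'   (nm); per-bead baselines are drawn from a normal truncated at 1 nm.
#' @param c_nm_bp BM increase per unwound base pair (nm/bp).
#' @param tau Relaxation time (s) of the bead position process. Free parameter
#'   of the motion model; windows used downstream are long relative to it.
#' @param v_bp_s True unwinding velocity (bp/s).
#' @param unwindable_bp Unwindable duplex length (bp).
#' @param dead_time Initial recording dead time (s); frames are flagged
#'   unrecorded but time spacing stays uniform.
#' @param t_bind_range Range (s) of the uniform distribution of unwinding
#'   start times.
#' @param p_unwind Probability that a tether is unwound during the recording.
#' @param drift_nm_s Slow stage drift speed (nm/s); direction is random per
#'   bead.
#' @param p_pause Probability that an unwinding tether pauses before release.
#' @param pause_dur Pause duration (s).
#' @param asym_frac Fraction of beads with anisotropic (2:1 axis-variance)
#'   motion, emulating multiply-tethered or stuck beads.
#' @param seed Optional integer seed; when set, simulation calls are
#'   reproducible bit-for-bit.
#'
#' @return An object of class `tpm_config` (a validated list).
#' @export
tpm_config <- function(frame_rate = 30, duration = 600, sigma0 = 9.90,
                       sigma0_sd = 2.18, c_nm_bp = 0.0718, tau = 0.05,
                       v_bp_s = 3.58, unwindable_bp = 90, dead_time = 20,
                       t_bind_range = c(dead_time + 100, dead_time + 300),
                       p_unwind = 0.17, drift_nm_s = 0.05, p_pause = 0.08,
                       pause_dur = 30, asym_frac = 0.1, seed = NULL) {
  cfg <- list(frame_rate = frame_rate, duration = duration, sigma0 = sigma0,
              sigma0_sd = sigma0_sd, c_nm_bp = c_nm_bp, tau = tau,
              v_bp_s = v_bp_s, unwindable_bp = unwindable_bp,
              dead_time = dead_time, t_bind_range = t_bind_range,
              p_unwind = p_unwind, drift_nm_s = drift_nm_s,
              p_pause = p_pause, pause_dur = pause_dur,
              asym_frac = asym_frac, seed = seed)
  stopifnot(cfg$frame_rate > 0, cfg$duration > 0, cfg$sigma0 > 0,
            cfg$sigma0_sd >= 0, cfg$c_nm_bp >= 0, cfg$tau > 0,
            cfg$v_bp_s >= 0, cfg$unwindable_bp >= 1, cfg$dead_time >= 0,
            length(cfg$t_bind_range) == 2L,
            cfg$t_bind_range[1] <= cfg$t_bind_range[2],
            cfg$p_unwind >= 0, cfg$p_unwind <= 1,
            cfg$p_pause >= 0, cfg$p_pause <= 1,
            cfg$asym_frac >= 0, cfg$asym_frac <= 1)
  structure(cfg, class = "tpm_config")
}

# Base pairs unwound at each time, with an optional mid-course pause.
unwound_at <- function(times, t_start, v, bp, pause = FALSE, pause_at = NA,
                       pause_dur = 0) {
  u <- pmax(times - t_start, 0) * v
  if (pause && v > 0) {
    t_p <- t_start + pause_at / v
    u <- ifelse(times <= t_p, u,
                ifelse(times <= t_p + pause_dur, pause_at,
                       pmin((times - t_p - pause_dur) * v + pause_at, Inf)))
  }
  pmin(u, bp)
}

#' Simulate one tethered-bead centroid trajectory
#'
#' The per-axis centroid follows a stationary mean-reverting Gaussian process
#' (an Ornstein-Uhlenbeck discretisation) with relaxation time `tau` whose
#' instantaneous per-axis standard deviation is `sigma0_bead + c_nm_bp * u(t)`,
#' where `u(t)` is the number of base pairs unwound. With the scalar BM
#' amplitude defined as `sqrt((MSDx + MSDy)/2)` this makes the expected BM
#' amplitude affine in unwound base pairs with slope `c_nm_bp` by
#' construction. Slow stage drift is added along a random direction.
#' When `u` reaches the unwindable duplex length the bead is released and all
#' later frames are flagged unrecorded, as are dead-time frames.
#'
#' @param config A [tpm_config()].
#' @param substrate Optional [anneal()] result; supplies `unwindable_bp`.
#' @param bead_id Identifier stored in the trajectory.
#' @param unwind Logical; does this tether unwind? `NA` draws from
#'   `p_unwind`.
#' @param t_start Unwinding start time (s); `NA` draws from `t_bind_range`.
#' @param asym Logical; anisotropic bead? `NA` draws from `asym_frac`.
#' @param pause Logical; insert a pre-release pause? `NA` draws from
#'   `p_pause` (unwinding tethers only).
#' @param sigma0_bead Per-bead baseline amplitude (nm); `NA` draws from
#'   `N(sigma0, sigma0_sd)` truncated at 1 nm.
#'
#' @return An object of class `tpm_trajectory`: `bead_id`, `times`, `x`, `y`
#'   (nm; `NA` on unrecorded frames), `recorded`, `frame_rate`, `duration`
#'   and a `truth` list (`unwound`, `t_start`, `v_bp_s`, `t_release`, `asym`,
#'   `pause`, `sigma0_bead`).
#' @export
simulate_trajectory <- function(config, substrate = NULL, bead_id = "bead-1",
                                unwind = NA, t_start = NA, asym = NA,
                                pause = NA, sigma0_bead = NA) {
  stopifnot(inherits(config, "tpm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  bp <- if (!is.null(substrate)) substrate$unwindable_bp else config$unwindable_bp
  dt <- 1 / config$frame_rate
  n <- round(config$duration * config$frame_rate)
  times <- (seq_len(n) - 1L) * dt

  if (is.na(unwind)) unwind <- runif(1) < config$p_unwind
  if (is.na(asym)) asym <- runif(1) < config$asym_frac
  if (is.na(pause)) pause <- unwind && runif(1) < config$p_pause
  if (is.na(sigma0_bead))
    sigma0_bead <- max(1, rnorm(1, config$sigma0, config$sigma0_sd))

  if (unwind && config$v_bp_s > 0) {
    if (is.na(t_start))
      t_start <- runif(1, config$t_bind_range[1], config$t_bind_range[2])
    pause_at <- if (pause) runif(1, 0.3, 0.8) * bp else NA
    u <- unwound_at(times, t_start, config$v_bp_s, bp, pause, pause_at,
                    config$pause_dur)
    t_release <- t_start + bp / config$v_bp_s +
      if (pause) config$pause_dur else 0
  } else {
    unwind <- FALSE
    pause <- FALSE
    t_start <- NA_real_
    t_release <- Inf
    u <- rep(0, n)
  }

  sdv <- sigma0_bead + config$c_nm_bp * u
  # 2:1 axis-variance anisotropy that preserves the scalar BM amplitude
  fx <- if (asym) sqrt(4 / 3) else 1
  fy <- if (asym) sqrt(2 / 3) else 1
  rho <- exp(-dt / config$tau)
  innov <- sqrt(1 - rho^2) * sdv
  wx <- rnorm(n) * innov * fx
  wy <- rnorm(n) * innov * fy
  # first value drawn from the stationary distribution, then the recursion
  wx[1] <- rnorm(1, 0, sdv[1] * fx)
  wy[1] <- rnorm(1, 0, sdv[1] * fy)
  x <- as.numeric(filter(wx, rho, method = "recursive"))
  y <- as.numeric(filter(wy, rho, method = "recursive"))

  if (config$drift_nm_s > 0) {
    ang <- runif(1, 0, 2 * pi)
    x <- x + cos(ang) * config$drift_nm_s * times
    y <- y + sin(ang) * config$drift_nm_s * times
  }

  recorded <- times >= config$dead_time & times < t_release
  x[!recorded] <- NA_real_
  y[!recorded] <- NA_real_

  structure(list(bead_id = bead_id, times = times, x = x, y = y,
                 recorded = recorded, frame_rate = config$frame_rate,
                 duration = config$duration,
                 truth = list(unwound = unwind, t_start = t_start,
                              v_bp_s = if (unwind) config$v_bp_s else NA_real_,
                              t_release = t_release, asym = asym,
                              pause = pause, sigma0_bead = sigma0_bead)),
            class = "tpm_trajectory")
}

#' @export
print.tpm_trajectory <- function(x, ...) {
  cat("<tpm_trajectory> ", x$bead_id, ": ", length(x$times), " frames @ ",
      x$frame_rate, " Hz, ", sum(x$recorded), " recorded\n", sep = "")
  if (isTRUE(x$truth$unwound))
    cat("  truth: unwinds at ", round(x$truth$t_start, 1), " s, ",
        x$truth$v_bp_s, " bp/s, release ", round(x$truth$t_release, 1),
        " s\n", sep = "")
  invisible(x)
}

#' Simulate a cohort of tethered beads
#'
#' Each tether independently unwinds with probability `p_unwind`; a fraction
#' `asym_frac` of beads move anisotropically (2:1 axis-variance ratio, to
#' exercise the symmetry filter) and a fraction `p_pause` of unwinding tethers
#' pause before release.
#'
#' @param config A [tpm_config()]. Its `seed`, when set, makes the cohort
#'   reproducible.
#' @param n Number of beads.
#' @param substrate Optional substrate passed to [simulate_trajectory()].
#' @param label Prefix for bead identifiers.
#' @return A list of `tpm_trajectory` objects (class `tpm_cohort`).
#' @export
simulate_cohort <- function(config, n, substrate = NULL, label = "bead") {
  stopifnot(inherits(config, "tpm_config"), n >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL
  out <- lapply(seq_len(n), function(i) {
    simulate_trajectory(cfg, substrate = substrate,
                        bead_id = sprintf("%s-%03d", label, i))
  })
  class(out) <- c("tpm_cohort", "list")
  out
}
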