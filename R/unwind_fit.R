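#' Fit a single-molecule unwinding event
#'
#' The central per-trace estimator. Given the BM time course of one tethered
#' bead it (i) checks that the trace qualifies (the bead disappears after a
#' significantly increasing BM section), (ii) detects the unwinding onset with
#' [detect_unwind_start()], (iii) estimates the unwinding velocity both from
#' the least-squares slope of the increasing BM section divided by the
#' calibration factor and from the dwell time between onset and maximum BM,
#' and (iv) flags pre-release pauses, which disqualify a molecule from
#' velocity statistics.
#'
#' @param series A [bm_series()], computed from a drift-corrected trajectory.
#' @param c_nm_bp Calibration factor (nm/bp).
#' @param unwindable_bp Unwindable duplex length (bp) used by the dwell
#'   estimator.
#' @param smooth,gap,persistence Onset-detection settings, see
#'   [detect_unwind_start()].
#' @param plateau_min_s,slope_tol Pause-flagging settings, see [flag_pause()].
#' @param qualify_span_s,qualify_level Qualification settings, see
#'   [qualify_event()].
#' @param window_debias Correct the slope for the finite-window MSD
#'   attenuation (default `TRUE`). Short analysis windows on a correlated
#'   position process systematically underestimate the instantaneous
#'   amplitude; the attenuation factor is estimated from the data as the
#'   ratio of the mean short-window BM to the long-block BM over the same
#'   pre-onset frames, and the fitted slope is divided by it before
#'   conversion to bp/s. The dwell estimator needs no such correction, so
#'   this keeps the two estimators commensurable.
#' @return An object of class `unwind_fit` with fields `bead_id`, `qualifies`,
#'   `detected`, `t_start`, `t_max`, `slope` (nm/s), `v_slope`, `v_dwell`
#'   (bp/s), `paused`, `baseline_bm` (nm), `band`, `c_nm_bp`,
#'   `unwindable_bp` and the input `series`. Supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `residuals()` and `plot()`.
#' @examples
#' cfg <- tpm_config(duration = 400, t_bind_range = c(150, 250), seed = 7,
#'                   drift_nm_s = 0, asym_frac = 0, p_pause = 0)
#' tr <- simulate_trajectory(cfg, unwind = TRUE)
#' fit <- unwind_fit(bm_series(correct_drift(tr), stride = 20))
#' coef(fit)
#' @export
unwind_fit <- function(series, c_nm_bp = 0.0718, unwindable_bp = 90,
                       smooth = 15, gap = 8, persistence = 15,
                       plateau_min_s = 15, slope_tol = NULL,
                       qualify_span_s = 30, qualify_level = 0.05,
                       window_debias = TRUE) {
  stopifnot(inherits(series, "bm_series"))
  qualifies <- qualify_event(series, qualify_span_s, qualify_level)
  onset <- detect_unwind_start(series, smooth = smooth, gap = gap,
                               persistence = persistence)
  out <- list(bead_id = series$bead_id, qualifies = qualifies,
              detected = onset$detected, t_start = onset$t_start,
              t_max = NA_real_, slope = NA_real_, v_slope = NA_real_,
              v_dwell = NA_real_, paused = FALSE,
              baseline_bm = NA_real_, window_bias = NA_real_,
              band = onset$band,
              c_nm_bp = c_nm_bp, unwindable_bp = unwindable_bp,
              series = series)
  if (onset$detected && qualifies) {
    # the bead disappears right after the last recorded frame; that moment,
    # not the center of the last analysis window, is when the maximum BM
    # is reached
    t_max <- series$last_recorded_t
    out$t_max <- t_max
    pre <- series$bm[series$times < onset$t_start]
    out$baseline_bm <- if (length(pre) >= 2) mean(pre) else NA_real_
    # window-attenuation factor from the pre-onset block: short-window BM
    # over long-block BM on the same frames
    wb <- 1
    if (window_debias && !is.null(series$bm_block) &&
        series$block_end_t < onset$t_start) {
      inblk <- series$times <= series$block_end_t
      if (sum(inblk) >= 10 && series$bm_block > 0) {
        wb <- mean(series$bm[inblk]) / series$bm_block
        wb <- min(max(wb, 0.5), 1.5)
      }
    }
    out$window_bias <- wb
    # start the slope section half a window after the onset: windows
    # straddling the onset mix baseline and ramp frames and round the knee
    sl <- try(fit_velocity_slope(series, onset$t_start + series$window_s / 2,
                                 t_max, c_nm_bp),
              silent = TRUE)
    if (inherits(sl, "try-error"))
      sl <- try(fit_velocity_slope(series, onset$t_start, t_max, c_nm_bp),
                silent = TRUE)
    if (!inherits(sl, "try-error")) {
      out$slope <- sl$slope
      out$v_slope <- sl$v_slope / wb
    }
    if (t_max > onset$t_start)
      out$v_dwell <- velocity_dwell(unwindable_bp, onset$t_start, t_max)
    out$paused <- flag_pause(series, onset$t_start, t_max,
                             plateau_min_s = plateau_min_s,
                             slope_tol = slope_tol)
  }
  class(out) <- "unwind_fit"
  out
}

#' @export
print.unwind_fit <- function(x, ...) {
  cat("<unwind_fit> ", x$bead_id, "\n", sep = "")
  if (!x$qualifies) {
    cat("  does not qualify (no dissociation preceded by increasing BM)\n")
  } else if (!x$detected) {
    cat("  qualifies, but no onset detected\n")
  } else {
    cat("  onset ", round(x$t_start, 1), " s, release ", round(x$t_max, 1),
        " s | v(slope) = ", signif(x$v_slope, 3), " bp/s, v(dwell) = ",
        signif(x$v_dwell, 3), " bp/s",
        if (x$paused) " | PAUSED (excluded from statistics)\n" else "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.unwind_fit <- function(object, ...) {
  cat("Single-molecule unwinding fit for", object$bead_id, "\n")
  cat("  qualifies:        ", object$qualifies, "\n")
  cat("  onset detected:   ", object$detected, "\n")
  if (object$detected && object$qualifies) {
    cat("  t_start:          ", round(object$t_start, 2), "s\n")
    cat("  t_max:            ", round(object$t_max, 2), "s\n")
    cat("  baseline BM:      ", signif(object$baseline_bm, 4), "nm\n")
    cat("  BM slope:         ", signif(object$slope, 4), "nm/s\n")
    cat("  v (slope method): ", signif(object$v_slope, 4), "bp/s\n")
    cat("  v (dwell method): ", signif(object$v_dwell, 4), "bp/s\n")
    cat("  paused:           ", object$paused, "\n")
    cat("  calibration:      ", object$c_nm_bp, "nm/bp over",
        object$unwindable_bp, "bp\n")
  }
  invisible(object)
}

#' @export
coef.unwind_fit <- function(object, ...) {
  c(t_start = object$t_start, t_max = object$t_max, slope = object$slope,
    v_slope = object$v_slope, v_dwell = object$v_dwell)
}

#' Predicted BM amplitude under the fitted flat-then-ramp model
#'
#' @param object An `unwind_fit`.
#' @param times Times (s) at which to predict; defaults to the series times.
#' @param ... Unused.
#' @return Predicted BM (nm): baseline level before `t_start`, the fitted
#'   line after.
#' @export
predict.unwind_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$series$times
  if (!object$detected || !object$qualifies || is.na(object$slope))
    stop("no fitted model to predict from")
  b0 <- object$baseline_bm
  ramp <- b0 + object$slope * (times - object$t_start)
  ifelse(times < object$t_start, b0, ramp)
}

#' @export
residuals.unwind_fit <- function(object, ...) {
  object$series$bm - predict(object)
}

#' @export
plot.unwind_fit <- function(x, ...) {
  plot(x$series$times, x$series$bm, type = "l", col = "grey40",
       xlab = "time (s)", ylab = "BM (nm)", main = x$bead_id, ...)
  if (x$detected && x$qualifies && !is.na(x$slope)) {
    lines(x$series$times, predict(x), col = "red", lwd = 2)
    abline(v = x$t_start, lty = 2, col = "red")
    legend("topleft", bty = "n", legend = c(
      sprintf("v(slope) = %.2f bp/s", x$v_slope),
      sprintf("v(dwell) = %.2f bp/s", x$v_dwell)))
  }
  invisible(x)
}

#' Per-molecule unwinding events for a cohort
#'
#' Runs drift correction, BM windowing and [unwind_fit()] over every
#' trajectory and tabulates the per-molecule results in the event-report
#' layout.
#'
#' @param trajs List of `tpm_trajectory` objects.
#' @param c_nm_bp Calibration factor (nm/bp).
#' @param unwindable_bp Unwindable duplex length (bp).
#' @param window_frames,stride BM windowing, see [bm_series()].
#' @param drift_window_s Drift-correction window (s); `NULL` to skip.
#' @param ... Further arguments passed to [unwind_fit()].
#' @return A data frame with columns `bead_id`, `t_start_s`, `t_max_s`,
#'   `slope_nm_s`, `v_slope_bp_s`, `v_dwell_bp_s`, `paused`, `qualifies`.
#' @export
unwind_events <- function(trajs, c_nm_bp = 0.0718, unwindable_bp = 90,
                          window_frames = 20, stride = 20,
                          drift_window_s = 10, ...) {
  rows <- lapply(trajs, function(tr) {
    if (!is.null(drift_window_s)) tr <- correct_drift(tr, drift_window_s)
    ev <- try({
      s <- bm_series(tr, window_frames = window_frames, stride = stride)
      unwind_fit(s, c_nm_bp = c_nm_bp, unwindable_bp = unwindable_bp, ...)
    }, silent = TRUE)
    if (inherits(ev, "try-error")) {
      return(data.frame(bead_id = tr$bead_id, t_start_s = NA_real_,
                        t_max_s = NA_real_, slope_nm_s = NA_real_,
                        v_slope_bp_s = NA_real_, v_dwell_bp_s = NA_real_,
                        paused = FALSE, qualifies = FALSE))
    }
    data.frame(bead_id = ev$bead_id, t_start_s = ev$t_start,
               t_max_s = ev$t_max, slope_nm_s = ev$slope,
               v_slope_bp_s = ev$v_slope, v_dwell_bp_s = ev$v_dwell,
               paused = ev$paused, qualifies = ev$qualifies && ev$detected)
  })
  do.call(rbind, rows)
}

#' Velocity list of the qualifying, non-paused molecules
#'
#' @param events Event table from [unwind_events()].
#' @param method `"slope"` (primary) or `"dwell"`.
#' @return Numeric vector of per-molecule velocities (bp/s).
#' @export
cohort_velocities <- function(events, method = c("slope", "dwell")) {
  method <- match.arg(method)
  col <- if (method == "slope") "v_slope_bp_s" else "v_dwell_bp_s"
  v <- events[[col]][events$qualifies & !events$paused]
  v[is.finite(v) & v > 0]
}
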