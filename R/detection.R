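# Rolling OLS slope over m consecutive points, computed from cumulative sums.
# Returns one slope per window start (length(x) - m + 1 values).
rolling_slope <- function(t, y, m) {
  n <- length(y)
  if (n < m) return(numeric(0))
  ct <- c(0, cumsum(t));   ct2 <- c(0, cumsum(t^2))
  cy <- c(0, cumsum(y));   cty <- c(0, cumsum(t * y))
  i <- seq_len(n - m + 1L)
  St <- ct[i + m] - ct[i]
  St2 <- ct2[i + m] - ct2[i]
  Sy <- cy[i + m] - cy[i]
  Sty <- cty[i + m] - cty[i]
  (m * Sty - St * Sy) / (m * St2 - St^2)
}

# First index at which `cond` holds for at least `k` consecutive entries,
# or NA if no such run exists.
first_run_start <- function(cond, k) {
  r <- rle(cond)
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0L) return(NA_integer_)
  if (hit[1L] == 1L) 1L else sum(r$lengths[seq_len(hit[1L] - 1L)]) + 1L
}

# Least-squares changepoint of the discontinuous two-segment model on
# (t, y): constant mean before b, a free line from b on; localizes abrupt
# steps that the continuous hinge cannot represent.
changepoint_fit <- function(t, y, candidates) {
  best_b <- NA_real_
  best_sse <- Inf
  best_jump <- NA_real_
  for (b in candidates) {
    pre <- t < b
    n_pre <- sum(pre)
    n_post <- length(t) - n_pre
    if (n_pre < 3 || n_post < 3) next
    mu_pre <- mean(y[pre])
    sse_pre <- sum((y[pre] - mu_pre)^2)
    fit <- lm.fit(cbind(1, t[!pre]), y[!pre])
    sse <- sse_pre + sum(fit$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_b <- b
      best_jump <- sum(fit$coefficients * c(1, b)) - mu_pre
    }
  }
  list(b = best_b, sse = best_sse, jump = best_jump, k = 4L)
}

# Least-squares breakpoint of the continuous flat-then-ramp (hinge) model
# y = b0 + b1 * (t - b)+ : the natural shape of a gradual unwinding ramp.
hinge_breakpoint <- function(t, y, candidates) {
  best_b <- NA_real_
  best_sse <- Inf
  for (b in candidates) {
    fit <- lm.fit(cbind(1, pmax(t - b, 0)), y)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_b <- b
    }
  }
  list(b = best_b, sse = best_sse, k = 3L)
}

#' Detect the unwinding onset in a BM time course
#'
#' The first derivative of the (smoothed) BM series is compared against the
#' 95% marginal band of its baseline values: the baseline mean and the
#' empirical 2.5/97.5 percentiles are estimated from the initial flat segment
#' (iteratively re-restricted to the data before the candidate onset), and an
#' onset is called at the first time the derivative exceeds the upper bound
#' for at least `persistence` consecutive points. The called time is then
#' refined by a least-squares changepoint fit of the raw BM series around
#' the trigger — a continuous flat-then-ramp hinge or, when parsimony (AIC)
#' favors it, a discontinuous flat-then-line model for abrupt steps — whose
#' breakpoint is returned as `t_start`.
#'
#' @param series A [bm_series()]. Dead-time windows are already absent
#'   (dead-time frames are unrecorded).
#' @param smooth Running-mean span (in windows) applied to the BM series
#'   before differencing.
#' @param gap Half-gap (in windows) of the central difference: the derivative
#'   at window i uses the smoothed BM at i - gap and i + gap.
#' @param persistence Consecutive out-of-band derivative points required to
#'   call an onset.
#' @param baseline_s Length (s) of the initial flat segment used to seed the
#'   baseline estimate (the tether BM is flat for >100 s before unwinding
#'   under the recording conditions); the segment is then re-restricted to
#'   the data before the candidate onset.
#' @param refine Refine the trigger time with the hinge fit (default `TRUE`).
#' @param refine_back,refine_fwd Span (s) of the hinge-fit window behind and
#'   ahead of the trigger.
#' @return An object of class `onset_detection`: `detected`, `t_start` (s, or
#'   `NA`), `t_trigger` (first persistent band crossing), and `band`
#'   (`mean`, `lower`, `upper`, nm/s, plus the number of baseline points).
#' @export
detect_unwind_start <- function(series, smooth = 15, gap = 8,
                                persistence = 15, baseline_s = 100,
                                refine = TRUE, refine_back = 100,
                                refine_fwd = 60) {
  stopifnot(inherits(series, "bm_series"))
  tt <- series$times
  bm <- series$bm
  nw <- length(bm)
  if (nw < 50) stop("BM series too short (", nw, " windows, need >= 50)")
  sm <- rolling_mean_na(bm, smooth)
  i <- seq_len(nw)
  lo <- pmax(i - gap, 1L)
  hi <- pmin(i + gap, nw)
  d <- (sm[hi] - sm[lo]) / (tt[hi] - tt[lo])

  # iterative baseline: seeded from the initial flat segment, then
  # restricted to everything before the candidate onset
  base_end <- max(min(sum(tt <= tt[1] + baseline_s), nw), min(50L, nw))
  trigger <- NA_integer_
  band <- NULL
  for (iter in 1:5) {
    base <- d[seq_len(base_end)]
    qs <- quantile(base, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    band <- list(mean = mean(base, na.rm = TRUE), lower = qs[1],
                 upper = qs[2], n_baseline = base_end)
    cand <- first_run_start(d > band$upper, persistence)
    if (is.na(cand)) {
      trigger <- NA_integer_
      break
    }
    new_end <- max(cand - 1L, min(50L, nw))
    if (!is.na(trigger) && cand == trigger) break
    trigger <- cand
    base_end <- new_end
  }

  if (is.na(trigger)) {
    return(structure(list(detected = FALSE, t_start = NA_real_,
                          t_trigger = NA_real_, band = band),
                     class = "onset_detection"))
  }

  t_trig <- tt[trigger]
  t_start <- t_trig
  if (refine) {
    sel <- tt >= t_trig - refine_back & tt <= t_trig + refine_fwd
    cand_b <- tt[sel]
    # thin the candidate grid to at most ~200 points for speed
    if (length(cand_b) > 200) {
      cand_b <- cand_b[round(seq(1, length(cand_b), length.out = 200))]
    }
    if (length(cand_b) >= 3 && sum(sel) >= 10) {
      # continuous hinge for gradual ramps; the discontinuous two-segment
      # model takes over only when it finds a jump that stands clearly
      # above the residual noise (an abrupt step, not a ramp)
      n_sel <- sum(sel)
      hg <- hinge_breakpoint(tt[sel], bm[sel], cand_b)
      cp <- changepoint_fit(tt[sel], bm[sel], cand_b)
      s_resid <- sqrt(cp$sse / max(n_sel - cp$k, 1))
      b <- if (!is.na(cp$b) && is.finite(cp$jump) &&
               abs(cp$jump) > 4 * (s_resid + 1e-12) &&
               cp$sse < 0.5 * hg$sse) cp$b else hg$b
      if (!is.na(b)) t_start <- b
    }
  }
  structure(list(detected = TRUE, t_start = t_start, t_trigger = t_trig,
                 band = band),
            class = "onset_detection")
}

#' @export
print.onset_detection <- function(x, ...) {
  if (x$detected) {
    cat("<onset_detection> onset at t = ", round(x$t_start, 2),
        " s (trigger ", round(x$t_trigger, 2), " s)\n", sep = "")
  } else {
    cat("<onset_detection> no onset detected\n")
  }
  if (!is.null(x$band))
    cat("  baseline derivative ", signif(x$band$mean, 3), " nm/s, 95% band [",
        signif(x$band$lower, 3), ", ", signif(x$band$upper, 3), "] (n = ",
        x$band$n_baseline, ")\n", sep = "")
  invisible(x)
}

#' Unwinding velocity from the BM slope
#'
#' Ordinary least-squares line through the increasing section of the BM time
#' course; the slope (nm/s) divided by the calibration factor (nm/bp) is the
#' unwinding velocity in bp/s.
#'
#' @param series A [bm_series()].
#' @param t_start,t_end Bounds (s) of the increasing section.
#' @param c_nm_bp Calibration factor (nm/bp), > 0.
#' @return List with `slope` (nm/s), `v_slope` (bp/s), `n` and the `lm` fit.
#' @export
fit_velocity_slope <- function(series, t_start, t_end, c_nm_bp) {
  stopifnot(inherits(series, "bm_series"))
  if (c_nm_bp <= 0) stop("c_nm_bp must be > 0")
  if (t_end <= t_start) stop("t_end must exceed t_start")
  sel <- series$times >= t_start & series$times <= t_end
  if (sum(sel) < 5) stop("fewer than 5 BM windows in [t_start, t_end]")
  fit <- lm(bm ~ t, data = data.frame(t = series$times[sel],
                                      bm = series$bm[sel]))
  slope <- unname(coef(fit)[2])
  list(slope = slope, v_slope = slope / c_nm_bp, n = sum(sel), fit = fit)
}

#' Unwinding velocity from the dwell time
#'
#' The dwell time runs from the beginning of the BM increase to the maximum
#' BM achieved (bead release); dividing the unwindable duplex length by it
#' gives the velocity.
#'
#' @param unwindable_bp Duplex length unwound over the dwell (bp).
#' @param t_start,t_max Onset and maximum-BM times (s), `t_max > t_start`.
#' @return Velocity (bp/s).
#' @examples
#' velocity_dwell(90, 100, 125) # 3.6 bp/s
#' @export
velocity_dwell <- function(unwindable_bp, t_start, t_max) {
  if (t_max <= t_start) stop("t_max must exceed t_start")
  unwindable_bp / (t_max - t_start)
}

#' Flag a pre-release pause in an unwinding trace
#'
#' Looks for a contiguous span of at least `plateau_min_s` between the onset
#' and the maximum BM where the local slope is flat (absolute rolling OLS
#' slope at most `slope_tol`) while the BM is still clearly below the final
#' level. Paused molecules are excluded from velocity statistics.
#'
#' @param series A [bm_series()].
#' @param t_start,t_max Onset and maximum-BM times (s).
#' @param plateau_min_s Minimum plateau duration (s).
#' @param slope_tol Flatness tolerance (nm/s); defaults to 30% of the overall
#'   slope of the increasing section.
#' @param level_margin_nm The plateau must sit at least this far (nm) below
#'   the final BM level (default 1 nm).
#' @return `TRUE` if a pause is present.
#' @export
flag_pause <- function(series, t_start, t_max, plateau_min_s = 15,
                       slope_tol = NULL, level_margin_nm = 1) {
  stopifnot(inherits(series, "bm_series"))
  sel <- series$times >= t_start & series$times <= t_max
  tt <- series$times[sel]
  bm <- series$bm[sel]
  if (length(tt) < 10) return(FALSE)
  step <- median(diff(tt))
  m <- max(3L, round(plateau_min_s / step))
  if (length(tt) < m + 2L) return(FALSE)
  if (is.null(slope_tol)) {
    overall <- rolling_slope(tt, bm, length(tt))
    slope_tol <- 0.3 * abs(overall)
  }
  sl <- rolling_slope(tt, bm, m)
  # window means, aligned with the rolling slopes
  cm <- c(0, cumsum(bm))
  i <- seq_len(length(bm) - m + 1L)
  wmean <- (cm[i + m] - cm[i]) / m
  final_level <- mean(tail(bm, m))
  flat <- abs(sl) <= slope_tol & wmean < final_level - level_margin_nm
  any(flat)
}

#' Does a trace qualify for velocity analysis?
#'
#' Only beads that disappear (the bead strand dissociates at completion of
#' unwinding) after a stretch of significantly increasing BM are analysed;
#' tethers that detach abruptly with a flat BM, or persist to the end of the
#' recording, do not qualify.
#'
#' @param series A [bm_series()] (carries the disappearance status).
#' @param span_s Length (s) of the pre-disappearance section tested for a
#'   positive slope.
#' @param level One-sided significance level for the slope test.
#' @return `TRUE` if the trace qualifies.
#' @export
qualify_event <- function(series, span_s = 30, level = 0.05) {
  stopifnot(inherits(series, "bm_series"))
  if (!isTRUE(series$disappeared)) return(FALSE)
  t_end <- max(series$times)
  sel <- series$times >= t_end - span_s
  if (sum(sel) < 5) return(FALSE)
  fit <- lm(bm ~ t, data = data.frame(t = series$times[sel],
                                      bm = series$bm[sel]))
  sm <- summary(fit)$coefficients
  slope <- sm[2, 1]
  p_onesided <- pt(sm[2, 3], df = fit$df.residual, lower.tail = FALSE)
  slope > 0 && p_onesided < level
}
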