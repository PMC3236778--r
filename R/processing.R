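# Centered rolling mean that ignores NA values; partial windows at the edges.
rolling_mean_na <- function(x, k) {
  n <- length(x)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(ok))
  half <- floor(k / 2)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- s / m
  out[m == 0] <- NA_real_
  out
}

#' Subtract slow stage drift from a trajectory
#'
#' Removes a centered moving average (default 10 s) from each coordinate.
#' The averaging window is long relative to the BM analysis window, so the
#' fast tether fluctuations that carry the signal are preserved while slow
#' drift is taken out.
#'
#' @param traj A `tpm_trajectory`.
#' @param drift_window_s Moving-average window (s). Must not exceed the
#'   trajectory length.
#' @return The drift-corrected `tpm_trajectory`.
#' @export
correct_drift <- function(traj, drift_window_s = 10) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  k <- round(drift_window_s * traj$frame_rate)
  if (k > length(traj$times))
    stop("trajectory (", length(traj$times), " frames) shorter than the ",
         "drift window (", k, " frames)")
  traj$x <- traj$x - rolling_mean_na(traj$x, k)
  traj$y <- traj$y - rolling_mean_na(traj$y, k)
  attr(traj, "drift_corrected") <- TRUE
  traj
}

#' Bead symmetry quality control
#'
#' A bead tethered by a single DNA molecule fluctuates isotropically; stuck or
#' multiply-tethered beads do not. The per-axis MSDs (position variances) are
#' computed over the first `n_frames` recorded frames and the bead passes iff
#' their ratio lies in the closed interval \[0.9, 1.1\].
#'
#' @param traj A `tpm_trajectory`.
#' @param n_frames Number of recorded frames used (default 1000).
#' @return An object of class `bead_qc`: `msd_x`, `msd_y` (nm^2), `ratio`,
#'   `symmetric`, `n_frames`.
#' @export
qc_symmetry <- function(traj, n_frames = 1000) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  idx <- which(traj$recorded & !is.na(traj$x))
  if (length(idx) < n_frames)
    stop("bead '", traj$bead_id, "': only ", length(idx),
         " recorded frames, need ", n_frames)
  idx <- idx[seq_len(n_frames)]
  msd_x <- var(traj$x[idx])
  msd_y <- var(traj$y[idx])
  ratio <- msd_x / msd_y
  structure(list(bead_id = traj$bead_id, msd_x = msd_x, msd_y = msd_y,
                 ratio = ratio, symmetric = ratio >= 0.9 & ratio <= 1.1,
                 n_frames = n_frames),
            class = "bead_qc")
}

#' @export
print.bead_qc <- function(x, ...) {
  cat("<bead_qc> ", x$bead_id, ": MSDx/MSDy = ", signif(x$ratio, 4),
      if (x$symmetric) " (symmetric)\n" else " (asymmetric)\n", sep = "")
  invisible(x)
}

#' Windowed Brownian-motion amplitude series
#'
#' Within each window of `window_frames` consecutive frames the per-axis MSD
#' is the within-window variance of the centroid position
#' (`<x^2> - <x>^2`, divide-by-n form) and the scalar BM amplitude is
#' `sqrt((MSDx + MSDy)/2)`, the per-axis RMS excursion in nm. Windows advance
#' by `stride` frames; windows touching any unrecorded frame are skipped.
#'
#' @param traj A `tpm_trajectory`, normally drift-corrected first.
#' @param window_frames Frames per window (default 20; 0.66 s at 30 Hz).
#' @param stride Window step in frames.
#' @return An object of class `bm_series`: `times` (window centers, s), `bm`
#'   (nm), plus window metadata and the disappearance status of the bead.
#' @export
bm_series <- function(traj, window_frames = 20, stride = 1) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  w <- as.integer(window_frames)
  if (w < 2) stop("window_frames must be >= 2")
  n <- length(traj$times)
  if (sum(traj$recorded) < w)
    stop("fewer recorded frames than one window")
  ok <- traj$recorded & !is.na(traj$x) & !is.na(traj$y)
  xs <- ifelse(ok, traj$x, 0)
  ys <- ifelse(ok, traj$y, 0)
  cx <- c(0, cumsum(xs));  cx2 <- c(0, cumsum(xs^2))
  cy <- c(0, cumsum(ys));  cy2 <- c(0, cumsum(ys^2))
  cn <- c(0, cumsum(ok))
  starts <- seq(1L, n - w + 1L, by = as.integer(stride))
  cnt <- cn[starts + w] - cn[starts]
  full <- cnt == w
  starts <- starts[full]
  if (length(starts) == 0L) stop("no fully recorded window")
  sx <- cx[starts + w] - cx[starts]
  sx2 <- cx2[starts + w] - cx2[starts]
  sy <- cy[starts + w] - cy[starts]
  sy2 <- cy2[starts + w] - cy2[starts]
  msd_x <- sx2 / w - (sx / w)^2
  msd_y <- sy2 / w - (sy / w)^2
  bm <- sqrt(pmax(msd_x + msd_y, 0) / 2)
  centers <- (traj$times[starts] + traj$times[starts + w - 1L]) / 2
  rec_t <- traj$times[ok]
  # long-block BM over the first (up to) 1000 recorded frames: used as a
  # window-bias reference (short windows on a correlated position process
  # underestimate the instantaneous amplitude; a long block does not)
  bidx <- which(ok)
  bidx <- bidx[seq_len(min(1000L, length(bidx)))]
  bx <- traj$x[bidx]; by <- traj$y[bidx]
  nb <- length(bidx)
  bm_block <- sqrt((sum((bx - mean(bx))^2) / nb +
                    sum((by - mean(by))^2) / nb) / 2)
  structure(list(bead_id = traj$bead_id, times = centers, bm = bm,
                 window_frames = w, stride = as.integer(stride),
                 frame_rate = traj$frame_rate,
                 window_s = w / traj$frame_rate,
                 duration = traj$duration,
                 last_recorded_t = max(rec_t),
                 disappeared = max(rec_t) <
                   traj$duration - 2 / traj$frame_rate,
                 bm_block = bm_block, block_frames = nb,
                 block_end_t = traj$times[bidx[nb]],
                 truth = traj$truth),
            class = "bm_series")
}

#' @export
print.bm_series <- function(x, ...) {
  cat("<bm_series> ", x$bead_id, ": ", length(x$times), " windows of ",
      x$window_frames, " frames (", signif(x$window_s, 3), " s), BM ",
      signif(min(x$bm), 3), "-", signif(max(x$bm), 3), " nm",
      if (x$disappeared) ", bead disappeared\n" else "\n", sep = "")
  invisible(x)
}

#' @export
plot.bm_series <- function(x, ...) {
  plot(x$times, x$bm, type = "l", xlab = "time (s)", ylab = "BM (nm)",
       main = x$bead_id, ...)
  invisible(x)
}

#' Population BM amplitudes and their Gaussian summary
#'
#' One BM amplitude per bead, computed from a single block of 1000
#' consecutive recorded frames, after the symmetry filter. The population is
#' summarised by the mean and standard deviation of the per-bead values
#' (the unbinned equivalent of fitting a single Gaussian to the histogram).
#'
#' @param trajs List of `tpm_trajectory` objects.
#' @param n_frames Frames per bead (default 1000).
#' @param qc Apply [qc_symmetry()] and drop failing beads (default `TRUE`).
#' @param drift_window_s Drift-correction window passed to [correct_drift()];
#'   `NULL` to skip drift correction.
#' @return An object of class `bm_population`: per-bead table (`bead_id`,
#'   `bm_nm`, `msd_x`, `msd_y`, `ratio`, `symmetric`), `mean`, `sd`, `n`,
#'   `degenerate` (TRUE when all values coincide).
#' @export
population_bm <- function(trajs, n_frames = 1000, qc = TRUE,
                          drift_window_s = 10) {
  stopifnot(length(trajs) >= 1)
  rows <- lapply(trajs, function(tr) {
    if (!is.null(drift_window_s)) tr <- correct_drift(tr, drift_window_s)
    q <- qc_symmetry(tr, n_frames)
    idx <- which(tr$recorded & !is.na(tr$x))[seq_len(n_frames)]
    vx <- var(tr$x[idx]) ; vy <- var(tr$y[idx])
    data.frame(bead_id = tr$bead_id, bm_nm = sqrt((vx + vy) / 2),
               msd_x = q$msd_x, msd_y = q$msd_y, ratio = q$ratio,
               symmetric = q$symmetric)
  })
  tab <- do.call(rbind, rows)
  keep <- if (qc) tab$symmetric else rep(TRUE, nrow(tab))
  vals <- tab$bm_nm[keep]
  if (length(vals) < 2) stop("need at least 2 beads passing QC")
  structure(list(beads = tab, values = vals, mean = mean(vals),
                 sd = sd(vals), n = length(vals),
                 degenerate = sd(vals) == 0),
            class = "bm_population")
}

#' @export
print.bm_population <- function(x, ...) {
  cat("<bm_population> ", x$n, " beads: BM = ", signif(x$mean, 4), " +/- ",
      signif(x$sd, 3), " nm (mean +/- s.d.)",
      if (x$degenerate) " [degenerate: zero spread]\n" else "\n", sep = "")
  invisible(x)
}

#' BM-to-base-pair calibration factor
#'
#' The conversion factor is the difference between the mean BM amplitudes of
#' the mimicked-unwound and intact fork substrates divided by their duplex
#' length difference: `c = (bm_final - bm_initial) / delta_bp` (nm/bp).
#'
#' @param initial,final `bm_population` objects (or bare numeric mean BM
#'   values, nm) for the intact and mimicked-unwound substrates.
#' @param delta_bp Duplex-length difference (bp), e.g. from the substrate
#'   model: `fork$duplex_bp - mimic$duplex_bp`.
#' @return An object of class `bm_calibration`: `c` (nm/bp), `bm_initial`,
#'   `bm_final`, `delta_bp`.
#' @examples
#' bm_calibration(9.90, 15.00, fork_ac90()$duplex_bp - mimic_unwound()$duplex_bp)
#' @export
bm_calibration <- function(initial, final, delta_bp) {
  bm0 <- if (inherits(initial, "bm_population")) initial$mean else initial
  bm1 <- if (inherits(final, "bm_population")) final$mean else final
  if (delta_bp <= 0) stop("delta_bp must be > 0")
  cc <- (bm1 - bm0) / delta_bp
  if (cc < 0)
    warning("negative conversion factor: final BM below initial BM")
  structure(list(c = cc, bm_initial = bm0, bm_final = bm1,
                 delta_bp = delta_bp),
            class = "bm_calibration")
}

#' @export
print.bm_calibration <- function(x, ...) {
  cat("<bm_calibration> c = (", signif(x$bm_final, 4), " - ",
      signif(x$bm_initial, 4), ") nm / ", x$delta_bp, " bp = ",
      signif(x$c, 3), " nm/bp\n", sep = "")
  invisible(x)
}
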