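# A quiet, clean configuration for focused tests: no drift, no anisotropy,
# no bead-to-bead spread unless a test asks for it.
quiet_config <- function(...) {
  args <- list(...)
  base <- list(drift_nm_s = 0, asym_frac = 0, sigma0_sd = 0, p_pause = 0)
  do.call(tpm_config, modifyList(base, args))
}

# Build a bm_series object directly from (times, bm) values, for tests that
# need full control over the BM time course (noiseless steps and ramps).
make_series <- function(times, bm, window_frames = 20, frame_rate = 30,
                        disappeared = TRUE, bm_block = NULL) {
  structure(list(bead_id = "synthetic", times = times, bm = bm,
                 window_frames = window_frames, stride = 20L,
                 frame_rate = frame_rate,
                 window_s = window_frames / frame_rate,
                 duration = max(times) + 1,
                 last_recorded_t = max(times),
                 disappeared = disappeared,
                 bm_block = bm_block, block_frames = 1000L,
                 block_end_t = if (is.null(bm_block)) -Inf else
                   times[1] + 1000 / frame_rate,
                 truth = NULL),
            class = "bm_series")
}

# Closed-form expected value of the divide-by-n within-window variance of a
# stationary AR(1)/OU-sampled process with per-frame correlation rho: the
# independent oracle for the finite-window BM bias.
ou_window_var_factor <- function(n, rho) {
  k <- seq_len(n - 1)
  (n - 1) / n - (2 / n^2) * sum((n - k) * rho^k)
}
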