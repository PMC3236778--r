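#' Write trajectories to CSV (with a ground-truth side-car)
#'
#' Columns: `bead_id, frame, t_s, x_nm, y_nm, recorded`. Numeric fields are
#' written at full precision so a read/write round trip is lossless. When any
#' trajectory carries simulation ground truth it is written to
#' `<path>.truth.json`.
#'
#' @param trajs List of `tpm_trajectory` objects.
#' @param path Output CSV path.
#' @param truth Also write the side-car JSON when available (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, truth = TRUE) {
  if (inherits(trajs, "tpm_trajectory")) trajs <- list(trajs)
  dfs <- lapply(trajs, function(tr) {
    data.frame(bead_id = tr$bead_id, frame = seq_along(tr$times) - 1L,
               t_s = tr$times, x_nm = tr$x, y_nm = tr$y,
               recorded = tr$recorded)
  })
  df <- do.call(rbind, dfs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("bead_id,frame,t_s,x_nm,y_nm,recorded", con)
  lines <- paste(df$bead_id, df$frame,
                 formatC(df$t_s, format = "g", digits = 17),
                 ifelse(is.na(df$x_nm), "",
                        formatC(df$x_nm, format = "g", digits = 17)),
                 ifelse(is.na(df$y_nm), "",
                        formatC(df$y_nm, format = "g", digits = 17)),
                 tolower(df$recorded), sep = ",")
  writeLines(lines, con)
  if (truth) {
    tl <- lapply(trajs, function(tr) tr$truth)
    names(tl) <- vapply(trajs, `[[`, character(1), "bead_id")
    if (any(!vapply(tl, is.null, logical(1))))
      jsonlite::write_json(tl, paste0(path, ".truth.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Inverse of [write_trajectories()]. Per-bead timestamps must be uniformly
#' spaced; malformed rows and non-uniform time grids are errors. A
#' `<path>.truth.json` side-car, when present, restores simulation ground
#' truth.
#'
#' @param path CSV path.
#' @return List of `tpm_trajectory` objects.
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bead_id", "frame", "t_s", "x_nm", "y_nm", "recorded")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$t_s))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, ": non-numeric t_s")
  truth_path <- paste0(path, ".truth.json")
  truths <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else list()
  ids <- unique(df$bead_id)
  lapply(ids, function(id) {
    d <- df[df$bead_id == id, ]
    d <- d[order(d$frame), ]
    dts <- diff(d$t_s)
    if (length(dts) > 1 && any(abs(dts - dts[1]) > 1e-9 * max(1, dts[1])))
      stop("bead '", id, "': non-uniform timestamps")
    rec <- as.logical(d$recorded)
    tr <- list(bead_id = id, times = d$t_s, x = d$x_nm, y = d$y_nm,
               recorded = rec, frame_rate = 1 / dts[1],
               duration = length(d$t_s) * dts[1],
               truth = if (id %in% names(truths)) truths[[id]] else NULL)
    class(tr) <- "tpm_trajectory"
    tr
  })
}

#' Write a BM series table
#'
#' Columns: `bead_id, t_s, bm_nm`.
#' @param series_list List of `bm_series` (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bm_series <- function(series_list, path) {
  if (inherits(series_list, "bm_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(bead_id = s$bead_id, t_s = s$times, bm_nm = s$bm)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-molecule event report
#'
#' TSV with columns `bead_id, t_start_s, t_max_s, slope_nm_s, v_slope_bp_s,
#' v_dwell_bp_s, paused, qualifies`.
#' @param events Event table from [unwind_events()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ensemble-assay tables
#'
#' `read_a340()` reads an absorbance time series CSV (`t_s, A340`);
#' `read_velocities()` reads a one-column CSV of per-molecule velocities;
#' `read_gel()` reads a gel TSV (`lane, percent_signal`).
#'
#' @param path Input file.
#' @return A data frame (`read_a340`, `read_gel`) or numeric vector
#'   (`read_velocities`).
#' @export
read_a340 <- function(path) {
  df <- read.csv(path)
  if (!all(c("t_s", "A340") %in% names(df)))
    stop("A340 CSV must have columns t_s, A340")
  df
}

#' @rdname read_a340
#' @export
read_velocities <- function(path) {
  df <- read.csv(path)
  as.numeric(df[[1]])
}

#' @rdname read_a340
#' @export
read_gel <- function(path) {
  df <- read.delim(path)
  if (!all(c("lane", "percent_signal") %in% names(df)))
    stop("gel TSV must have columns lane, percent_signal")
  df
}
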