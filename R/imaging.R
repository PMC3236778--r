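#' Optics settings for frame rendering
#'
#' @param pixel_nm Pixel size (nm/px).
#' @param psf_sigma_px Gaussian spot width (px).
#' @param photons Expected photons in the spot per frame; 0 gives pure
#'   background frames.
#' @param background Background level (counts/px).
#' @param image_size Side length of the square frame (px).
#' @param shot_noise Add Poisson shot noise (default `TRUE`).
#' @return A validated list of class `tpm_optics`.
#' @export
tpm_optics <- function(pixel_nm = 100, psf_sigma_px = 1.2, photons = 5000,
                       background = 10, image_size = 32, shot_noise = TRUE) {
  stopifnot(pixel_nm > 0, psf_sigma_px > 0, photons >= 0, background >= 0,
            image_size >= 4)
  structure(list(pixel_nm = pixel_nm, psf_sigma_px = psf_sigma_px,
                 photons = photons, background = background,
                 image_size = as.integer(image_size),
                 shot_noise = shot_noise),
            class = "tpm_optics")
}

#' Render a trajectory as a synthetic image stack
#'
#' One frame per time point; on recorded frames the bead is drawn as a 2-D
#' Gaussian spot centered at the true position (in nm, relative to the field
#' center), with optional Poisson shot noise. Frames after bead release (or
#' during the dead time) contain background only.
#'
#' @param traj A `tpm_trajectory`.
#' @param optics A [tpm_optics()].
#' @return An object of class `tpm_stack`: `frames` (list of matrices),
#'   `times`, `recorded`, `optics`, `bead_id`.
#' @export
render_frames <- function(traj, optics = tpm_optics()) {
  stopifnot(inherits(traj, "tpm_trajectory"), inherits(optics, "tpm_optics"))
  sz <- optics$image_size
  ctr <- (sz + 1) / 2
  px <- ctr + traj$x / optics$pixel_nm
  py <- ctr + traj$y / optics$pixel_nm
  rec <- traj$recorded & !is.na(traj$x)
  if (any(px[rec] < 1 | px[rec] > sz | py[rec] < 1 | py[rec] > sz))
    stop("bead leaves the field of view; enlarge image_size or pixel_nm")
  gx <- seq_len(sz)
  frames <- vector("list", length(traj$times))
  s2 <- 2 * optics$psf_sigma_px^2
  for (i in seq_along(frames)) {
    f <- matrix(optics$background, sz, sz)
    if (rec[i] && optics$photons > 0) {
      kx <- exp(-(gx - px[i])^2 / s2)
      ky <- exp(-(gx - py[i])^2 / s2)
      spot <- optics$photons * outer(ky, kx) / (pi * s2)
      f <- f + spot
    }
    if (optics$shot_noise) f <- matrix(rpois(sz * sz, f), sz, sz)
    frames[[i]] <- f
  }
  structure(list(frames = frames, times = traj$times, recorded = rec,
                 optics = optics, bead_id = traj$bead_id,
                 frame_rate = traj$frame_rate, duration = traj$duration),
            class = "tpm_stack")
}

#' Write an image stack as a multi-page TIFF
#'
#' @param stack A `tpm_stack`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "tpm_stack"))
  mx <- max(vapply(stack$frames, max, numeric(1)), 1)
  tiff::writeTIFF(lapply(stack$frames, function(f) f / mx), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file.
#' @param frame_rate Frames per second of the recording.
#' @param bead_id Identifier to attach.
#' @return A `tpm_stack` (times reconstructed from `frame_rate`).
#' @export
read_stack_tiff <- function(path, frame_rate = 30, bead_id = "bead-1") {
  frames <- tiff::readTIFF(path, all = TRUE)
  n <- length(frames)
  structure(list(frames = frames, times = (seq_len(n) - 1) / frame_rate,
                 recorded = rep(TRUE, n), optics = NULL, bead_id = bead_id,
                 frame_rate = frame_rate, duration = n / frame_rate),
            class = "tpm_stack")
}

#' Localize bead centroids in an image stack
#'
#' Per frame, pixels above `threshold` are segmented into connected
#' components; the intensity-weighted centroid (above background) of the
#' selected component is converted to nm relative to the field center. When
#' several spots are present the one nearest the previous position is
#' followed; ambiguity in the first frame is an error. Frames with no pixel
#' above threshold are marked unrecorded.
#'
#' @param stack A `tpm_stack`.
#' @param threshold Intensity threshold separating spot from background.
#' @return A `tpm_trajectory` (without ground truth).
#' @export
localize_centroids <- function(stack, threshold) {
  stopifnot(inherits(stack, "tpm_stack"))
  n <- length(stack$frames)
  if (n == 0) stop("empty stack")
  sz <- nrow(stack$frames[[1]])
  ctr <- (sz + 1) / 2
  pixel_nm <- if (!is.null(stack$optics)) stack$optics$pixel_nm else 1
  x <- rep(NA_real_, n)
  y <- rep(NA_real_, n)
  rec <- rep(FALSE, n)
  prev <- NULL
  for (i in seq_len(n)) {
    f <- stack$frames[[i]]
    mask <- f > threshold
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    ids <- setdiff(unique(as.vector(lab)), 0)
    bg <- median(f[!mask])
    cents <- t(vapply(ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      wt <- pmax(f[lab == id] - bg, 0)
      if (sum(wt) == 0) wt <- rep(1, nrow(w))
      c(sum(w[, 2] * wt), sum(w[, 1] * wt)) / sum(wt) # (col = x, row = y)
    }, numeric(2)))
    pick <- 1L
    if (length(ids) > 1L) {
      if (is.null(prev))
        stop("ambiguous first frame: ", length(ids), " spots above threshold")
      dists <- (cents[, 1] - prev[1])^2 + (cents[, 2] - prev[2])^2
      pick <- which.min(dists)
    }
    prev <- cents[pick, ]
    x[i] <- (prev[1] - ctr) * pixel_nm
    y[i] <- (prev[2] - ctr) * pixel_nm
    rec[i] <- TRUE
  }
  if (!any(rec)) stop("no spot found in any frame")
  structure(list(bead_id = stack$bead_id, times = stack$times, x = x, y = y,
                 recorded = rec, frame_rate = stack$frame_rate,
                 duration = stack$duration, truth = NULL),
            class = "tpm_trajectory")
}
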