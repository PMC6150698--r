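#' Render a dF/F0 trace as a synthetic run movie
#'
#' A bright disc ROI over a dim background: foreground intensity follows the
#' trace scaled to photon-count-like levels with shot-like noise
#' (sd proportional to the square root of the clean intensity); the whole
#' run is translated by a fixed drift, recorded as ground truth.
#'
#' @param trace dF/F0 values: a vector (one repeat) or an
#'   `n_samples x n_repeats` matrix (one run; repeats are concatenated in
#'   time).
#' @param frame_shape `(height, width)` in pixels.
#' @param roi_center `(row, col)` of the ROI disc; defaults to frame center.
#' @param roi_radius disc radius in pixels.
#' @param drift `(dy, dx)` whole-run translation in pixels.
#' @param seed seed for the noise.
#' @param fg_gain foreground counts per unit (1 + dF/F0).
#' @param bg_level background counts.
#' @param noise_scale multiplier on the shot-noise sd; 0 for a noiseless movie.
#' @return list with `frames` (array `time x height x width`, counts in
#'   `[0, 65535]`), `shift` (the ground-truth drift), `mask` (ground-truth ROI,
#'   undrifted), `trace`.
#' @export
simulate_movie <- function(trace, frame_shape = c(32, 32), roi_center = NULL,
                           roi_radius = 6, drift = c(0, 0), seed = 1,
                           fg_gain = 80, bg_level = 12, noise_scale = 1) {
  tr <- as.vector(trace)
  h <- frame_shape[1]; w <- frame_shape[2]
  roi_center <- roi_center %||% c((h + 1) / 2, (w + 1) / 2)
  d2 <- outer((seq_len(h) - roi_center[1])^2, (seq_len(w) - roi_center[2])^2, `+`)
  mask <- d2 <= roi_radius^2
  if (!any(mask)) stop("ROI disc contains no pixels")
  lim <- roi_radius + 1
  if (roi_center[1] - lim + min(drift[1], 0) < 0 ||
      roi_center[1] + lim + max(drift[1], 0) > h + 1 ||
      roi_center[2] - lim + min(drift[2], 0) < 0 ||
      roi_center[2] + lim + max(drift[2], 0) > w + 1)
    stop(sprintf("drift (%.1f, %.1f) px pushes the ROI out of the %dx%d frame",
                 drift[1], drift[2], h, w))
  frames <- array(0, dim = c(length(tr), h, w))
  with_seed(seed, {
    for (t in seq_along(tr)) {
      img <- matrix(bg_level, h, w)
      img[mask] <- bg_level + fg_gain * max(1 + tr[t], 0)
      if (any(drift != 0)) img <- fourier_shift(img, drift)
      if (noise_scale > 0)
        img <- img + stats::rnorm(h * w, 0, noise_scale * sqrt(pmax(img, 0)))
      frames[t, , ] <- pmin(pmax(round(img), 0), 65535)
    }
  })
  list(frames = frames, shift = drift, mask = mask, trace = tr)
}

#' Write a run movie as a multi-page 16-bit TIFF
#'
#' @param frames array `time x height x width` of counts in `[0, 65535]`.
#' @param path output file.
#' @export
write_movie_tiff <- function(frames, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF movies")
  pages <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF run movie
#'
#' @param path TIFF file written by [write_movie_tiff()] (or equivalent
#'   16-bit multi-page stack).
#' @return array `time x height x width` of counts.
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF movies")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  out <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) out[t, , ] <- pages[[t]] * 65535
  out
}
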