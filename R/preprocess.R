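#' @name preprocess
#' @title From raw movies to dF/F0 traces
#'
#' @description
#' Movie preprocessing follows a fixed recipe, computed once per experiment
#' and reused for every run: run-average images are aligned by correlation-
#' based sub-pixel registration; a single ROI is segmented from the grand
#' average image by 2-cluster k-means on pixel intensity (intensity only,
#' never activity); the background `B` is the mean of the dimmest 10% of
#' pixels of the average image; the baseline `F0` is the median ROI
#' fluorescence over the dimmest 3% of frames pooled across all runs; and
#' `dF/F0 = (F - F0) / (F0 - B)` per frame.
NULL

# signed FFT frequencies (cycles per sample) in FFT storage order
fft_freqs <- function(n) c(0:(ceiling(n / 2) - 1), seq.int(-floor(n / 2), -1)) / n

#' Translate an image by a (possibly fractional) shift via the Fourier shift
#' theorem
#'
#' @param img numeric matrix.
#' @param shift numeric length-2 `(rows, cols)`; positive moves content down
#'   and right (circularly).
#' @return shifted matrix.
#' @export
fourier_shift <- function(img, shift) {
  stopifnot(is.matrix(img), length(shift) == 2)
  nr <- nrow(img); nc <- ncol(img)
  fy <- fft_freqs(nr); fx <- fft_freqs(nc)
  phase <- exp(-2i * pi * (outer(fy * shift[1], rep(1, nc)) +
                           outer(rep(1, nr), fx * shift[2])))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (nr * nc)
}

# Upsampled inverse DFT of the cross-power spectrum, evaluated at the shift
# grid rows_at x cols_at (in pixels), by explicit matrix products.
dft_upsample <- function(CP, rows_at, cols_at) {
  kr <- exp(2i * pi * outer(rows_at, fft_freqs(nrow(CP))))
  kc <- exp(2i * pi * outer(fft_freqs(ncol(CP)), cols_at))
  kr %*% CP %*% kc
}

#' Estimate the translation between two images by cross-correlation with
#' Fourier-upsampled sub-pixel refinement
#'
#' Returns the shift to apply (with [fourier_shift()]) to `img` so that it
#' aligns with `ref`: if `img` is `ref` translated by `(+2, +3)` pixels the
#' estimate is `(-2, -3)`.
#'
#' @param ref,img numeric matrices of identical size.
#' @param upsample sub-pixel refinement factor (1 = integer-pixel only).
#' @return numeric length-2 shift `(rows, cols)` in pixels.
#' @export
estimate_shift <- function(ref, img, upsample = 10) {
  stopifnot(is.matrix(ref), all(dim(ref) == dim(img)), upsample >= 1)
  nr <- nrow(ref); nc <- ncol(ref)
  CP <- stats::fft(ref) * Conj(stats::fft(img))
  cc <- Mod(stats::fft(CP, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc)) - 1L
  s <- c(if (pk[1] > nr / 2) pk[1] - nr else pk[1],
         if (pk[2] > nc / 2) pk[2] - nc else pk[2])
  if (upsample > 1) {
    grid_r <- s[1] + seq(-1.5, 1.5, by = 1 / upsample)
    grid_c <- s[2] + seq(-1.5, 1.5, by = 1 / upsample)
    up <- Mod(dft_upsample(CP, grid_r, grid_c))
    pk <- arrayInd(which.max(up), dim(up))
    s <- c(grid_r[pk[1]], grid_c[pk[2]])
  }
  s
}

#' Align the runs of an experiment to a common reference
#'
#' For each run the time-average image is computed; the translation between
#' each run average and the reference run's average is estimated with
#' [estimate_shift()] and every frame of the run is shifted accordingly.
#'
#' @param movies list of 3-D arrays `(time, height, width)`, one per run.
#' @param reference index of the reference run.
#' @param upsample sub-pixel refinement factor.
#' @param max_shift_frac warn when an estimated shift exceeds this fraction
#'   of the frame size (possible registration failure).
#' @return list with `aligned` (list of arrays) and `shifts` (runs x 2 matrix).
#' @export
register_runs <- function(movies, reference = 1, upsample = 10,
                          max_shift_frac = 0.25) {
  stopifnot(is.list(movies), length(movies) >= 1)
  dims <- dim(movies[[1]])
  avg <- lapply(movies, function(m) apply(m, c(2, 3), mean))
  ref <- avg[[reference]]
  shifts <- matrix(0, length(movies), 2,
                   dimnames = list(names(movies), c("dy", "dx")))
  aligned <- vector("list", length(movies))
  names(aligned) <- names(movies)
  for (i in seq_along(movies)) {
    s <- if (i == reference) c(0, 0) else estimate_shift(ref, avg[[i]], upsample)
    if (any(abs(s) > max_shift_frac * dims[2:3]))
      warning(sprintf("run %d: estimated shift (%.2f, %.2f) px exceeds %.0f%% of the frame; registration may have failed",
                      i, s[1], s[2], 100 * max_shift_frac))
    shifts[i, ] <- s
    m <- movies[[i]]
    if (all(s == 0)) aligned[[i]] <- m
    else {
      out <- m
      for (t in seq_len(dims[1])) out[t, , ] <- fourier_shift(m[t, , ], s)
      aligned[[i]] <- out
    }
  }
  list(aligned = aligned, shifts = shifts)
}

#' Segment the experiment ROI by 2-cluster k-means on average intensity
#'
#' The grand average image is partitioned into two intensity clusters with
#' deterministically initialized k-means (centroids at the minimum and
#' maximum intensity); the brighter cluster is the foreground ROI. The
#' segmentation uses average intensity only, never activity, so responsive
#' and non-responsive experiments are treated identically.
#'
#' @param mean_image average image over all aligned runs.
#' @return logical matrix (`TRUE` = ROI).
#' @export
segment_roi <- function(mean_image) {
  stopifnot(is.matrix(mean_image))
  v <- as.vector(mean_image)
  if (stats::sd(v) <= 1e-12 * (abs(mean(v)) + 1))
    stop("near-zero intensity variance: no foreground/background structure to segment")
  km <- stats::kmeans(v, centers = matrix(c(min(v), max(v))),
                      iter.max = 200, algorithm = "Lloyd")
  fg <- which.max(km$centers)
  matrix(km$cluster == fg, nrow(mean_image), ncol(mean_image))
}

#' Background estimate: the dimmest 10% of pixels of the average image
#'
#' @param mean_image average image of the experiment.
#' @param frac pixel fraction defining "dimmest".
#' @param method `"mean"` (default) or `"median"` summary of that pixel set.
#' @return scalar `B`.
#' @export
estimate_background <- function(mean_image, frac = 0.1, method = c("mean", "median")) {
  method <- match.arg(method)
  v <- sort(as.vector(mean_image))
  k <- max(1L, floor(frac * length(v)))
  if (method == "mean") mean(v[seq_len(k)]) else stats::median(v[seq_len(k)])
}

#' Baseline fluorescence F0: median ROI fluorescence of the dimmest 3% of
#' frames of the entire experiment
#'
#' Baseline fluorescence can vary widely over an experiment, so F0 is global:
#' per-frame mean ROI fluorescence is pooled across all runs, frames are
#' ranked by it, and F0 is the median over the dimmest 3%.
#'
#' @param roi_fluorescence numeric vector (or list of per-run vectors) of
#'   per-frame mean ROI fluorescence, pooled over all runs.
#' @param frac frame fraction defining "dimmest".
#' @return scalar `F0`.
#' @export
compute_f0 <- function(roi_fluorescence, frac = 0.03) {
  f <- unlist(roi_fluorescence, use.names = FALSE)
  nf <- length(f)
  if (nf < ceiling(1 / frac)) {
    warning(sprintf("only %d frames: fewer than 1/%.0f%%; falling back to the dimmest single frame",
                    nf, 100 * frac))
    return(min(f))
  }
  k <- max(1L, floor(frac * nf))
  stats::median(sort(f)[seq_len(k)])
}

#' Normalized fluorescence dF/F0 = (F - F0) / (F0 - B)
#'
#' @param f per-frame ROI fluorescence.
#' @param f0 baseline fluorescence (see [compute_f0()]).
#' @param b background (see [estimate_background()]).
#' @return numeric vector of dF/F0.
#' @export
compute_dff <- function(f, f0, b) {
  if (f0 <= b)
    stop(sprintf("F0 (%.4g) must exceed the background B (%.4g): normalizer F0 - B is not positive", f0, b))
  (f - f0) / (f0 - b)
}

# per-frame mean fluorescence over the ROI
extract_roi_trace <- function(movie, mask) {
  stopifnot(length(dim(movie)) == 3, any(mask))
  m <- matrix(movie, nrow = dim(movie)[1])
  rowMeans(m[, as.vector(mask), drop = FALSE])
}

#' Full preprocessing of one experiment's run movies
#'
#' Registration, ROI segmentation, background and F0 estimation and dF/F0
#' extraction, with the ROI and F0 computed once for the whole experiment.
#'
#' @param movies list of per-run arrays `(time, height, width)`; each run
#'   holds `n_repeats` concatenated repeats.
#' @param n_repeats repeats per run (frames are split evenly).
#' @param upsample registration sub-pixel factor.
#' @return list with `traces` (per-run `n_samples x n_repeats` dF/F0
#'   matrices), `shifts`, `mask`, `B`, `F0`, and a `report` list.
#' @export
preprocess_experiment <- function(movies, n_repeats = 4, upsample = 10) {
  reg <- register_runs(movies, upsample = upsample)
  avg <- lapply(reg$aligned, function(m) apply(m, c(2, 3), mean))
  grand <- Reduce(`+`, avg) / length(avg)
  mask <- segment_roi(grand)
  b <- estimate_background(grand)
  raw <- lapply(reg$aligned, extract_roi_trace, mask = mask)
  f0 <- compute_f0(raw)
  traces <- lapply(raw, function(f) {
    dff <- compute_dff(f, f0, b)
    matrix(dff, ncol = n_repeats)
  })
  list(traces = traces, shifts = reg$shifts, mask = mask, B = b, F0 = f0,
       report = list(n_runs = length(movies), roi_pixels = sum(mask),
                     B = b, F0 = f0, shifts = reg$shifts))
}
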