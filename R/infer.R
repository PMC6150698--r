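#' @name inference
#' @title Connection inference against the non-overlapping null
#'
#' @description
#' Each cell-type pair is summarized by two coordinates: the dataset-scaled,
#' baseline-normalized response integral (`ItoPeak_norm_scaled`, amplitude
#' and sign) and the between-fly transient correlation (`R_between`,
#' reliability). Anatomically non-overlapping pairs, which cannot be
#' synaptically connected, provide an empirical null sample in this plane.
#' A high-breakdown robust location/scatter estimate (minimum covariance
#' determinant) is fitted to the null sample and every pair is scored by its
#' squared Mahalanobis distance to it. Significance comes from a resampling
#' estimate of the null distance distribution's upper tail: pairs beyond the
#' `1 - alpha` quantile (p < alpha) are called connected, signed by the
#' response integral.
NULL

#' Fit the robust null model on non-overlapping pairs
#'
#' Location and scatter are estimated by the minimum-covariance-determinant
#' (MCD) estimator, so that a few contaminated "null" pairs (e.g. real but
#' unannotated connections) cannot inflate the null.
#'
#' @param points numeric matrix (n x 2) of feature points, or a data.frame
#'   with columns `x1`, `x2`.
#' @param support_fraction fraction of the sample the MCD covers.
#' @param nsamp number of subset candidates for the MCD search.
#' @param seed seed for the (stochastic) MCD search; fixed by default so the
#'   fit is reproducible.
#' @return object of class `cx_nullmodel`: list with `mu` (length-2), `S`
#'   (2 x 2 covariance), `n`, and estimator metadata.
#' @export
fit_null <- function(points, support_fraction = 0.75, nsamp = 100, seed = 20230101) {
  x <- as.matrix(if (is.data.frame(points)) points[, c("x1", "x2")] else points)
  storage.mode(x) <- "double"
  if (nrow(x) < 5)
    stop(sprintf("need at least 5 null points for a 2-D robust covariance (got %d)", nrow(x)))
  if (any(!is.finite(x))) stop("null points must be finite")
  if (qr(stats::cov(x))$rank < 2)
    stop("degenerate null sample: points are collinear, covariance is singular")
  # cov.rob chats about falling back to exhaustive subset search on small n
  fit <- with_seed(seed, suppressWarnings(
    MASS::cov.rob(x, method = "mcd",
                  quantile.used = floor(support_fraction * nrow(x)),
                  nsamp = nsamp)))
  structure(list(mu = unname(fit$center), S = unname(fit$cov), n = nrow(x),
                 method = "mcd", support_fraction = support_fraction,
                 nsamp = nsamp, seed = seed),
            class = "cx_nullmodel")
}

#' Squared Mahalanobis distance to the null model
#'
#' Computes `(x - mu)' S^-1 (x - mu)` — the squared form; note that the
#' conventional "Mahalanobis distance" is its square root. All strengths and
#' thresholds in this package are on the squared scale.
#'
#' @param points numeric vector (length 2) or matrix (n x 2).
#' @param model a [fit_null()] model, or any list with `mu` and `S`.
#' @return numeric vector of squared distances.
#' @export
mahalanobis_sq <- function(points, model) {
  x <- if (is.null(dim(points))) matrix(points, nrow = 1) else as.matrix(points)
  stopifnot(ncol(x) == length(model$mu))
  r <- tryCatch(solve(model$S), error = function(e)
    stop("singular covariance matrix in the null model"))
  d <- sweep(x, 2, model$mu)
  unname(rowSums((d %*% r) * d))
}

#' Resampling estimate of the significance threshold
#'
#' Estimates the `1 - alpha` quantile of the null distance distribution by
#' pooling distances over `B` resampling replicates of the null sample, and
#' returns it as the significance threshold (a pair is significant iff its
#' squared distance exceeds it, i.e. p < `alpha`).
#'
#' Two schemes are available. `"holdout"` (default): each replicate refits
#' the robust model on a random subset with `d = max(2, ceil(holdout_frac *
#' n))` points held out and pools the distances of the held-out points —
#' held-out scoring avoids the optimism of in-sample distances while keeping
#' the refit close to the full-sample estimator. `"resample"`: the classic
#' pair bootstrap (resample the null with replacement, refit, pool the
#' distances of the resampled points); with a robust fit this is markedly
#' conservative, because bootstrap duplicates shrink the MCD scatter.
#'
#' @param points null feature points (n x 2 matrix or data.frame with
#'   `x1`, `x2`).
#' @param B number of replicates (>= 1000 recommended; must be at least
#'   `1/alpha`).
#' @param alpha significance level.
#' @param seed seed fixing the resampling.
#' @param scheme `"holdout"` or `"resample"`.
#' @param holdout_frac held-out fraction for the `"holdout"` scheme.
#' @param support_fraction,nsamp passed to the per-replicate [fit_null()].
#' @return list with `threshold`, `alpha`, `B`, `scheme`, `pool` (the pooled
#'   null distances, used for empirical p-values).
#' @export
significance_threshold <- function(points, B = 10000, alpha = 0.01, seed = 1,
                                   scheme = c("holdout", "resample"),
                                   holdout_frac = 0.05,
                                   support_fraction = 0.75, nsamp = 100) {
  scheme <- match.arg(scheme)
  x <- as.matrix(if (is.data.frame(points)) points[, c("x1", "x2")] else points)
  n <- nrow(x)
  if (B < 1 / alpha)
    stop(sprintf("B = %d replicates cannot resolve the %g quantile; need at least %d",
                 B, 1 - alpha, ceiling(1 / alpha)))
  d_out <- max(2L, ceiling(holdout_frac * n))
  pool <- vector("list", B)
  failed <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      if (scheme == "holdout") {
        keep <- sample.int(n, n - d_out)
        score_idx <- setdiff(seq_len(n), keep)
      } else {
        keep <- sample.int(n, n, replace = TRUE)
        score_idx <- keep
      }
      fit <- tryCatch(
        fit_null(x[keep, , drop = FALSE], support_fraction, nsamp, seed = NULL),
        error = function(e) NULL)
      if (is.null(fit)) { failed <- failed + 1L; next }
      pool[[b]] <- mahalanobis_sq(x[score_idx, , drop = FALSE], fit)
    }
  })
  if (failed > 0.2 * B)
    stop(sprintf("robust refit failed in %d of %d replicates: null sample too degenerate", failed, B))
  pooled <- unlist(pool)
  list(threshold = unname(stats::quantile(pooled, 1 - alpha)), alpha = alpha,
       B = B, scheme = scheme, holdout = d_out, n_failed = failed,
       pool = pooled)
}

#' Empirical p-value of an observed distance against the pooled null
#'
#' @param d squared distances.
#' @param pool pooled null distances from [significance_threshold()].
#' @return p-values `(1 + #\{pool >= d\}) / (1 + length(pool))`.
#' @export
empirical_p <- function(d, pool) {
  vapply(d, function(di) (1 + sum(pool >= di)) / (1 + length(pool)), numeric(1))
}

#' Score all pairs and build the connectivity edge list
#'
#' Every pair (candidates and controls alike) is scored by its squared
#' Mahalanobis distance to the null model; an edge is significant when its
#' distance exceeds the threshold. The sign of the scaled normalized
#' integral gives the connection sign, `R_between` its reliability;
#' non-overlapping pairs are flagged as controls.
#'
#' @param features data.frame with columns `pair_id`, `pre`, `post`, `x1`
#'   (`ItoPeak_norm_scaled`), `x2` (`R_between`), `overlapping`.
#' @param model a [fit_null()] model.
#' @param threshold a [significance_threshold()] result (or a bare number).
#' @return data.frame of edges: `pair_id`, `pre`, `post`, `strength`
#'   (squared distance), `sign`, `reliability`, `significant`, `control`,
#'   and `p_value` when the threshold carries its pooled null.
#' @export
classify_edges <- function(features, model, threshold) {
  stopifnot(all(c("pair_id", "pre", "post", "x1", "x2", "overlapping") %in%
                names(features)))
  thr <- if (is.list(threshold)) threshold$threshold else threshold
  d <- mahalanobis_sq(cbind(features$x1, features$x2), model)
  out <- data.frame(
    pair_id = features$pair_id, pre = features$pre, post = features$post,
    strength = d, sign = sign(features$x1), reliability = features$x2,
    significant = d > thr, control = !features$overlapping)
  if (is.list(threshold) && !is.null(threshold$pool))
    out$p_value <- empirical_p(d, threshold$pool)
  out
}

#' Extract the 2-D feature table for inference from pair statistics
#'
#' Pairs with undefined `R_between` (single fly) are dropped with a warning.
#'
#' @param pair_table the `pairs` table from [screen_statistics()].
#' @param n_pulses which stimulation protocol to use; defaults to the
#'   strongest present.
#' @return data.frame with `pair_id`, `pre`, `post`, `x1`, `x2`,
#'   `overlapping`.
#' @export
feature_points <- function(pair_table, n_pulses = NULL) {
  n_pulses <- n_pulses %||% max(pair_table$n_pulses)
  sub <- pair_table[pair_table$n_pulses == n_pulses, , drop = FALSE]
  if (nrow(sub) == 0) stop(sprintf("no pairs at %d pulses", n_pulses))
  bad <- !is.finite(sub$R_between)
  if (any(bad)) {
    warning(sprintf("dropping %d pair(s) with undefined R_between (single usable fly)", sum(bad)))
    sub <- sub[!bad, , drop = FALSE]
  }
  data.frame(pair_id = sub$pair_id, pre = sub$pre, post = sub$post,
             x1 = sub$ItoPeak_norm_scaled, x2 = sub$R_between,
             overlapping = sub$overlapping)
}
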