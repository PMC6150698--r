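rand_model <- function() {
  A <- matrix(rnorm(4), 2)
  list(mu = rnorm(2), S = crossprod(A) + diag(0.3, 2))
}

test_that("the squared Mahalanobis distance matches independent computations", {
  m <- list(mu = c(0, 0), S = diag(2))
  expect_equal(mahalanobis_sq(c(3, 4), m), 25)
  expect_equal(mahalanobis_sq(c(0, 0), m), 0)
  set.seed(4)
  for (k in 1:200) {
    mm <- rand_model()
    x <- rnorm(2)
    # explicit 2x2 inverse and quadratic form
    S <- mm$S; det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    inv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2) / det
    d <- x - mm$mu
    expect_equal(mahalanobis_sq(x, mm), drop(t(d) %*% inv %*% d),
                 tolerance = 1e-10)
    # independent library cross-check
    expect_equal(mahalanobis_sq(x, mm),
                 unname(stats::mahalanobis(matrix(x, 1), mm$mu, mm$S)),
                 tolerance = 1e-10)
  }
  expect_error(mahalanobis_sq(c(1, 1), list(mu = c(0, 0),
                                            S = matrix(1, 2, 2))), "singular")
})

test_that("distances are invariant under a common affine transform", {
  set.seed(5)
  mm <- rand_model()
  X <- matrix(rnorm(40), ncol = 2)
  A <- matrix(c(2, 0.5, -1, 1.5), 2); b <- c(3, -7)
  mt <- list(mu = drop(A %*% mm$mu + b), S = A %*% mm$S %*% t(A))
  Xt <- t(A %*% t(X) + b)
  expect_equal(mahalanobis_sq(Xt, mt), mahalanobis_sq(X, mm), tolerance = 1e-10)
})

test_that("the robust null fit recovers a clean bivariate normal and resists contamination", {
  set.seed(6)
  X <- matrix(rnorm(400), ncol = 2)
  fit <- fit_null(X)
  expect_lt(max(abs(fit$mu)), 0.2)
  expect_lt(max(abs(fit$S - diag(2))), 0.3)
  # 10% duplicated gross points at the corner of the feature plane
  Xc <- rbind(X, matrix(1, 20, 2))
  fitc <- fit_null(Xc)
  expect_lt(max(abs(fitc$mu - fit$mu)), 0.2)
  expect_lt(max(abs(fitc$S - fit$S)), 0.3)
})

test_that("degenerate null samples are rejected", {
  expect_error(fit_null(matrix(rnorm(6), 3, 2)), "at least 5")
  line <- cbind(1:10, 2 * (1:10))
  expect_error(fit_null(line), "collinear")
})

test_that("with known standard-normal parameters the null distances are chi-square(2)", {
  set.seed(7)
  X <- matrix(rnorm(2e5), ncol = 2)
  d <- mahalanobis_sq(X, list(mu = c(0, 0), S = diag(2)))
  expect_lt(abs(quantile(d, 0.99) - qchisq(0.99, 2)), 0.15)
})

test_that("the bootstrap threshold is deterministic under a seed and validates B", {
  set.seed(8)
  X <- matrix(rnorm(80), ncol = 2)
  t1 <- significance_threshold(X, B = 200, seed = 3)
  t2 <- significance_threshold(X, B = 200, seed = 3)
  expect_identical(t1$threshold, t2$threshold)
  t3 <- significance_threshold(X, B = 200, seed = 4)
  expect_false(identical(t1$threshold, t3$threshold))
  expect_error(significance_threshold(X, B = 50, alpha = 0.01), "cannot resolve")
})

test_that("a tight null cluster flags a distant point but not itself", {
  set.seed(9)
  X <- matrix(rnorm(120, sd = 1e-3), ncol = 2)
  fit <- fit_null(X)
  thr <- significance_threshold(X, B = 200, seed = 1)
  d_null <- mahalanobis_sq(X, fit)
  d_test <- mahalanobis_sq(c(1, 1), fit)
  expect_gt(d_test, thr$threshold)
  expect_lt(mean(d_null > thr$threshold), 0.05)
})

test_that("edge classification fills sign, reliability, control and p-values", {
  set.seed(10)
  feats <- data.frame(pair_id = sprintf("p%02d", 1:22),
                      pre = "a", post = "b",
                      x1 = c(rnorm(20, 0, 0.05), 0.9, -0.9),
                      x2 = c(rnorm(20, 0, 0.05), 0.95, 0.9),
                      overlapping = c(rep(FALSE, 20), TRUE, TRUE))
  nulls <- feats[!feats$overlapping, c("x1", "x2")]
  model <- fit_null(nulls)
  thr <- significance_threshold(nulls, B = 500, seed = 2)
  edges <- classify_edges(feats, model, thr)
  expect_equal(nrow(edges), 22)
  expect_true(all(edges$strength >= 0))
  expect_true(all(edges$significant == (edges$strength > thr$threshold)))
  expect_equal(edges$control, !feats$overlapping)
  expect_equal(edges$sign[21:22], c(1, -1))
  expect_true(all(edges$significant[21:22]))
  expect_true(all(edges$p_value[21:22] < 0.01))
})

test_that("feature extraction selects the strongest protocol and drops single-fly pairs", {
  pt <- data.frame(pair_id = c("a", "a", "b"), pre = "x", post = "y",
                   n_pulses = c(30, 5, 30), overlapping = c(TRUE, TRUE, FALSE),
                   ItoPeak_norm_scaled = c(0.5, 0.1, 0.2),
                   R_between = c(0.9, 0.8, NA))
  expect_warning(fe <- feature_points(pt), "undefined R_between")
  expect_equal(nrow(fe), 1)
  expect_equal(fe$x1, 0.5)
  fe2 <- feature_points(pt, n_pulses = 5)
  expect_equal(fe2$x1, 0.1)
})
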