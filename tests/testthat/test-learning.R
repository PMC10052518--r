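test_that("standardization centers, scales and drops constant columns", {
  set.seed(1)
  x <- cbind(a = rnorm(200, 5, 2), b = rnorm(200), const = rep(3, 200))
  expect_warning(sc <- fit_scaler(x), "constant")
  expect_setequal(sc$keep, c("a", "b"))
  xs <- apply_scaler(sc, x)
  expect_equal(unname(colMeans(xs)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(xs, 2, sd)), c(1, 1), tolerance = 1e-12)

  # an already standardized column passes through almost unchanged
  z <- scale(rnorm(500))[, 1]
  x2 <- cbind(z = z)
  sc2 <- fit_scaler(x2)
  expect_equal(unname(apply_scaler(sc2, x2)[, 1]), unname(z),
               tolerance = 1e-9)
})

test_that("MLR recovers exact linear data and SVR respects its tube", {
  set.seed(2)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(x %*% c(1.5, -2, 0.5)) + 4
  m <- fit_regressor(x, y, "MLR")
  expect_equal(unname(stats::coef(m$fit)[-1]), c(1.5, -2, 0.5),
               tolerance = 1e-8)
  expect_equal(predict(m, x), y, tolerance = 1e-8)

  yc <- rep(2.5, 100)
  sv <- fit_regressor(x, yc, "SVR")
  expect_true(all(abs(predict(sv, x) - 2.5) <= 0.1 + 1e-6))

  rf <- fit_regressor(x, y, "RFR", seed = 3)
  r2 <- function(yy, pp) 1 - sum((yy - pp)^2) / sum((yy - mean(yy))^2)
  expect_gt(r2(y, predict(rf, x)), 0.5)
})

test_that("every algorithm ranks the informative feature first", {
  rt <- make_regression_table(n = 500, weights = 3, n_noise = 5,
                              sigma = 0.1, seed = 2)
  sc <- fit_scaler(rt$x)
  xs <- apply_scaler(sc, rt$x)
  for (alg in c("MLR", "SVR", "RFR", "MLP")) {
    m <- fit_regressor(xs, rt$y, alg, seed = 1)
    imp <- importance_rank(m, xs, rt$y, seed = 1)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_equal(names(which.max(imp)), "f01",
                 info = paste("algorithm", alg))
    expect_true(all(imp[setdiff(names(imp), "f01")] < 0.05),
                info = paste("algorithm", alg))
  }
})

test_that("iterative elimination keeps the informative features", {
  rt <- make_regression_table(n = 500, weights = c(3, 2, 1), n_noise = 7,
                              sigma = 0.1, seed = 1)
  sel <- eliminate_features(rt$x, rt$y, "MLR", k = 10, seed = 1)
  expect_true(all(rt$informative %in% sel))
  expect_lt(length(sel), ncol(rt$x))

  # degenerate controls
  expect_error(eliminate_features(rt$x[, 1, drop = FALSE], rt$y))
  only_one <- eliminate_features(rt$x, rt$y, "MLR", k = 10, seed = 1,
                                 tol = Inf)
  expect_length(only_one, 1)
})

test_that("correlation pruning drops exactly one member of each r=1 pair", {
  rt <- make_regression_table(n = 300, weights = c(2, 1), n_noise = 3,
                              sigma = 0.5, seed = 5)
  x <- cbind(rt$x, f01_copy = rt$x[, "f01"], f03_copy = rt$x[, "f03"])
  kept <- correlation_prune(x, 0.9)
  expect_equal(length(kept), ncol(x) - 2)
  expect_equal(sum(c("f01", "f01_copy") %in% kept), 1)
  expect_equal(sum(c("f03", "f03_copy") %in% kept), 1)
  # importance steers which member survives
  imp <- stats::setNames(rep(1, ncol(x)), colnames(x))
  imp["f01"] <- 0.01
  expect_false("f01" %in% correlation_prune(x, 0.9, importance = imp))
  # idempotence
  expect_identical(correlation_prune(x[, kept], 0.9), kept)
  # independent columns survive
  ind <- make_regression_table(n = 1000, weights = 0, n_noise = 9,
                               sigma = 1, seed = 3)
  expect_length(correlation_prune(ind$x, 0.9), 10)
})

test_that("cross-validation is leakage-free, balanced and calibrated", {
  rt <- make_regression_table(n = 200, weights = c(1, 1), n_noise = 2,
                              sigma = 0, seed = 7)
  cv <- cross_validate(rt$x, rt$y, "MLR", k = 10, seed = 1)
  expect_equal(cv$k, 10)
  expect_equal(nrow(cv$folds), 10)
  expect_gte(cv$mean_r2, 0.999)

  fold <- fcaffinity:::.fold_assign(203, 10, seed = 1)
  expect_lte(diff(range(table(fold))), 1)

  # signal fraction 0.8: R2 should estimate it
  r2s <- vapply(1:10, function(s) {
    n <- 1000
    set.seed(100 + s)
    x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    y <- drop(x %*% c(sqrt(2), sqrt(2))) + rnorm(n, 0, 1)
    cross_validate(x, y, "MLR", k = 10, seed = s)$mean_r2
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.8), 0.05)
})

test_that("cross-validated fit degrades monotonically with noise", {
  set.seed(11)
  x <- matrix(rnorm(400 * 3), 400, 3, dimnames = list(NULL, c("a", "b", "c")))
  mu <- drop(x %*% c(1, -1, 0.5))
  mean_r2 <- vapply(c(0, 0.1, 0.3, 1.0), function(s) {
    mean(vapply(1:10, function(rep) {
      set.seed(1000 * rep + round(100 * s))
      y <- mu + rnorm(400, 0, s)
      cross_validate(x, y, "MLR", k = 10, seed = rep)$mean_r2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) <= 0))
})

test_that("shuffling labels destroys the fit; identity shuffle is a no-op", {
  rt <- make_regression_table(n = 300, weights = c(2, 1), n_noise = 3,
                              sigma = 0.2, seed = 9)
  cv <- cross_validate(rt$x, rt$y, "MLR", k = 10, seed = 2)
  for (s in 1:5) {
    sh <- shuffled_control(rt$x, rt$y, "MLR", k = 10, seed = s)
    expect_lte(sh$mean_r2, 0.05)
    expect_gte(sh$mean_mae, cv$mean_mae)
  }
  ident <- shuffled_control(rt$x, rt$y, "MLR", k = 10, seed = 2,
                            permutation = seq_along(rt$y))
  expect_equal(ident$folds, cv$folds, tolerance = 1e-12)
})

test_that("MLR coefficients recover planted weights within 3 SE", {
  rt <- make_regression_table(n = 500, weights = c(1.2, -0.7, 0.3),
                              n_noise = 4, sigma = 0.3, seed = 13)
  fit <- stats::lm(rt$y ~ rt$x[, rt$informative])
  cf <- summary(fit)$coefficients[-1, ]
  z <- (cf[, "Estimate"] - rt$weights) / cf[, "Std. Error"]
  expect_true(all(abs(z) < 3))
})
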