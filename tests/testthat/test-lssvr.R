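# independent dense-solve oracle: Schur-complement block elimination of the
# LS-SVM system (never the packaged solver's code path)
lssvr_oracle_predict <- function(X, y, h, gamma, Xnew) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  Ns <- sweep(sweep(Xnew, 2, ctr), 2, scl, `/`)
  d2 <- function(A, B) outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  K <- exp(-pmax(d2(Xs, Xs), 0) / h^2)
  M <- K + diag(nrow(Xs)) / gamma
  Minv <- solve(M)
  one <- rep(1, nrow(Xs))
  b <- drop(crossprod(one, Minv %*% y) / crossprod(one, Minv %*% one))
  alpha <- drop(Minv %*% (y - b * one))
  drop(exp(-pmax(d2(Ns, Xs), 0) / h^2) %*% alpha + b)
}

test_that("LS-SVR equals the block-elimination dense-solve oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:50, 1); p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rnorm(n, 100, 30)
    h <- runif(1, 0.5, 5); gamma <- 10^runif(1, -1, 3)
    m <- train_lssvr(X, y, h, gamma)
    Xnew <- matrix(rnorm(20 * p), 20, p, dimnames = list(NULL, paste0("f", 1:p)))
    expect_lt(max(abs(predict(m, Xnew) - lssvr_oracle_predict(X, y, h, gamma, Xnew))),
              1e-8)
  }
})

test_that("LS-SVR interpolates noiseless data as gamma grows", {
  set.seed(3)
  X <- matrix(rnorm(5), 5, 1, dimnames = list(NULL, "x"))
  y <- 3 * X[, 1] + 2
  m <- train_lssvr(X, y, h = 2, gamma = 1e8)
  expect_lt(max(abs(predict(m, X) - y)), 1e-4)
})

test_that("constant response collapses to the bias term", {
  set.seed(4)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  m <- train_lssvr(X, rep(7, 10), h = 1, gamma = 10)
  expect_lt(max(abs(m$alpha)), 1e-8)
  expect_equal(m$b, 7, tolerance = 1e-8)
  expect_equal(predict(m, X), rep(7, 10), tolerance = 1e-8)
})

test_that("predictions are invariant to feature order and affine rescaling", {
  set.seed(6)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20, 50, 10)
  m1 <- train_lssvr(X, y, 1.5, 50)
  Xnew <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  p1 <- predict(m1, Xnew)
  expect_equal(predict(m1, Xnew[, c("c", "a", "b")]), p1)
  # affine rescaling of inputs is absorbed by standardization
  X2 <- sweep(sweep(X, 2, c(2, 0.5, 10), `*`), 2, c(1, -4, 100), `+`)
  m2 <- train_lssvr(X2, y, 1.5, 50)
  X2new <- sweep(sweep(Xnew, 2, c(2, 0.5, 10), `*`), 2, c(1, -4, 100), `+`)
  expect_equal(predict(m2, X2new), p1, tolerance = 1e-10)
})

test_that("grid search honours trivial grids, seeds and fold feasibility", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20, 100, 20)
  gs <- grid_search_cv(X, y, h_grid = 2, gamma_grid = 7, k = 5, seed = 1)
  expect_equal(gs$h, 2); expect_equal(gs$gamma, 7)
  g1 <- grid_search_cv(X, y, test_h_grid, test_gamma_grid, k = 5, seed = 42)
  g2 <- grid_search_cv(X, y, test_h_grid, test_gamma_grid, k = 5, seed = 42)
  expect_identical(g1[c("h", "gamma")], g2[c("h", "gamma")])
  expect_error(grid_search_cv(X[1:4, ], y[1:4], 1, 1, k = 10),
               class = "firecarb_fold_infeasible")
})

test_that("cross validation lands near the noise-optimal bandwidth", {
  set.seed(15)
  n <- 120
  X <- matrix(runif(n, -2, 2), n, 1, dimnames = list(NULL, "x"))
  f <- function(x) sin(2 * x) * 10
  y <- f(X[, 1]) + rnorm(n, 0, 1)
  h_grid <- 10^seq(-1.5, 1.5, length.out = 9)
  # oracle: bandwidth minimizing the true error on a dense noiseless test set
  Xt <- matrix(seq(-2, 2, length.out = 300), ncol = 1, dimnames = list(NULL, "x"))
  true_err <- vapply(h_grid, function(h) {
    m <- train_lssvr(X, y, h, 100)
    mean((predict(m, Xt) - f(Xt[, 1]))^2)
  }, numeric(1))
  h_star <- h_grid[which.min(true_err)]
  gs <- grid_search_cv(X, y, h_grid, gamma_grid = 100, k = 10, seed = 2)
  expect_lte(abs(log10(gs$h) - log10(h_star)), log10(h_grid[2] / h_grid[1]) + 1e-9)
})

test_that("feature selection: expert subsets, planted signals, seeded search", {
  set.seed(20)
  X <- as.data.frame(matrix(rnorm(300), 100, 3))
  names(X) <- c("AUCW", "H50", "junk")
  expect_equal(feature_select(X, rnorm(100), "expert"), c("AUCW", "H50"))
  expect_error(feature_select(X[c("AUCW", "junk")], rnorm(100), "expert",
                              expert_features = c("AUCW", "H50")), "H50")
  # stepwise recovers a planted single-feature signal first
  y <- 5 * X$H50 + rnorm(100, 0, 0.5)
  sel <- feature_select(X, y, "stepwise")
  expect_equal(sel[1], "H50")
  # degenerate evolutionary search returns the seeded random subset
  s1 <- feature_select(X, y, "evolutionary", population = 1, generations = 1, seed = 5)
  s2 <- feature_select(X, y, "evolutionary", population = 1, generations = 1, seed = 5)
  expect_identical(s1, s2)
  # with a real budget it keeps the informative feature
  s3 <- feature_select(X, y, "evolutionary", population = 12, generations = 6, seed = 3)
  expect_true("H50" %in% s3)
})

test_that("fit statistics match their definitions and the printed example", {
  y <- c(1, 2, 3, 4)
  expect_equal(fit_metrics(y, y, 1)$r2, 1)
  expect_equal(fit_metrics(y, y, 1)$rmse, 0)
  expect_equal(fit_metrics(y, rep(mean(y), 4), 1)$r2, 0)
  expect_error(fit_metrics(rep(2, 4), y, 1), class = "firecarb_zero_variance")
  # a model with RMSE 59.98 Mg/ha over stands averaging 195.8 Mg/ha
  y_obs <- 195.8 + c(-80, 80, -80, 80)
  y_hat <- y_obs + 59.98 * c(1, -1, -1, 1)
  fm <- fit_metrics(y_obs, y_hat, 1)
  expect_equal(fm$rmse, 59.98)
  expect_equal(fm$rel_rmse, 30.63, tolerance = 0.005)
})

test_that("calibration/validation split is stratified, exhaustive and seeded", {
  set.seed(30)
  y <- runif(514, 20, 600)
  sp <- split_calibration_validation(y, 0.7, seed = 9)
  expect_length(sp$cal, 360)
  expect_length(sp$val, 154)
  expect_length(intersect(sp$cal, sp$val), 0)
  expect_setequal(c(sp$cal, sp$val), seq_along(y))
  sp2 <- split_calibration_validation(y, 0.7, seed = 9)
  expect_identical(sp, sp2)
  expect_warning(split_calibration_validation(y, 1, seed = 1), "empty")
  # stratification: calibration set covers the response range
  expect_lt(min(y[sp$cal]), quantile(y, 0.05))
  expect_gt(max(y[sp$cal]), quantile(y, 0.95))
})

test_that("histogram-stratified sampling respects mask and covers the range", {
  set.seed(40)
  agb <- matrix(runif(2500, 0, 600), 50, 50)
  mask <- matrix(runif(2500) < 0.6, 50, 50)
  idx <- stratified_histogram_sample(agb, mask, n = 300, bins = 10, seed = 3)
  expect_length(idx, 300)
  expect_true(all(mask[idx]))
  expect_length(unique(idx), 300)
  # spans at least 95% of the masked biomass range
  rng <- range(agb[mask])
  expect_lt(diff(range(agb[idx])) / diff(rng), 1.0 + 1e-9)
  expect_gt(diff(range(agb[idx])) / diff(rng), 0.95)
  # n equal to the masked count returns every masked pixel
  small <- matrix(runif(16), 4, 4)
  all_idx <- stratified_histogram_sample(small, small > 0, n = 16, seed = 1)
  expect_setequal(all_idx, 1:16)
  expect_error(stratified_histogram_sample(small, small > 2, n = 4),
               class = "firecarb_insufficient_pixels")
})
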