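# pairwise squared Euclidean distances between rows of A and B
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Train a least-squares support-vector regression (LS-SVR) model
#'
#' Solves the LS-SVM dual linear system
#' \deqn{[[0, 1^T], [1, K + I/\gamma]] [b; \alpha] = [0; y]}
#' with the Gaussian radial basis kernel
#' `K_ij = exp(-||x_i - x_j||^2 / h^2)` on internally standardized
#' features. Predictions are `f(x) = sum_i alpha_i K(x, x_i) + b`.
#'
#' @param X Numeric matrix or data frame of features (n >= 3 rows).
#' @param y Numeric response (AGB, Mg/ha).
#' @param h Kernel bandwidth (> 0), in standardized feature space.
#' @param gamma Penalty parameter (> 0); larger values fit the training
#'   data more closely.
#' @return An object of class `fc_lssvr` with dual coefficients `alpha`,
#'   bias `b`, the standardized training matrix, feature names and
#'   standardization constants.
#' @export
train_lssvr <- function(X, y, h, gamma) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 3, length(y) == nrow(X), h > 0, gamma > 0)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  n <- nrow(Xs)
  K <- exp(-cross_dist2(Xs, Xs) / h^2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  sol <- tryCatch(solve(A, c(0, y)), error = function(e)
    stop_fc("firecarb_singular_system",
            "ill-conditioned LS-SVR system; raise gamma or h"))
  structure(list(h = h, gamma = gamma, alpha = sol[-1], b = sol[1],
                 X = Xs, center = center, scale = scale,
                 features = colnames(X), y_range = range(y)),
            class = "fc_lssvr")
}

#' Predict from an LS-SVR model
#'
#' @param object An `fc_lssvr` model.
#' @param newdata Matrix or data frame with the model's features (matched
#'   by name when available, so feature order is irrelevant).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fc_lssvr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    missing <- setdiff(object$features, colnames(newdata))
    if (length(missing))
      stop("feature mismatch; missing: ", paste(missing, collapse = ", "))
    newdata <- newdata[, object$features, drop = FALSE]
  }
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  Kn <- exp(-cross_dist2(Xs, object$X) / object$h^2)
  drop(Kn %*% object$alpha + object$b)
}

# default hyperparameter grids: 15 log-spaced values each
default_h_grid <- function() 10^seq(log10(0.1), log10(100), length.out = 15)
default_gamma_grid <- function() 10^seq(log10(0.1), log10(1e4), length.out = 15)

# seeded k-fold assignment stratified by deciles of y
stratified_folds <- function(y, k, seed) {
  with_seed(seed, "folds", {
    dec <- cut(rank(y, ties.method = "first"), breaks = k * 0 + 10, labels = FALSE)
    fold <- integer(length(y))
    nxt <- 0L
    for (d in unique(dec)) {
      idx <- sample(which(dec == d))
      fold[idx] <- ((seq_along(idx) + nxt) %% k) + 1L
      nxt <- nxt + length(idx)
    }
    fold
  })
}

#' Grid-search hyperparameters by tenfold cross validation
#'
#' Evaluates every `(h, gamma)` pair on seeded folds stratified by
#' response deciles and returns the pair minimizing mean CV MSE. Ties go
#' to the smallest `gamma`, then the smallest `h` (preferring smoother,
#' more regularized models).
#'
#' @inheritParams train_lssvr
#' @param h_grid,gamma_grid Candidate values (default 15 log-spaced
#'   values, `h` in `[0.1, 100]`, `gamma` in `[0.1, 1e4]`).
#' @param k Number of folds (default 10); requires `n >= k`.
#' @param seed Integer seed for the fold assignment.
#' @param repeats Number of repeated fold assignments averaged into the
#'   CV score. The default repeats the CV on small samples (roughly
#'   `400/n` times), where a single fold draw makes the selection noisy,
#'   and runs once on large ones.
#' @return List with `h`, `gamma`, and the full `cv` table
#'   (`h`, `gamma`, `mse`).
#' @export
grid_search_cv <- function(X, y, h_grid = default_h_grid(),
                           gamma_grid = default_gamma_grid(), k = 10, seed = 1,
                           repeats = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(h_grid) > 0, length(gamma_grid) > 0)
  if (n < k)
    stop_fc("firecarb_fold_infeasible", sprintf("n = %d < k = %d folds", n, k))
  if (is.null(repeats)) repeats <- max(1L, ceiling(400 / n))
  folds <- lapply(seq_len(repeats), function(r)
    stratified_folds(y, k, seed + (r - 1L) * 7919L))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd); scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  D2 <- cross_dist2(Xs, Xs)

  grid <- expand.grid(h = sort(h_grid), gamma = sort(gamma_grid))
  grid$mse <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    h <- grid$h[gi]; gamma <- grid$gamma[gi]
    K <- exp(-D2 / h^2)
    sse <- 0
    for (fold in folds) for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      ntr <- sum(tr)
      A <- rbind(c(0, rep(1, ntr)), cbind(1, K[tr, tr] + diag(ntr) / gamma))
      sol <- tryCatch(solve(A, c(0, y[tr])), error = function(e) NULL)
      if (is.null(sol)) { sse <- Inf; break }
      pred <- drop(K[te, tr, drop = FALSE] %*% sol[-1] + sol[1])
      sse <- sse + sum((y[te] - pred)^2)
    }
    grid$mse[gi] <- sse / (n * repeats)
  }
  best <- grid[order(grid$mse, grid$gamma, grid$h), ][1, ]
  list(h = best$h, gamma = best$gamma, cv = grid)
}

#' Feature selection for the biomass models
#'
#' Three strategies:
#' * `expert`: return a fixed, field-knowledge subset (default the
#'   headline LiDAR pair `AUCW` + `H50`; for the optical models the
#'   reflective bands 2-6, NDII and elevation).
#' * `stepwise`: forward-backward selection on linear fits with entry /
#'   exit p-values 0.05 / 0.10.
#' * `evolutionary`: seeded genetic search over feature subsets with
#'   k-fold CV MSE of a linear fit as fitness.
#'
#' @inheritParams train_lssvr
#' @param method One of `"expert"`, `"stepwise"`, `"evolutionary"`.
#' @param expert_features Character vector used by the expert method.
#' @param population,generations,mutation Evolutionary-search settings.
#' @param seed Integer seed (stepwise is deterministic).
#' @return Character vector of selected feature names.
#' @export
feature_select <- function(X, y, method = c("expert", "stepwise", "evolutionary"),
                           expert_features = c("AUCW", "H50"),
                           population = 30, generations = 25, mutation = 0.1,
                           seed = 1) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  if (method == "expert") {
    missing <- setdiff(expert_features, names(X))
    if (length(missing))
      stop("expert feature(s) not in X: ", paste(missing, collapse = ", "))
    return(expert_features)
  }
  if (method == "stepwise") {
    selected <- character(0)
    repeat {
      changed <- FALSE
      cand <- setdiff(names(X), selected)
      if (length(cand)) {
        pv <- vapply(cand, function(v) {
          fit <- stats::lm(y ~ ., data = X[, c(selected, v), drop = FALSE])
          cf <- summary(fit)$coefficients
          if (v %in% rownames(cf)) cf[v, 4] else 1
        }, numeric(1))
        if (min(pv) < 0.05) {
          selected <- c(selected, names(which.min(pv)))
          changed <- TRUE
        }
      }
      if (length(selected) > 1) {
        fit <- stats::lm(y ~ ., data = X[, selected, drop = FALSE])
        cf <- summary(fit)$coefficients
        pv <- cf[intersect(selected, rownames(cf)), 4]
        if (length(pv) && max(pv) > 0.10) {
          selected <- setdiff(selected, names(which.max(pv)))
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    return(selected)
  }
  # evolutionary: binary-mask GA, CV-MSE fitness on linear fits
  with_seed(seed, "ga", {
    p <- ncol(X)
    fold <- stratified_folds(y, k = min(5, length(y)), seed = seed)
    fitness <- function(mask) {
      if (!any(mask)) return(Inf)
      sse <- 0
      for (f in unique(fold)) {
        tr <- fold != f
        fit <- stats::lm(y[tr] ~ ., data = X[tr, mask, drop = FALSE])
        pred <- stats::predict(fit, newdata = X[!tr, mask, drop = FALSE])
        sse <- sse + sum((y[!tr] - pred)^2)
      }
      sse / length(y)
    }
    pop <- lapply(seq_len(population), function(i) stats::runif(p) < 0.5)
    fit_v <- vapply(pop, fitness, numeric(1))
    for (g in seq_len(generations - 1)) {
      ord <- order(fit_v)
      keep <- pop[ord[seq_len(max(2, population %/% 2))]]
      children <- lapply(seq_len(population - length(keep)), function(i) {
        pa <- keep[[sample.int(length(keep), 1)]]
        pb <- keep[[sample.int(length(keep), 1)]]
        child <- ifelse(stats::runif(p) < 0.5, pa, pb)
        flip <- stats::runif(p) < mutation
        xor(child, flip)
      })
      pop <- c(keep, children)
      fit_v <- vapply(pop, fitness, numeric(1))
    }
    names(X)[pop[[which.min(fit_v)]]]
  })
}

#' Fit statistics for observed vs predicted biomass
#'
#' `R2 = 1 - SSE/SST` (penalizing bias, not the squared correlation),
#' `R2adj = 1 - (1 - R2)(n - 1)/(n - p - 1)`, `RMSE = sqrt(SSE/n)` and
#' `relRMSE = 100 RMSE / mean(observed)`.
#'
#' @param y_obs,y_hat Observed and predicted values (equal length,
#'   `n > p + 1`).
#' @param p Number of predictors.
#' @return Named list: `r2`, `r2_adj`, `rmse`, `rel_rmse`, `n`, `p`.
#' @export
fit_metrics <- function(y_obs, y_hat, p) {
  n <- length(y_obs)
  stopifnot(length(y_hat) == n, n > p + 1)
  sst <- sum((y_obs - mean(y_obs))^2)
  if (sst == 0)
    stop_fc("firecarb_zero_variance", "constant observations: R2 undefined")
  sse <- sum((y_obs - y_hat)^2)
  r2 <- 1 - sse / sst
  list(r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       rmse = sqrt(sse / n), rel_rmse = 100 * sqrt(sse / n) / mean(y_obs),
       n = n, p = p)
}

#' Split samples into calibration and validation sets
#'
#' Seeded random split stratified by response deciles; the calibration
#' size is `round(fraction * n)` and the two sets are disjoint and
#' exhaustive.
#'
#' @param y Numeric response driving the stratification (`n >= 10`).
#' @param fraction Calibration fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `cal` and `val`; `val` may be
#'   empty (with a warning) when `fraction = 1`.
#' @export
split_calibration_validation <- function(y, fraction = 0.7, seed = 1) {
  n <- length(y)
  stopifnot(n >= 10, fraction > 0, fraction <= 1)
  n_cal <- round(fraction * n)
  with_seed(seed, "split", {
    dec <- cut(rank(y, ties.method = "first"), breaks = 10, labels = FALSE)
    quota <- table(dec) * fraction
    take <- floor(quota)
    rem <- n_cal - sum(take)
    if (rem > 0) {
      extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1
    } else if (rem < 0) {
      drop_from <- order(quota - take)[seq_len(-rem)]
      take[drop_from] <- pmax(take[drop_from] - 1, 0)
    }
    cal <- unlist(lapply(seq_along(take), function(i) {
      idx <- which(dec == as.integer(names(take)[i]))
      sample(idx, min(take[i], length(idx)))
    }), use.names = FALSE)
    # top up / trim in case stratum capacities clipped the quotas
    if (length(cal) < n_cal)
      cal <- c(cal, sample(setdiff(seq_len(n), cal), n_cal - length(cal)))
    val <- setdiff(seq_len(n), cal)
    if (!length(val)) warning("validation set is empty (fraction = 1)")
    list(cal = sort(cal), val = sort(val))
  })
}

#' Histogram-stratified pixel sampling for model transfer
#'
#' Randomly selects `n` pixels from the masked area (unburned and
#' low-severity cells), allocating draws across equal-width biomass
#' histogram bins (uniform per-bin quota, remainder to the densest bins)
#' so the sample covers the full biomass range. Bins with too few pixels
#' contribute what they have; the shortfall is reallocated to dense bins
#' with a warning.
#'
#' @param agb Biomass matrix (Mg/ha).
#' @param mask Logical matrix, `TRUE` where sampling is allowed.
#' @param n Sample size (default 514).
#' @param bins Number of histogram bins (default 10).
#' @param seed Integer seed.
#' @return Integer vector of sampled cell indices (column-major).
#' @export
stratified_histogram_sample <- function(agb, mask, n = 514, bins = 10, seed = 1) {
  idx <- which(mask & !is.na(agb))
  if (length(idx) < n)
    stop_fc("firecarb_insufficient_pixels",
            sprintf("only %d masked pixels for n = %d", length(idx), n))
  if (length(idx) == n) return(idx)
  with_seed(seed, "pixsample", {
    v <- agb[idx]
    edges <- seq(min(v), max(v), length.out = bins + 1)
    bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), bins)
    avail <- tabulate(bin, bins)
    quota <- rep(n %/% bins, bins)
    quota[order(avail, decreasing = TRUE)[seq_len(n %% bins)]] <-
      quota[1] + 1L
    take <- pmin(quota, avail)
    short <- n - sum(take)
    if (short > 0) {
      warning(sprintf("%d draws reallocated from sparse to dense biomass bins", short))
      while (short > 0) {
        room <- which(avail > take)
        b <- room[which.max(avail[room] - take[room])]
        add <- min(short, avail[b] - take[b])
        take[b] <- take[b] + add
        short <- short - add
      }
    }
    out <- unlist(lapply(seq_len(bins), function(b) {
      if (take[b] == 0) return(integer(0))
      pool <- idx[bin == b]
      if (length(pool) == 1) pool else sample(pool, take[b])
    }), use.names = FALSE)
    sort(out)
  })
}
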