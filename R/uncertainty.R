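#' Compose the error of a two-step regression chain
#'
#' The spatio-temporal extrapolation stacks two models (field -> LiDAR
#' biomass, LiDAR biomass -> optical biomass). Assuming independent step
#' errors, the overall modeling error is
#' `sigma = sqrt(RMSE1^2 + RMSE2^2)`, applied identically to absolute
#' (Mg/ha) and relative (%) RMSEs.
#'
#' @param rmse1,rmse2 Step errors (>= 0), both on the same scale.
#' @return Composed error on that scale.
#' @export
compose_two_step_error <- function(rmse1, rmse2) {
  stopifnot(all(rmse1 >= 0), all(rmse2 >= 0))
  sqrt(rmse1^2 + rmse2^2)
}

#' Fit an exponential correlogram to a residual raster
#'
#' Estimates the spatial autocorrelation of per-pixel model error:
#' empirical correlations are accumulated per distance bin from all
#' pixel-pair offsets up to `max_lag_m` (NA pixels skipped), then an
#' exponential model `rho(d) = exp(-d / phi)` is fitted by count-weighted
#' least squares. `rho(0) = 1` by construction and the model is
#' non-increasing.
#'
#' @param residual Residual matrix (at least 200 non-NA pixels).
#' @param cell_size_m Grid cell size (m).
#' @param max_lag_m Largest lag distance considered (default 10 cells).
#' @param n_lag_bins Number of distance bins.
#' @return An `fc_correlogram`: range `phi` (m), and the empirical table
#'   `empirical` (`distance_m`, `rho`, `n_pairs`). Evaluate with
#'   [correlogram_rho()].
#' @export
fit_correlogram <- function(residual, cell_size_m = 30,
                            max_lag_m = 10 * cell_size_m, n_lag_bins = 10) {
  ok <- is.finite(residual)
  if (sum(ok) < 200)
    stop_fc("firecarb_too_few_cells",
            sprintf("%d residual pixels (need >= 200)", sum(ok)))
  mu <- mean(residual[ok]); v <- mean((residual[ok] - mu)^2)
  e <- residual - mu
  e[!ok] <- NA_real_
  nr <- nrow(e); nc <- ncol(e)
  max_off <- floor(max_lag_m / cell_size_m)
  binw <- max_lag_m / n_lag_bins
  sum_prod <- numeric(n_lag_bins); n_pair <- numeric(n_lag_bins)
  sum_dist <- numeric(n_lag_bins)
  for (dr in 0:max_off) for (dc in (-max_off):max_off) {
    if (dr == 0 && dc <= 0) next               # count each ordered pair once
    d <- cell_size_m * sqrt(dr^2 + dc^2)
    if (d > max_lag_m) next
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- e[r1, c1, drop = FALSE]
    b <- e[r1 + dr, c1 + dc, drop = FALSE]
    prod <- a * b
    k <- sum(is.finite(prod))
    if (k == 0) next
    bin <- min(ceiling(d / binw), n_lag_bins)
    sum_prod[bin] <- sum_prod[bin] + sum(prod, na.rm = TRUE)
    n_pair[bin] <- n_pair[bin] + k
    sum_dist[bin] <- sum_dist[bin] + k * d
  }
  if (sum(n_pair) == 0)
    stop_fc("firecarb_no_pairs", "no positive-lag pixel pairs within max_lag_m")
  use <- n_pair > 0
  emp <- data.frame(distance_m = sum_dist[use] / n_pair[use],
                    rho = pmin(pmax(sum_prod[use] / (n_pair[use] * v), 0), 1),
                    n_pairs = n_pair[use])
  obj <- function(phi) sum(emp$n_pairs * (emp$rho - exp(-emp$distance_m / phi))^2)
  phi <- stats::optimize(obj, c(1e-3, 100 * max_lag_m))$minimum
  structure(list(phi = phi, empirical = emp, model = "exponential"),
            class = "fc_correlogram")
}

#' Evaluate a correlogram model at given distances
#'
#' @param cg An `fc_correlogram` (or a plain function of distance).
#' @param d Distances (m).
#' @return Correlations in `[0, 1]`; `rho(0) = 1`.
#' @export
correlogram_rho <- function(cg, d) {
  if (is.function(cg)) return(pmin(pmax(cg(d), 0), 1))
  pmin(pmax(exp(-d / cg$phi), 0), 1)
}

#' Standard error of a stratum mean under spatial autocorrelation
#'
#' `Var(mean) = (sigma^2 / n^2) * sum_ij rho(d_ij)`, evaluated through
#' distance classes: pairwise distances are tabulated into their unique
#' values and `rho` is evaluated once per class, which is exactly
#' equivalent to the full double loop. Reduces to `sigma^2/n` for
#' uncorrelated error and to `sigma^2` under perfect correlation.
#'
#' @param sigma Per-pixel residual standard deviation (Mg/ha).
#' @param coords Two-column matrix of pixel coordinates (m).
#' @param rho An `fc_correlogram` or a function of distance (m) with
#'   `rho(0) = 1`.
#' @return Standard error of the stratum mean.
#' @export
stratum_mean_se <- function(sigma, coords, rho) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 1, ncol(coords) == 2)
  if (n == 1) return(sigma)
  d <- stats::dist(coords)
  cls <- table(factor(round(as.numeric(d), 9)))
  du <- as.numeric(names(cls))
  S <- n + 2 * sum(as.numeric(cls) * correlogram_rho(rho, du))
  sqrt(sigma^2 * S / n^2)
}

#' Variance of a difference of correlated estimates
#'
#' `Var(pre - post) = Var(pre) + Var(post) - 2 Cov(pre, post)`, floored
#' at 0 with a warning (a tiny negative value can arise when the
#' covariance is estimated from finite reference pairs).
#'
#' @param var_pre,var_post Variances of the two estimates.
#' @param cov Their covariance (estimated from paired residuals).
#' @return Variance of the difference.
#' @export
difference_variance <- function(var_pre, var_post, cov = 0) {
  v <- var_pre + var_post - 2 * cov
  if (any(v < 0)) {
    warning("negative difference variance floored at 0")
    v <- pmax(v, 0)
  }
  v
}
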