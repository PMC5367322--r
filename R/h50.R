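#' Fit the unburned H50-AUCW reference curve
#'
#' Over unburned canopy cells, the amount of canopy material (AUCW)
#' follows the canopy height percentile H50 along a tight monotone
#' curve; fire breaks this relationship by removing canopy returns while
#' standing dead trees (snags) keep H50 high. The reference curve is a
#' power law `AUCW = a * H50^b` fitted by least squares on log-log
#' values of unburned cells; cells with non-positive H50 or AUCW are
#' excluded from the log fit.
#'
#' @param h50,aucw Numeric vectors of per-cell metrics over unburned
#'   cells (at least 30 usable cells).
#' @return Object of class `fc_h50_ref`: coefficients `a`, `b`, the
#'   log-log fit R-squared and the number of cells used. The curve is
#'   evaluated with [predict_aucw()].
#' @export
fit_h50_aucw_reference <- function(h50, aucw) {
  ok <- is.finite(h50) & is.finite(aucw) & h50 > 0 & aucw > 0
  if (sum(ok) < 30)
    stop_fc("firecarb_too_few_cells",
            sprintf("only %d usable unburned canopy cells (need >= 30)", sum(ok)))
  lx <- log(h50[ok]); ly <- log(aucw[ok])
  if (stats::sd(lx) < 1e-8)
    stop_fc("firecarb_degenerate_fit", "H50 is constant: reference curve degenerate")
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  structure(list(a = exp(stats::coef(fit)[[1]]), b = stats::coef(fit)[[2]],
                 r2 = r2, n = sum(ok)),
            class = "fc_h50_ref")
}

#' Expected AUCW at a given H50 under the unburned reference
#'
#' @param ref An `fc_h50_ref`.
#' @param h50 Numeric vector of H50 values.
#' @return Expected AUCW (`a * H50^b`; 0 where `H50 <= 0`).
#' @export
predict_aucw <- function(ref, h50) {
  out <- ifelse(h50 > 0, ref$a * h50^ref$b, 0)
  as.numeric(out)
}

#' Correct fire-biased H50 across the burned area
#'
#' For every cell inside the burn perimeter (all severity levels), the
#' observed AUCW is compared with the AUCW expected for the observed H50
#' under the unburned reference; the deficit re-weights H50:
#' `w = min(1, AUCW_obs / g(H50_obs))`, `H50_corr = w * H50_obs`. Cells
#' outside the perimeter are untouched, a cell on the reference curve is
#' unchanged (`w = 1`), a fully defoliated cell (`AUCW = 0`) drops to
#' `H50 = 0`, and `g(H50) = 0` yields `w = 1` (no evidence of loss). The
#' weight is capped at 1: fire only ever removes canopy.
#'
#' @param metrics Metric stack from [rasterize_metrics()].
#' @param ref An `fc_h50_ref` reference curve.
#' @param burned Logical matrix, `TRUE` inside the burn perimeter.
#' @return The metric stack with `H50` corrected (and the weight matrix
#'   attached as attribute `"h50_weight"`).
#' @export
correct_h50 <- function(metrics, ref, burned) {
  h50 <- metrics$H50
  stopifnot(identical(dim(h50), dim(burned)))
  expected <- predict_aucw(ref, h50)
  w <- matrix(1, nrow(h50), ncol(h50))
  idx <- which(burned & is.finite(h50) & expected > 0)
  w[idx] <- pmin(1, metrics$AUCW[idx] / expected[idx])
  metrics$H50 <- h50 * w
  attr(metrics, "h50_weight") <- w
  metrics
}

#' Biomass map from (corrected) LiDAR metrics
#'
#' Applies an already-trained LiDAR LS-SVR model to a metric stack; the
#' model is *not* refitted, so running it on a corrected stack yields the
#' corrected biomass map and unburned cells are bit-identical to the
#' uncorrected map. Predictions are clamped to the calibration response
#' range: an RBF-kernel model extrapolates erratically outside its
#' training hull, and no pixel can credibly hold less biomass than the
#' sparsest or more than the densest calibration stand.
#'
#' @param metrics Metric stack (possibly from [correct_h50()]).
#' @param model A trained `fc_lssvr` whose features are metric names.
#' @param provenance Provenance tag stored on the map (e.g. `"lidar"`,
#'   `"lidar_corrected"`).
#' @return A biomass matrix (Mg/ha) with attribute `provenance`; `NA`
#'   where any input metric is `NA`.
#' @export
agb_map_from_metrics <- function(metrics, model, provenance = "lidar") {
  missing <- setdiff(model$features, names(metrics))
  if (length(missing))
    stop("feature mismatch; metric stack lacks: ", paste(missing, collapse = ", "))
  dims <- dim(metrics[[model$features[1]]])
  X <- vapply(model$features, function(f) as.vector(metrics[[f]]),
              numeric(prod(dims)))
  colnames(X) <- model$features
  ok <- stats::complete.cases(X)
  pred <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    p <- predict(model, X[ok, , drop = FALSE])
    lim <- model$y_range %||% c(0, Inf)
    pred[ok] <- pmin(pmax(p, max(lim[1], 0)), lim[2])
  }
  out <- matrix(pred, dims[1], dims[2])
  attr(out, "provenance") <- provenance
  out
}
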