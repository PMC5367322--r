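#' Join optical features with reference biomass at sampled pixels
#'
#' Builds the training table for the optical (multispectral) biomass
#' models: one row per sampled pixel with the selected feature values
#' and the reference biomass (typically the LiDAR-based map) at that
#' pixel. Rows with any missing value are dropped and the count is
#' recorded as an attribute.
#'
#' @param sample_idx Integer cell indices from
#'   [stratified_histogram_sample()].
#' @param features Feature stack (named list of matrices).
#' @param reference Reference biomass matrix (Mg/ha).
#' @param feature_names Features to extract (default bands 2-6, NDII and
#'   elevation).
#' @return Data frame with the features, `agb`, and `cell` columns;
#'   attribute `n_dropped` counts removed incomplete rows.
#' @export
build_training_table <- function(sample_idx, features, reference,
                                 feature_names = c("B2", "B3", "B4", "B5", "B6",
                                                   "NDII", "elevation")) {
  missing <- setdiff(feature_names, names(features))
  if (length(missing))
    stop("feature mismatch; stack lacks: ", paste(missing, collapse = ", "))
  df <- as.data.frame(lapply(stats::setNames(feature_names, feature_names),
                             function(f) features[[f]][sample_idx]))
  df$agb <- reference[sample_idx]
  df$cell <- sample_idx
  ok <- stats::complete.cases(df)
  dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0)
    stop_fc("firecarb_empty_table", "all training rows incomplete")
  if (nrow(df) < 100)
    warning(sprintf("only %d complete training rows", nrow(df)))
  attr(df, "n_dropped") <- dropped
  df
}

#' Predict a wall-to-wall biomass map from an optical model
#'
#' Applies a trained optical LS-SVR model pixelwise to a feature stack.
#' Predictions are clamped to the calibration response range (kernel
#' models extrapolate erratically outside their training hull); the
#' clamp count is attached as attribute `n_clipped`. Missing feature
#' values propagate to `NA`.
#'
#' @param model A trained `fc_lssvr` on optical features.
#' @param features Feature stack containing all model features.
#' @param provenance Tag for the resulting map (`"landsat_pre"` or
#'   `"landsat_post"`).
#' @return Biomass matrix (Mg/ha) with attributes `provenance` and
#'   `n_clipped`.
#' @export
predict_agb_map <- function(model, features, provenance = "landsat_pre") {
  missing <- setdiff(model$features, names(features))
  if (length(missing))
    stop("feature mismatch; stack lacks: ", paste(missing, collapse = ", "))
  dims <- dim(features[[model$features[1]]])
  X <- vapply(model$features, function(f) as.vector(features[[f]]),
              numeric(prod(dims)))
  colnames(X) <- model$features
  ok <- stats::complete.cases(X)
  pred <- rep(NA_real_, nrow(X))
  if (any(ok)) pred[ok] <- predict(model, X[ok, , drop = FALSE])
  lim <- model$y_range %||% c(0, Inf)
  lo <- max(lim[1], 0)
  n_clip <- sum(pred < lo | pred > lim[2], na.rm = TRUE)
  pred <- pmin(pmax(pred, lo), lim[2])
  out <- matrix(pred, dims[1], dims[2])
  attr(out, "provenance") <- provenance
  attr(out, "n_clipped") <- n_clip
  out
}
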