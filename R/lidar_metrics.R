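#' @name lidar_metrics
#' @title Per-cell LiDAR canopy metrics
#' @description
#' Forty-one per-cell metrics computed from height-normalized
#' discrete-return point clouds on the 30 m grid: 16 canopy-height
#' metrics (percentiles, moments, inter-percentile spreads, canopy depth,
#' cover ratio), 19 intensity metrics (percentiles, moments, accumulated
#' intensity fractions at the height percentiles, energy-based fractional
#' cover, canopy reflection sum and its density-weighted version) and 6
#' pseudowaveform metrics (height of median energy, height/median ratio,
#' mean and quadratic mean canopy height, canopy-height-profile variation
#' coefficient, and the area under the canopy waveform, AUCW).
NULL

# canonical metric order; H50 and AUCW are the headline biomass predictors
fc_metric_names <- c(
  "H25", "H50", "H75", "H90", "H99", "mean_h", "sd_h", "kurt_h", "skew_h",
  "cv_h", "H99_H50", "H99_H25", "H90_H50", "H90_H25", "canopy_depth",
  "cover_ratio",
  "I25", "I50", "I75", "I90", "I99", "mean_i", "kurt_i", "range_i", "skew_i",
  "cv_i", "sd_i", "AI_H25", "AI_H50", "AI_H75", "AI_H90", "AI_H99",
  "FC_energy", "CRS", "dwCRS",
  "HOME", "height_median_ratio", "mean_canopy_height", "QMCH", "CHP_cv", "AUCW")

stop_fc <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Normalize return intensity to a standard sensor range
#'
#' Applies the inverse-square range correction
#' `I_norm = I_raw * (range / reference_range)^2`.
#'
#' @param tile An `fc_tile`.
#' @param reference_range_m Standard range (m); defaults to the tile's
#'   mean range.
#' @return The tile with normalized `intensity` and an attribute
#'   recording the reference range.
#' @export
normalize_intensity <- function(tile, reference_range_m = NULL) {
  if (is.null(tile$range_m) || !length(tile$range_m) || any(tile$range_m <= 0))
    stop_fc("firecarb_no_range", "tile lacks positive sensor ranges; cannot normalize")
  if (is.null(reference_range_m)) reference_range_m <- mean(tile$range_m)
  tile$intensity <- tile$intensity * (tile$range_m / reference_range_m)^2
  attr(tile, "reference_range_m") <- reference_range_m
  tile
}

#' Height metrics of a point-cloud tile
#'
#' Percentiles (linear interpolation between order statistics) and
#' moments are computed over canopy returns (height above the canopy
#' threshold); the cover ratio is the fraction of *all* returns that are
#' canopy. A tile with no canopy returns yields zeros for the canopy
#' statistics and a cover ratio of 0.
#'
#' @param tile An `fc_tile` with at least one return.
#' @param canopy_threshold_m Canopy height threshold (m), default 2.
#' @return Named numeric vector of the 16 height metrics.
#' @export
height_metrics <- function(tile, canopy_threshold_m = 2) {
  h <- tile$height_m
  if (!length(h)) stop_fc("firecarb_empty_tile", "empty tile: missing data cell")
  canopy <- h > canopy_threshold_m
  hc <- h[canopy]
  out <- stats::setNames(numeric(16), fc_metric_names[1:16])
  out["cover_ratio"] <- sum(canopy) / length(h)
  if (length(hc)) {
    q <- stats::quantile(hc, c(0.25, 0.50, 0.75, 0.90, 0.99), names = FALSE, type = 7)
    out[c("H25", "H50", "H75", "H90", "H99")] <- q
    out["mean_h"] <- mean(hc)
    out["sd_h"] <- if (length(hc) > 1) stats::sd(hc) else 0
    out["kurt_h"] <- moment_kurtosis(hc)
    out["skew_h"] <- moment_skewness(hc)
    out["cv_h"] <- safe_cv(hc)
    out["H99_H50"] <- q[5] - q[2]; out["H99_H25"] <- q[5] - q[1]
    out["H90_H50"] <- q[4] - q[2]; out["H90_H25"] <- q[4] - q[1]
    out["canopy_depth"] <- max(hc) - min(hc)
  }
  out
}

#' Intensity metrics of a point-cloud tile
#'
#' Percentiles and moments of canopy-return intensities, accumulated
#' intensity fractions `AI@Hp` (fraction of canopy intensity at or below
#' the height percentile `Hp`), energy fractional cover
#' `FC_energy = canopy energy / total energy`, the canopy reflection sum
#' `CRS` and its density-weighted version `dwCRS = CRS / (returns per m2)`.
#' Zero total intensity defines all energy ratios as 0.
#'
#' @param tile An `fc_tile` with (range-) normalized intensities.
#' @param canopy_threshold_m Canopy height threshold (m), default 2.
#' @return Named numeric vector of the 19 intensity metrics.
#' @export
intensity_metrics <- function(tile, canopy_threshold_m = 2) {
  h <- tile$height_m
  if (!length(h)) stop_fc("firecarb_empty_tile", "empty tile: missing data cell")
  canopy <- h > canopy_threshold_m
  ic <- tile$intensity[canopy]
  hc <- h[canopy]
  out <- stats::setNames(numeric(19), fc_metric_names[17:35])
  tot <- sum(tile$intensity)
  if (length(ic)) {
    q <- stats::quantile(ic, c(0.25, 0.50, 0.75, 0.90, 0.99), names = FALSE, type = 7)
    out[c("I25", "I50", "I75", "I90", "I99")] <- q
    out["mean_i"] <- mean(ic)
    out["kurt_i"] <- moment_kurtosis(ic)
    out["range_i"] <- max(ic) - min(ic)
    out["skew_i"] <- moment_skewness(ic)
    out["cv_i"] <- safe_cv(ic)
    out["sd_i"] <- if (length(ic) > 1) stats::sd(ic) else 0
    ctot <- sum(ic)
    if (ctot > 0) {
      hp <- stats::quantile(hc, c(0.25, 0.50, 0.75, 0.90, 0.99), names = FALSE, type = 7)
      out[c("AI_H25", "AI_H50", "AI_H75", "AI_H90", "AI_H99")] <-
        vapply(hp, function(p) sum(ic[hc <= p]) / ctot, numeric(1))
    }
    out["FC_energy"] <- if (tot > 0) ctot / tot else 0
    out["CRS"] <- ctot
    out["dwCRS"] <- ctot / (length(h) / tile$area_m2)
  }
  out
}

#' Build a pseudowaveform from a point-cloud tile
#'
#' Bins the height axis from `min(0, min height)` to the maximum height
#' at uniform `bin_width_m` and sums the (normalized) return intensity in
#' each bin, emulating a full-waveform signal from discrete returns.
#' Energy is conserved: the amplitudes sum to the total tile intensity.
#'
#' @param tile An `fc_tile` with normalized intensities.
#' @param bin_width_m Bin width (m), default 0.5.
#' @return An `fc_pseudowaveform`: `bin_edges`, `amplitude`,
#'   `total_energy`, `bin_width_m`, and `n_pulses` (count of first
#'   returns, used to normalize AUCW).
#' @export
build_pseudowaveform <- function(tile, bin_width_m = 0.5) {
  stopifnot(bin_width_m > 0)
  h <- tile$height_m
  if (!length(h)) stop_fc("firecarb_empty_tile", "empty tile: missing data cell")
  lo <- min(0, min(h))
  n_bins <- max(1L, ceiling((max(h) - lo) / bin_width_m + 1e-12))
  edges <- lo + bin_width_m * (0:n_bins)
  idx <- pmin(pmax(floor((h - lo) / bin_width_m) + 1L, 1L), n_bins)
  amp <- vapply(split(tile$intensity, factor(idx, levels = seq_len(n_bins))),
                sum, numeric(1), USE.NAMES = FALSE)
  n_pulses <- if (length(tile$return_number)) sum(tile$return_number == 1L) else length(h)
  structure(list(bin_edges = edges, amplitude = amp, total_energy = sum(tile$intensity),
                 bin_width_m = bin_width_m, n_pulses = max(n_pulses, 1L)),
            class = "fc_pseudowaveform")
}

#' Pseudowaveform metrics
#'
#' * `HOME`: height of median energy, interpolated linearly on the
#'   piecewise-linear cumulative energy profile across bin edges.
#' * `height_median_ratio`: top canopy height / HOME.
#' * `mean_canopy_height`, `QMCH`: energy-weighted (quadratic) mean bin
#'   height over canopy bins.
#' * `CHP_cv`: coefficient of variation of the MacArthur-Horn canopy
#'   height profile (log-ratio of energy entering vs leaving each bin,
#'   top down, with log arguments clipped at 1e-6).
#' * `AUCW`: area under the canopy waveform, the summed canopy-bin
#'   amplitude times bin width normalized by pulse count.
#'
#' Canopy bins are those whose centre exceeds the canopy threshold; with
#' zero canopy energy the canopy metrics are 0 and HOME is computed from
#' the full profile.
#'
#' @param wf An `fc_pseudowaveform` with positive total energy.
#' @param canopy_threshold_m Canopy height threshold (m), default 2.
#' @return Named numeric vector of the 6 waveform metrics.
#' @export
waveform_metrics <- function(wf, canopy_threshold_m = 2) {
  if (wf$total_energy <= 0)
    stop_fc("firecarb_zero_energy", "pseudowaveform has zero total energy")
  centers <- wf$bin_edges[-1] - wf$bin_width_m / 2
  amp <- wf$amplitude
  out <- stats::setNames(numeric(6), fc_metric_names[36:41])

  # cumulative energy is piecewise linear across bin edges; HOME is the
  # height where it crosses half of the total
  Fe <- c(0, cumsum(amp)) / wf$total_energy
  i <- which(Fe >= 0.5)[1]
  out["HOME"] <- if (Fe[i] == 0.5) wf$bin_edges[i] else
    wf$bin_edges[i - 1] + (0.5 - Fe[i - 1]) / (Fe[i] - Fe[i - 1]) * wf$bin_width_m

  can <- centers > canopy_threshold_m
  ec <- sum(amp[can])
  if (ec > 0) {
    out["mean_canopy_height"] <- sum(amp[can] * centers[can]) / ec
    out["QMCH"] <- sqrt(sum(amp[can] * centers[can]^2) / ec)
    top <- max(wf$bin_edges[-1][can & amp > 0], -Inf)
    if (is.finite(top) && out["HOME"] > 0)
      out["height_median_ratio"] <- top / out["HOME"]
    # MacArthur-Horn profile, processed from the top of the canopy down
    eps <- 1e-6
    above <- rev(cumsum(rev(amp)))        # energy at or above each bin
    dens <- log(pmax(above, eps) / pmax(above - amp, eps)) / wf$bin_width_m
    dc <- dens[can]
    out["CHP_cv"] <- if (length(dc) > 1 && mean(dc) > 0) stats::sd(dc) / mean(dc) else 0
    out["AUCW"] <- ec * wf$bin_width_m / wf$n_pulses
  }
  out
}

#' All 41 metrics for one tile
#'
#' Convenience wrapper: normalizes intensity, computes height, intensity
#' and pseudowaveform metrics and returns them in canonical order.
#'
#' @inheritParams height_metrics
#' @param bin_width_m Pseudowaveform bin width (m).
#' @param reference_range_m Range-normalization reference; `NULL` for the
#'   tile mean range.
#' @return Named numeric vector of length 41.
#' @export
cell_metrics <- function(tile, canopy_threshold_m = 2, bin_width_m = 0.5,
                         reference_range_m = NULL) {
  tile <- normalize_intensity(tile, reference_range_m)
  c(height_metrics(tile, canopy_threshold_m),
    intensity_metrics(tile, canopy_threshold_m),
    waveform_metrics(build_pseudowaveform(tile, bin_width_m), canopy_threshold_m))
}

#' Rasterize per-cell LiDAR metrics over a scene grid
#'
#' Computes the 41-metric vector for every grid cell and returns one
#' matrix per metric. Accepts either an `fc_scene` (tiles are streamed
#' through [scene_tile()], never all held in memory) or a list of
#' `fc_tile` objects carrying `cell_id`s. Cells with no returns are
#' flagged as `NA` (nodata).
#'
#' @param x An `fc_scene`, or a list of tiles with `cell_id` in
#'   `1..nrow*ncol`.
#' @param nrow,ncol Grid dimensions (taken from the scene config when `x`
#'   is a scene).
#' @param ... Passed to [cell_metrics()].
#' @return Named list of 41 numeric matrices (a metric stack).
#' @export
rasterize_metrics <- function(x, nrow = NULL, ncol = NULL, ...) {
  if (inherits(x, "fc_scene")) {
    nrow <- x$config$grid_rows; ncol <- x$config$grid_cols
    get_tile <- function(i) scene_tile(x, i)
    n_cells <- nrow * ncol
    cells <- seq_len(n_cells)
  } else {
    stopifnot(is.list(x), !is.null(nrow), !is.null(ncol))
    n_cells <- nrow * ncol
    ids <- vapply(x, function(t) as.integer(t$cell_id), integer(1))
    if (anyNA(ids) || any(ids < 1L | ids > n_cells) || anyDuplicated(ids))
      stop_fc("firecarb_grid_mismatch", "tiles not aligned to the grid")
    get_tile <- function(i) x[[match(i, ids)]]
    cells <- sort(ids)
  }
  mats <- stats::setNames(
    rep(list(matrix(NA_real_, nrow, ncol)), length(fc_metric_names)),
    fc_metric_names)
  for (i in cells) {
    tile <- get_tile(i)
    if (isTRUE(tile$empty) || !length(tile$height_m)) next
    m <- cell_metrics(tile, ...)
    for (nm in fc_metric_names) mats[[nm]][i] <- m[[nm]]
  }
  mats
}
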