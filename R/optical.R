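#' Vegetation indices from a six-band reflectance stack
#'
#' NDVI, NDII, EVI and VARI from bands `B2` (blue), `B3` (green), `B4`
#' (red), `B5` (NIR), `B6` (SWIR1):
#' `NDVI = (NIR-Red)/(NIR+Red)`, `NDII = (NIR-SWIR1)/(NIR+SWIR1)`,
#' `EVI = 2.5 (NIR-Red)/(NIR + 6 Red - 7.5 Blue + 1)`,
#' `VARI = (Green-Red)/(Green+Red-Blue)`. Zero denominators yield `NA`.
#'
#' @param stack Named list of band matrices including `B2`..`B6`.
#' @return Named list of matrices `NDVI`, `NDII`, `EVI`, `VARI`.
#' @export
vegetation_indices <- function(stack) {
  need <- c("B2", "B3", "B4", "B5", "B6")
  missing <- setdiff(need, names(stack))
  if (length(missing))
    stop("missing reflectance band(s): ", paste(missing, collapse = ", "))
  blue <- stack$B2; green <- stack$B3; red <- stack$B4
  nir <- stack$B5; swir1 <- stack$B6
  ratio <- function(num, den) {
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  list(
    NDVI = ratio(nir - red, nir + red),
    NDII = ratio(nir - swir1, nir + swir1),
    EVI  = ratio(2.5 * (nir - red), nir + 6 * red - 7.5 * blue + 1),
    VARI = ratio(green - red, green + red - blue)
  )
}

# Published OLI tasseled-cap coefficients (Baig et al. 2014), bands 2-7.
fc_tasseled_cap_coefs <- rbind(
  brightness = c(B2 = 0.3029, B3 = 0.2786, B4 = 0.4733,
                 B5 = 0.5599, B6 = 0.5080, B7 = 0.1872),
  greenness  = c(B2 = -0.2941, B3 = -0.2430, B4 = -0.5424,
                 B5 = 0.7276, B6 = 0.0713, B7 = -0.1608),
  wetness    = c(B2 = 0.1511, B3 = 0.1973, B4 = 0.3283,
                 B5 = 0.3407, B6 = -0.7117, B7 = -0.4559))

#' Tasseled cap transformation (OLI coefficients)
#'
#' Brightness, greenness and wetness as fixed linear combinations of the
#' six reflective bands, plus the derived angle
#' `atan(greenness/brightness)` and distance
#' `sqrt(brightness^2 + greenness^2)`.
#'
#' @param stack Named list of band matrices `B2`..`B7`.
#' @return Named list: `brightness`, `greenness`, `wetness`, `tc_angle`,
#'   `tc_distance`.
#' @export
tasseled_cap <- function(stack) {
  need <- colnames(fc_tasseled_cap_coefs)
  missing <- setdiff(need, names(stack))
  if (length(missing))
    stop("missing reflectance band(s): ", paste(missing, collapse = ", "))
  comb <- function(w) Reduce(`+`, Map(function(b, wi) stack[[b]] * wi, need, w))
  b <- comb(fc_tasseled_cap_coefs["brightness", ])
  g <- comb(fc_tasseled_cap_coefs["greenness", ])
  w <- comb(fc_tasseled_cap_coefs["wetness", ])
  list(brightness = b, greenness = g, wetness = w,
       tc_angle = atan2(g, b), tc_distance = sqrt(b^2 + g^2))
}

#' Moving-window gray-level co-occurrence (GLCM) textures
#'
#' Quantizes the raster to `levels` gray levels by scene-wide min-max,
#' then for each pixel builds the symmetric co-occurrence matrix of the
#' surrounding `window x window` neighbourhood averaged over the four
#' 1-pixel offsets (isotropic), with mirrored edges, and derives six
#' textures: homogeneity, contrast, gray-level standard deviation,
#' entropy, angular second moment (ASM) and correlation (defined as 0
#' for constant windows).
#'
#' @param band Numeric matrix.
#' @param window Odd window size in (3, 5, 7, 9).
#' @param levels Number of gray levels (default 64).
#' @return Named list of matrices: `homogeneity`, `contrast`, `sd`,
#'   `entropy`, `asm`, `correlation`.
#' @export
glcm_textures <- function(band, window = 3, levels = 64) {
  stopifnot(window %in% c(3, 5, 7, 9), window %% 2 == 1, window^2 > 1)
  nr <- nrow(band); nc <- ncol(band)
  rng <- range(band, finite = TRUE)
  q <- if (diff(rng) == 0) matrix(1L, nr, nc) else
    pmin(as.integer(floor((band - rng[1]) / diff(rng) * levels)) + 1L, levels)
  q <- matrix(as.integer(q), nr, nc)
  w <- (window - 1L) / 2L
  mirror <- function(i, n) ifelse(i < 1L, 2L - i, ifelse(i > n, 2L * n - i, i))
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  out <- lapply(1:6, function(i) matrix(0, nr, nc))
  names(out) <- c("homogeneity", "contrast", "sd", "entropy", "asm", "correlation")
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    ri <- mirror((r - w):(r + w), nr)
    ci <- mirror((cc - w):(cc + w), nc)
    win <- q[ri, ci, drop = FALSE]
    # accumulate symmetric pair counts over the four offsets
    p <- matrix(0, levels, levels)
    for (o in offs) {
      dr <- o[1]; dc <- o[2]
      rs <- seq_len(window - dr)
      cs <- if (dc >= 0) seq_len(window - dc) else seq.int(1L - dc, window)
      a <- win[rs, cs, drop = FALSE]
      b2 <- win[rs + dr, cs + dc, drop = FALSE]
      for (k in seq_along(a)) {
        p[a[k], b2[k]] <- p[a[k], b2[k]] + 1
        p[b2[k], a[k]] <- p[b2[k], a[k]] + 1
      }
    }
    p <- p / sum(p)
    nz <- which(p > 0, arr.ind = TRUE)
    pv <- p[nz]
    i <- nz[, 1]; j <- nz[, 2]
    out$homogeneity[r, cc] <- sum(pv / (1 + (i - j)^2))
    out$contrast[r, cc] <- sum(pv * (i - j)^2)
    out$entropy[r, cc] <- -sum(pv * log(pv))
    out$asm[r, cc] <- sum(pv^2)
    pi_m <- rowSums(p)
    mu <- sum(seq_len(levels) * pi_m)
    sg2 <- sum((seq_len(levels) - mu)^2 * pi_m)
    out$sd[r, cc] <- sqrt(sg2)
    out$correlation[r, cc] <- if (sg2 > 0)
      sum(pv * (i - mu) * (j - mu)) / sg2 else 0
  }
  out
}

# block-average downsampling of a fine raster by an integer factor
block_mean <- function(x, factor) {
  stopifnot(nrow(x) %% factor == 0, ncol(x) %% factor == 0)
  nr <- nrow(x) %/% factor; nc <- ncol(x) %/% factor
  out <- matrix(0, nr, nc)
  for (i in seq_len(factor)) for (j in seq_len(factor))
    out <- out + x[seq.int(i, by = factor, length.out = nr),
                   seq.int(j, by = factor, length.out = nc)]
  out / factor^2
}

#' Terrain features from a fine DEM
#'
#' Resamples the DEM to the analysis grid by block averaging, then
#' computes slope and aspect on the coarse grid with Horn's 3x3 finite
#' differences (edges mirrored). Slope is in degrees; aspect in degrees
#' clockwise from north, `NA` on flat cells.
#'
#' @param dem_fine Fine DEM matrix whose dimensions are `factor` times
#'   the analysis grid.
#' @param factor Integer resampling factor (fine cells per coarse cell).
#' @param cell_size_m Coarse cell size (m), default 30.
#' @return List of matrices: `elevation`, `slope`, `aspect`.
#' @export
terrain_features <- function(dem_fine, factor = 1, cell_size_m = 30) {
  dem <- if (factor > 1) block_mean(dem_fine, factor) else dem_fine
  nr <- nrow(dem); nc <- ncol(dem)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  z <- function(di, dj) dem[pad(seq_len(nr) + di, nr), pad(seq_len(nc) + dj, nc)]
  # Horn kernel: row +1 is south (grid row 1 = north edge)
  dzdx <- ((z(-1, 1) + 2 * z(0, 1) + z(1, 1)) -
           (z(-1, -1) + 2 * z(0, -1) + z(1, -1))) / (8 * cell_size_m)
  dzdy <- ((z(1, -1) + 2 * z(1, 0) + z(1, 1)) -
           (z(-1, -1) + 2 * z(-1, 0) + z(-1, 1))) / (8 * cell_size_m)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # downslope azimuth clockwise from north (dzdy is the southward gradient)
  aspect <- (atan2(-dzdx, dzdy) * 180 / pi) %% 360
  aspect[slope == 0] <- NA_real_
  list(elevation = dem, slope = slope, aspect = aspect)
}

#' Assemble the optical predictor stack
#'
#' Bands, vegetation indices, tasseled cap components, terrain layers
#' and (optionally) GLCM textures in one named list of aligned matrices.
#' Textures are computed on request but excluded from the default model
#' feature set: window-scale texture artifacts print through to the
#' biomass maps, so they are off unless explicitly enabled.
#'
#' @param refl Named list of band matrices `B2`..`B7` (a reflectance
#'   stack from [simulate_reflectance()] or read from rasters).
#' @param elevation,slope,aspect Terrain matrices (e.g. from
#'   [terrain_features()]).
#' @param textures If `TRUE`, adds the six GLCM textures of each band.
#' @param texture_window GLCM window size.
#' @return Named list of feature matrices (a `FeatureStack`).
#' @export
feature_stack <- function(refl, elevation, slope = NULL, aspect = NULL,
                          textures = FALSE, texture_window = 3) {
  out <- c(refl[c("B2", "B3", "B4", "B5", "B6", "B7")],
           vegetation_indices(refl), tasseled_cap(refl))
  out$elevation <- elevation
  if (!is.null(slope)) out$slope <- slope
  if (!is.null(aspect)) out$aspect <- aspect
  if (isTRUE(textures)) {
    for (b in c("B2", "B3", "B4", "B5", "B6", "B7")) {
      tx <- glcm_textures(refl[[b]], window = texture_window)
      names(tx) <- paste0(b, "_", names(tx))
      out <- c(out, tx)
    }
  }
  attr(out, "date") <- attr(refl, "date")
  out
}
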