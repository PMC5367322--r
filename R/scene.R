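#' Scene configuration for the synthetic fire-landscape generator
#'
#' Bundles every knob of the virtual landscape: grid dimensions on a 30 m
#' cell, LiDAR point density, burn-severity and vegetation-type mixtures,
#' per-severity true consumption fractions, terrain relief, and noise
#' levels. Defaults encode the study conditions the package emulates:
#' ~20 returns/m2 acquisitions, a burn perimeter whose severity mixture is
#' 7.9% unburned, 30.9% low, 25.4% moderate and 35.8% high severity,
#' surrounded by an unburned buffer holding the calibration plots, and
#' true per-severity consumption fractions (0, 0.30, 0.50, 0.85) of
#' aboveground biomass (AGB).
#'
#' @param grid_rows,grid_cols Cell counts of the 30 m grid.
#' @param cell_size_m Cell size (m); fixed at 30 to match the sensor grid.
#' @param point_density LiDAR return density (points/m2).
#' @param severity_fractions Proportions over (unburned, low, moderate,
#'   high) *inside* the burn perimeter; must sum to 1.
#' @param veg_fractions Proportions over (conifer, deciduous, mixed);
#'   must sum to 1.
#' @param consumption_fractions True fraction of AGB removed per severity
#'   level (unburned, low, moderate, high); non-decreasing in `[0,1]`.
#' @param removal_fractions Fraction of canopy returns converted to
#'   ground returns per severity level. Tracks crown scorch rather than
#'   total consumption: surface and understory fuels contribute biomass
#'   loss but few canopy returns, so these sit below the consumption
#'   fractions except in stand-replacing (high) severity.
#' @param buffer_fraction Fraction of the scene outside the burn
#'   perimeter (unburned buffer, where field plots live).
#' @param elevation_range_m Length-2 vector, DEM relief (m).
#' @param reflectance_noise Gaussian noise sd added to each band.
#' @param intensity_noise Relative sd of per-return intensity noise.
#' @param snag_mode If `TRUE`, high-severity cells keep sparse top-of-
#'   canopy returns from standing dead trees (snags), so the canopy
#'   height percentile H50 stays high while return counts collapse.
#' @param n_plots,n_gps_fail,n_low_fc Field-plot campaign: total plot
#'   count, plots with degraded GPS fixes (> 2 m), plots with fractional
#'   cover below 10%.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @return An object of class `fc_scene_config` (a validated list).
#' @export
scene_config <- function(grid_rows = 60, grid_cols = 60, cell_size_m = 30,
                         point_density = 20,
                         severity_fractions = c(unburned = 0.079, low = 0.309,
                                                moderate = 0.254, high = 0.358),
                         veg_fractions = c(conifer = 0.6, deciduous = 0.1, mixed = 0.3),
                         consumption_fractions = c(unburned = 0, low = 0.30,
                                                   moderate = 0.50, high = 0.85),
                         removal_fractions = c(unburned = 0, low = 0.18,
                                               moderate = 0.32, high = 0.78),
                         buffer_fraction = 0.35,
                         elevation_range_m = c(600, 1600),
                         reflectance_noise = 0.01,
                         intensity_noise = 0.2,
                         snag_mode = TRUE,
                         n_plots = 71, n_gps_fail = 2, n_low_fc = 4,
                         seed = 42) {
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_size_m = cell_size_m, point_density = point_density,
    severity_fractions = severity_fractions, veg_fractions = veg_fractions,
    consumption_fractions = consumption_fractions,
    removal_fractions = removal_fractions,
    buffer_fraction = buffer_fraction, elevation_range_m = elevation_range_m,
    reflectance_noise = reflectance_noise, intensity_noise = intensity_noise,
    snag_mode = isTRUE(snag_mode),
    n_plots = as.integer(n_plots), n_gps_fail = as.integer(n_gps_fail),
    n_low_fc = as.integer(n_low_fc), seed = as.integer(seed),
    # AGB distribution envelope of the field campaign (plot scale, Mg/ha)
    agb_mean = 195.8, agb_sd = 143.1, agb_range = c(24.21, 645.4),
    # stratified campaign design: plots allocated across four stand-size
    # classes so small stands anchor the low end of the calibration
    campaign_edges = c(24.21, 90, 250, 450, 645.4),
    campaign_shares = c(0.36, 0.36, 0.19, 0.09),
    plot_area_ha = 0.09, max_trees = 5000,
    # saturating height-DBH curve H = 1.3 + a (1 - exp(-b DBH))^c
    height_curve = list(conifer = c(a = 48, b = 0.012, c = 1.0),
                        deciduous = c(a = 33, b = 0.016, c = 1.1)),
    # generic power allometry agb_kg = alpha DBH^beta H^delta
    allometry = list(conifer = c(alpha = 0.036, beta = 2.0, delta = 1.0),
                     deciduous = c(alpha = 0.045, beta = 2.0, delta = 1.0)),
    crown_diameter = c(intercept = 0.25, slope = 0.15),  # m, vs DBH (cm)
    stocking_cv = 0.45,      # lognormal sd of stand-level crown-cover multiplier
    flight_altitude_m = 650,
    canopy_intensity = c(mean = 60, ground = 25)
  )
  stopifnot(abs(sum(cfg$severity_fractions) - 1) < 1e-9,
            abs(sum(cfg$veg_fractions) - 1) < 1e-9,
            all(cfg$consumption_fractions >= 0 & cfg$consumption_fractions <= 1),
            !is.unsorted(cfg$consumption_fractions[-1]),  # low -> high monotone
            all(cfg$removal_fractions >= 0 & cfg$removal_fractions <= 1),
            !is.unsorted(cfg$removal_fractions),
            cfg$grid_rows > 0, cfg$grid_cols > 0, cfg$point_density >= 0,
            cfg$buffer_fraction >= 0, cfg$buffer_fraction < 1)
  class(cfg) <- "fc_scene_config"
  cfg
}

# truncated-normal quantile and sampler (inverse-CDF, exact)
qtruncnorm <- function(p, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd); pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + p * (pb - pa), mean, sd)
}
rtruncnorm <- function(n, mean, sd, lower, upper) {
  qtruncnorm(stats::runif(n), mean, sd, lower, upper)
}

#' Height from DBH along a saturating curve
#'
#' `H = 1.3 + a (1 - exp(-b DBH))^c`, with species-group coefficients.
#'
#' @param dbh_cm Diameter at breast height (cm).
#' @param species_group `"conifer"` or `"deciduous"`.
#' @param config A [scene_config()].
#' @return Height (m).
#' @export
height_from_dbh <- function(dbh_cm, species_group = "conifer", config = scene_config()) {
  cf <- config$height_curve[[match.arg(species_group, c("conifer", "deciduous"))]]
  1.3 + cf[["a"]] * (1 - exp(-cf[["b"]] * dbh_cm))^cf[["c"]]
}

#' Per-tree aboveground biomass from a power allometry
#'
#' `agb_kg = alpha DBH^beta H^delta` with species-group coefficients. A
#' single configurable published-form allometry per species group stands
#' in for a species-resolved equation library: only plot-level AGB
#' realism matters downstream.
#'
#' @inheritParams height_from_dbh
#' @param height_m Tree height (m).
#' @return Biomass (kg).
#' @export
tree_agb <- function(dbh_cm, height_m, species_group = "conifer", config = scene_config()) {
  cf <- config$allometry[[match.arg(species_group, c("conifer", "deciduous"))]]
  cf[["alpha"]] * dbh_cm^cf[["beta"]] * height_m^cf[["delta"]]
}

#' Generate a tree list hitting a target plot biomass
#'
#' Draws trees (DBH >= 10 cm, the tally threshold) from a right-skewed
#' diameter distribution matched to the field campaign envelope, assigns
#' heights from the saturating height-DBH curve with lognormal scatter,
#' computes per-tree AGB from the allometry, and adjusts the tree count
#' so the realized plot AGB lands within 5% of `target_agb`.
#'
#' @param target_agb Target plot AGB (Mg/ha), > 0.
#' @param species_group Cell vegetation type: `"conifer"`, `"deciduous"`
#'   or `"mixed"` (mixed draws each tree's group at random).
#' @param config A [scene_config()].
#' @param seed Optional integer; if `NULL` the current RNG stream is used.
#' @return A data frame with columns `dbh_cm`, `height_m`,
#'   `species_group`, `agb_kg`.
#' @export
generate_trees <- function(target_agb, species_group = "conifer",
                           config = scene_config(), seed = NULL) {
  stopifnot(target_agb > 0)
  if (!is.null(seed)) return(with_seed(seed, "trees",
    generate_trees(target_agb, species_group, config, seed = NULL)))
  species_group <- match.arg(species_group, c("conifer", "deciduous", "mixed"))
  area_ha <- config$plot_area_ha
  target_kg <- target_agb * area_ha * 1000

  # stand development: richer stands carry larger trees, not only more of
  # them, so canopy height percentiles track biomass as in real forests
  size_f <- min(max((target_agb / 195.8)^0.6, 0.35), 2.2)
  draw <- function(n) {
    dbh <- pmin(10 + stats::rgamma(n, shape = 1.05, scale = 19.4 * size_f), 145)
    sp <- if (species_group == "mixed") {
      ifelse(stats::runif(n) < 0.55, "conifer", "deciduous")
    } else rep(species_group, n)
    h <- numeric(n); agb <- numeric(n)
    for (g in unique(sp)) {
      i <- sp == g
      h[i] <- height_from_dbh(dbh[i], g, config) * exp(stats::rnorm(sum(i), 0, 0.08))
      agb[i] <- tree_agb(dbh[i], h[i], g, config)
    }
    data.frame(dbh_cm = dbh, height_m = h, species_group = sp, agb_kg = agb)
  }

  n0 <- min(config$max_trees, max(8L, ceiling(target_kg / 450) + 8L))
  trees <- draw(n0)
  while (sum(trees$agb_kg) < target_kg) {
    if (nrow(trees) >= config$max_trees)
      stop(structure(class = c("firecarb_infeasible_target", "error", "condition"),
                     list(message = sprintf(
                       "target AGB %.1f Mg/ha unreachable within %d trees",
                       target_agb, config$max_trees), call = sys.call(-1))))
    trees <- rbind(trees, draw(max(8L, ceiling((target_kg - sum(trees$agb_kg)) / 450))))
  }
  k <- which(cumsum(trees$agb_kg) >= target_kg)[1]
  trees <- trees[seq_len(k), , drop = FALSE]
  # trim overshoot, then top up with trees sized to the remaining deficit
  # (never a flood of saplings, which would wreck the stand height profile)
  while (nrow(trees) > 1 && (sum(trees$agb_kg) - target_kg) / target_kg > 0.05)
    trees <- trees[-nrow(trees), , drop = FALSE]
  tries <- 0L
  while (abs(sum(trees$agb_kg) - target_kg) / target_kg > 0.05) {
    if (nrow(trees) >= config$max_trees || tries > 1000L)
      stop(structure(class = c("firecarb_infeasible_target", "error", "condition"),
                     list(message = sprintf(
                       "cannot reach target AGB %.1f Mg/ha within 5%%", target_agb),
                       call = sys.call(-1))))
    if (sum(trees$agb_kg) < target_kg) {
      deficit <- target_kg - sum(trees$agb_kg)
      sp <- if (species_group == "mixed") {
        if (stats::runif(1) < 0.55) "conifer" else "deciduous"
      } else species_group
      dbh <- dbh_for_mass(deficit * stats::runif(1, 0.75, 1), sp, config)
      h <- height_from_dbh(dbh, sp, config) * exp(stats::rnorm(1, 0, 0.08))
      trees <- rbind(trees, data.frame(dbh_cm = dbh, height_m = h,
                                       species_group = sp,
                                       agb_kg = tree_agb(dbh, h, sp, config)))
    } else trees <- trees[-nrow(trees), , drop = FALSE]
    tries <- tries + 1L
  }
  rownames(trees) <- NULL
  trees
}

# DBH (>= 10 cm) whose noiseless allometric mass best matches `mass_kg`
dbh_for_mass <- function(mass_kg, species_group, config) {
  grid <- seq(10, 145, by = 0.5)
  agb <- tree_agb(grid, height_from_dbh(grid, species_group, config),
                  species_group, config)
  grid[which.min(abs(agb - mass_kg))]
}

# crown area (m2) from DBH (cm) through a linear crown-diameter model
crown_area <- function(dbh_cm, config) {
  d <- config$crown_diameter[["intercept"]] + config$crown_diameter[["slope"]] * dbh_cm
  pi * (d / 2)^2
}

# internal tile constructor
new_tile <- function(height_m, intensity, range_m, return_number,
                     cell_id = NA_integer_, area_m2 = 900, x = NULL, y = NULL,
                     empty = length(height_m) == 0L) {
  structure(list(height_m = height_m, intensity = intensity, range_m = range_m,
                 return_number = return_number, cell_id = cell_id,
                 area_m2 = area_m2, x = x, y = y, empty = empty),
            class = "fc_tile")
}

#' Simulate a discrete-return LiDAR tile over a tree list
#'
#' Canopy returns are drawn from per-tree crown envelopes (heights
#' uniform in `[0.5 H, H]`), ground returns sit at ~0 m, intensities are
#' higher for canopy than ground on average, and each return carries a
#' sensor range (m). Fire effects: the severity's canopy-return removal
#' fraction converts canopy returns to ground returns;
#' in snag mode (high severity) a sparse set of top-of-canopy returns
#' survives, so maximum height is preserved while canopy counts collapse.
#'
#' @param trees Tree data frame from [generate_trees()] (may have 0 rows
#'   for a treeless cell).
#' @param config A [scene_config()].
#' @param severity Integer severity code 0 (unburned) to 3 (high).
#' @param area_m2 Tile footprint (m2); 900 for a 30 m cell.
#' @param seed Optional integer; `NULL` uses the current RNG stream.
#' @return An `fc_tile`: vectors `height_m`, `intensity`, `range_m`,
#'   `return_number`, plus `cell_id`, `area_m2` and an `empty` flag.
#' @export
simulate_point_cloud <- function(trees, config = scene_config(), severity = 0L,
                                 area_m2 = 900, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, "cloud",
    simulate_point_cloud(trees, config, severity, area_m2, seed = NULL)))
  severity <- as.integer(severity)
  stopifnot(severity %in% 0:3)
  if (config$point_density <= 0)
    return(new_tile(numeric(0), numeric(0), numeric(0), integer(0),
                    area_m2 = area_m2, empty = TRUE))
  n <- stats::rpois(1, config$point_density * area_m2)
  if (n == 0)
    return(new_tile(numeric(0), numeric(0), numeric(0), integer(0),
                    area_m2 = area_m2, empty = TRUE))

  has_trees <- !is.null(trees) && nrow(trees) > 0
  # stand-level stocking multiplier: crown cover varies between stands of
  # equal biomass (species mix, clumping), decoupling cover from height
  stocking <- exp(stats::rnorm(1, 0, config$stocking_cv))
  cover <- if (has_trees)
    1 - exp(-stocking * sum(crown_area(trees$dbh_cm, config)) / area_m2) else 0
  canopy <- stats::runif(n) < cover

  height <- stats::rnorm(n, 0, 0.03)            # ground microrelief
  if (any(canopy)) {
    idx <- sample.int(nrow(trees), sum(canopy), replace = TRUE,
                      prob = crown_area(trees$dbh_cm, config))
    hh <- trees$height_m[idx]
    # crown base rises with tree height: young/open-grown trees carry deep
    # crowns, closed-canopy giants self-prune the lower half of the stem
    cb <- 0.25 + 0.25 * pmin(hh / 20, 1)
    height[canopy] <- stats::runif(sum(canopy), cb * hh, hh)
  }

  # fire effect: returns once intercepted by scorched crown material now hit
  # ground; the removal fraction tracks crown scorch, not total biomass
  # consumption (surface and understory fuels burn without moving canopy
  # returns), so it sits below the consumption fraction at low severity
  rf <- config$removal_fractions[severity + 1L]
  if (severity > 0 && rf > 0 && any(canopy)) {
    ci <- which(canopy)
    burn <- stats::runif(length(ci)) < rf
    if (config$snag_mode && severity == 3L && length(ci) > 0) {
      # standing dead trees: sparse survivors near the top of the canopy
      top <- height[ci] >= stats::quantile(height[ci], 0.97)
      burn[top & stats::runif(length(ci)) < 0.35] <- FALSE
      burn[which.max(height[ci])] <- FALSE      # tallest snag always returns
    }
    drop <- ci[burn]
    height[drop] <- stats::rnorm(length(drop), 0, 0.03)
    canopy[drop] <- FALSE
  }
  height <- pmax(height, -0.49)

  ci <- config$canopy_intensity
  intensity <- ifelse(canopy,
    stats::rnorm(n, ci[["mean"]], ci[["mean"]] * config$intensity_noise),
    stats::rnorm(n, ci[["ground"]], ci[["ground"]] * config$intensity_noise))
  intensity <- pmax(intensity, 0)
  range_m <- pmax(config$flight_altitude_m - height + stats::rnorm(n, 0, 5), 1)
  return_number <- sample.int(4L, n, replace = TRUE, prob = c(0.7, 0.2, 0.07, 0.03))
  new_tile(height, intensity, range_m, return_number, area_m2 = area_m2)
}

#' Generate a field-plot campaign in the unburned buffer
#'
#' Produces `n_plots` circular 0.09 ha plots with tree lists from
#' [generate_trees()], plot AGB (`sum(agb_kg)/1000/0.09`), LiDAR-style
#' fractional cover and GPS error. A fixed number of plots carry degraded
#' GPS fixes (> 2 m) and a fixed number are sparse low-cover plots
#' (fractional cover < 10%), mirroring a real campaign's losses.
#'
#' @param config A [scene_config()].
#' @param n_plots Number of plots (default from `config`).
#' @param seed Optional integer seed.
#' @return A list of class `fc_plots`: data frame `$plots` (columns
#'   `plot_id`, `x`, `y`, `plot_agb_Mg_ha`, `fractional_cover`,
#'   `gps_error_m`, `veg`) and `$trees`, a list of tree data frames.
#' @export
generate_field_plots <- function(config = scene_config(), n_plots = config$n_plots,
                                 seed = config$seed) {
  with_seed(seed, "plots", {
    veg_pool <- c("conifer", "deciduous", "mixed")
    veg <- sample(veg_pool, n_plots, replace = TRUE, prob = config$veg_fractions)
    # stratified random design over stand-size classes (largest-remainder
    # allocation), uniform within class
    quota <- floor(config$campaign_shares * n_plots)
    rem <- n_plots - sum(quota)
    if (rem > 0) {
      extra <- order(config$campaign_shares * n_plots - quota,
                     decreasing = TRUE)[seq_len(rem)]
      quota[extra] <- quota[extra] + 1L
    }
    cls <- sample(rep(seq_along(quota), times = quota))
    target <- stats::runif(n_plots, config$campaign_edges[cls],
                           config$campaign_edges[cls + 1])
    low_fc_idx <- seq_len(min(config$n_low_fc, n_plots))
    gps_idx <- seq.int(config$n_low_fc + 1, length.out = min(config$n_gps_fail, n_plots))

    trees <- lapply(seq_len(n_plots), function(i) {
      if (i %in% low_fc_idx) {
        # sparse scrub plots: one to three tallied stems, shrub cover below
        # the tally threshold carries no tree biomass
        n_stems <- sample(1:3, 1)
        dbh <- stats::runif(n_stems, 10, 14)
        sp <- rep(if (veg[i] == "deciduous") "deciduous" else "conifer", n_stems)
        h <- height_from_dbh(dbh, sp[1], config) * exp(stats::rnorm(n_stems, 0, 0.08))
        data.frame(dbh_cm = dbh, height_m = h, species_group = sp,
                   agb_kg = tree_agb(dbh, h, sp[1], config))
      } else generate_trees(target[i], veg[i], config)
    })
    agb <- vapply(trees, function(tr) sum(tr$agb_kg), numeric(1)) / 1000 / config$plot_area_ha
    fc <- vapply(trees, function(tr)
      1 - exp(-exp(stats::rnorm(1, 0, config$stocking_cv)) *
                sum(crown_area(tr$dbh_cm, config)) / (config$plot_area_ha * 1e4)),
      numeric(1))
    # understory/shrub returns add cover not counted as tree AGB
    fc <- pmax(fc, 0.12)
    fc[low_fc_idx] <- stats::runif(length(low_fc_idx), 0.02, 0.08)
    gps <- stats::runif(n_plots, 0.05, 0.5)
    gps[gps_idx] <- stats::runif(length(gps_idx), 2.5, 6)
    plots <- data.frame(plot_id = seq_len(n_plots),
                        x = stats::runif(n_plots, 0, config$grid_cols * config$cell_size_m),
                        y = stats::runif(n_plots, 0, config$grid_rows * config$cell_size_m),
                        plot_agb_Mg_ha = agb, fractional_cover = fc,
                        gps_error_m = gps, veg = veg)
    structure(list(plots = plots, trees = trees), class = "fc_plots")
  })
}

#' Filter field plots on GPS accuracy and fractional cover
#'
#' Drops plots with a GPS error exceeding `max_gps_error_m` or a
#' fractional cover strictly below `min_fc` (a plot at exactly the cover
#' threshold is retained). Order is preserved.
#'
#' @param plots An `fc_plots` object or its `$plots` data frame.
#' @param max_gps_error_m GPS error threshold (m), default 2.
#' @param min_fc Fractional-cover threshold, default 0.10.
#' @return Same structure as the input, with failing plots removed.
#' @export
filter_plots <- function(plots, max_gps_error_m = 2, min_fc = 0.10) {
  df <- if (inherits(plots, "fc_plots")) plots$plots else plots
  keep <- df$gps_error_m <= max_gps_error_m & df$fractional_cover >= min_fc
  if (!any(keep))
    stop(structure(class = c("firecarb_empty_calibration", "error", "condition"),
                   list(message = "all plots removed by filtering", call = sys.call(-1))))
  if (inherits(plots, "fc_plots")) {
    structure(list(plots = df[keep, , drop = FALSE], trees = plots$trees[keep]),
              class = "fc_plots")
  } else df[keep, , drop = FALSE]
}

#' Simulate six-band surface reflectance for a scene
#'
#' Linear mixing of vegetation, soil and char end-member spectra: the
#' vegetated fraction follows canopy cover (a saturating function of true
#' AGB), and on the postfire date a charred fraction proportional to the
#' severity's consumption fraction replaces the whole pixel signal, so
#' NIR drops and SWIR rises with severity. A small elevation-dependent
#' term and Gaussian noise are added; values are clipped to `[0, 1]`.
#'
#' @param scene An `fc_scene` from [simulate_scene()].
#' @param date `"pre"` or `"post"`.
#' @param seed Optional integer seed.
#' @return Named list of matrices `B2`..`B7` with attribute `date`.
#' @export
simulate_reflectance <- function(scene, date = c("pre", "post"), seed = NULL) {
  date <- match.arg(date)
  cfg <- scene$config
  if (is.null(seed)) seed <- cfg$seed
  with_seed(seed, paste0("refl_", date), {
    veg  <- c(B2 = 0.04, B3 = 0.07, B4 = 0.05, B5 = 0.38, B6 = 0.17, B7 = 0.09)
    soil <- c(B2 = 0.10, B3 = 0.14, B4 = 0.18, B5 = 0.26, B6 = 0.30, B7 = 0.25)
    char <- c(B2 = 0.05, B3 = 0.06, B4 = 0.08, B5 = 0.09, B6 = 0.30, B7 = 0.28)
    elev_coef <- c(B2 = -0.002, B3 = -0.002, B4 = -0.003,
                   B5 = -0.008, B6 = 0.005, B7 = 0.005)
    agb <- scene$agb_pre
    cover <- agb / (agb + 300)   # weakly saturating over the observed AGB range
    burn_frac <- if (date == "post")
      matrix(cfg$consumption_fractions[scene$severity + 1L],
             nrow(agb), ncol(agb)) else 0
    elev_std <- (scene$dem - mean(scene$dem)) / max(stats::sd(scene$dem), 1e-9)
    out <- lapply(names(veg), function(b) {
      green <- cover * veg[[b]] + (1 - cover) * soil[[b]]
      r <- (1 - burn_frac) * green + burn_frac * char[[b]] +
        elev_coef[[b]] * elev_std +
        stats::rnorm(length(agb), 0, cfg$reflectance_noise)
      matrix(pmin(pmax(r, 0), 1), nrow(agb), ncol(agb))
    })
    names(out) <- names(veg)
    attr(out, "date") <- date
    out
  })
}

#' Generate a complete pre/post-fire virtual landscape
#'
#' Builds terrain (smooth DEM plus slope/aspect), a blob-shaped burn
#' perimeter with an unburned buffer, spatially coherent severity and
#' vegetation-type maps with exact class fractions, true pre/postfire AGB
#' rasters (postfire = prefire times one minus the severity's consumption
#' fraction), per-cell tree lists, six-band pre/post reflectance, and the
#' field-plot campaign with matching LiDAR tiles. Per-cell point clouds
#' are *not* stored: [scene_tile()] regenerates any tile bit-identically
#' from the master seed, keeping memory flat for large scenes.
#'
#' @param config A [scene_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `fc_scene`.
#' @export
simulate_scene <- function(config = scene_config(), quiet = TRUE) {
  nr <- config$grid_rows; nc <- config$grid_cols
  seed <- config$seed

  dem_fine <- with_seed(seed, "dem", {
    f <- smooth_field(3L * nr, 3L * nc, range_cells = 18)
    er <- config$elevation_range_m
    er[1] + (f - min(f)) / (max(f) - min(f)) * (er[2] - er[1])
  })
  dem <- block_mean(dem_fine, 3L)
  terr <- terrain_features(dem_fine, factor = 3L, cell_size_m = config$cell_size_m)

  # burn perimeter: central blob covering 1 - buffer_fraction of the scene
  perim_field <- with_seed(seed, "perimeter", smooth_field(nr, nc, range_cells = 10))
  rr <- (row(perim_field) - (nr + 1) / 2) / nr
  cc <- (col(perim_field) - (nc + 1) / 2) / nc
  radial <- -sqrt(rr^2 + cc^2) + 0.35 * perim_field
  burned <- radial >= stats::quantile(radial, config$buffer_fraction)

  sev_field <- with_seed(seed, "severity", smooth_field(nr, nc, range_cells = 5))
  severity <- matrix(0L, nr, nc)
  severity[burned] <- classify_by_quantile(
    matrix(sev_field[burned], ncol = 1), config$severity_fractions)[, 1]

  veg_field <- with_seed(seed, "vegtype", smooth_field(nr, nc, range_cells = 7))
  vegtype <- classify_by_quantile(veg_field, config$veg_fractions, codes = 1:3)

  agb_pre <- with_seed(seed, "agb", {
    z <- smooth_field(nr, nc, range_cells = 6)
    z <- (0.75 * z + 0.35 * (dem - mean(dem)) / stats::sd(dem) +
            0.2 * stats::rnorm(nr * nc))
    z <- (z - mean(z)) / stats::sd(z)
    base <- qtruncnorm(stats::pnorm(z), config$agb_mean, config$agb_sd,
                       config$agb_range[1], config$agb_range[2])
    mult <- c(1.1, 0.45, 0.8)[vegtype]
    matrix(base * mult, nr, nc)
  })
  agb_post <- agb_pre * (1 - config$consumption_fractions[severity + 1L])

  if (!quiet) message("generating per-cell tree lists ...")
  trees <- with_seed(seed, "trees_cells", {
    veg_names <- c("conifer", "deciduous", "mixed")
    lapply(seq_len(nr * nc), function(i)
      generate_trees(agb_pre[i], veg_names[vegtype[i]], config))
  })

  scene <- structure(list(
    config = config, dem = dem, dem_fine = dem_fine,
    slope = terr$slope, aspect = terr$aspect,
    vegtype = vegtype, severity = severity, burned = burned,
    agb_pre = agb_pre, agb_post = agb_post, trees = trees
  ), class = "fc_scene")

  scene$refl_pre <- simulate_reflectance(scene, "pre")
  scene$refl_post <- simulate_reflectance(scene, "post")

  plots_all <- generate_field_plots(config)
  scene$plots <- plots_all
  scene$plot_tiles <- with_seed(seed, "plot_tiles", lapply(
    seq_along(plots_all$trees), function(i)
      simulate_point_cloud(plots_all$trees[[i]], config, severity = 0L)))
  scene
}

#' Regenerate the postfire LiDAR tile of one scene cell
#'
#' Tiles are deterministic functions of the scene's master seed and the
#' cell index, so they never need to be stored; a 60x60 scene at
#' 20 points/m2 would otherwise hold ~65 million returns.
#'
#' @param scene An `fc_scene`.
#' @param cell Cell index (column-major, `1..grid_rows*grid_cols`).
#' @return An `fc_tile`.
#' @export
scene_tile <- function(scene, cell) {
  cfg <- scene$config
  with_seed(cfg$seed, paste0("tile", cell), {
    tile <- simulate_point_cloud(scene$trees[[cell]], cfg,
                                 severity = scene$severity[cell],
                                 area_m2 = cfg$cell_size_m^2)
    tile$cell_id <- as.integer(cell)
    tile
  })
}
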