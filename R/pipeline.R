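#' Pipeline configuration
#'
#' One structured object drives the whole chain: scene generation, model
#' training, extrapolation, emission accounting and uncertainty. All
#' stage seeds derive from the scene's master seed, so a config fully
#' determines every output byte.
#'
#' @param scene A [scene_config()].
#' @param n_samples Pixels sampled for the optical models (default 514).
#' @param sample_bins Histogram bins for the pixel sampling.
#' @param split_fraction Calibration fraction of the 70/30 split.
#' @param carbon_fraction Carbon fraction of biomass (default 0.5).
#' @param pixel_area_ha Pixel area (ha); 0.09 for 30 m cells.
#' @param h_grid,gamma_grid Hyperparameter grids for [grid_search_cv()].
#' @param cv_folds Cross-validation folds (default 10).
#' @param lidar_features,optical_features Expert feature subsets.
#' @param max_lag_m,n_lag_bins Correlogram settings.
#' @param write_outputs Write maps/tables when an output dir is given.
#' @return An `fc_pipeline_config` list.
#' @export
pipeline_config <- function(scene = scene_config(), n_samples = 514,
                            sample_bins = 10, split_fraction = 0.7,
                            carbon_fraction = 0.5, pixel_area_ha = 0.09,
                            h_grid = default_h_grid(),
                            gamma_grid = default_gamma_grid(),
                            cv_folds = 10,
                            lidar_features = c("AUCW", "H50"),
                            optical_features = c("B2", "B3", "B4", "B5", "B6",
                                                 "NDII", "elevation"),
                            max_lag_m = 300, n_lag_bins = 10,
                            write_outputs = TRUE) {
  structure(list(scene = scene, n_samples = n_samples, sample_bins = sample_bins,
                 split_fraction = split_fraction, carbon_fraction = carbon_fraction,
                 pixel_area_ha = pixel_area_ha, h_grid = h_grid,
                 gamma_grid = gamma_grid, cv_folds = cv_folds,
                 lidar_features = lidar_features, optical_features = optical_features,
                 max_lag_m = max_lag_m, n_lag_bins = n_lag_bins,
                 write_outputs = isTRUE(write_outputs)),
            class = "fc_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear; the `scene` block maps
#' onto [scene_config()] arguments. Missing fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `fc_pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scene_args <- raw$scene %||% list()
  raw$scene <- NULL
  args <- raw
  args$scene <- do.call(scene_config, scene_args)
  do.call(pipeline_config, args)
}

# fit-metric rows for calibration / validation / combined sets
fit_table <- function(y, pred, split, p, model_name) {
  sets <- list(calibration = split$cal, validation = split$val,
               combined = c(split$cal, split$val))
  do.call(rbind, lapply(names(sets), function(s) {
    idx <- sets[[s]]
    if (!length(idx)) return(NULL)
    fm <- fit_metrics(y[idx], pred[idx], p)
    data.frame(model = model_name, set = s, r2 = fm$r2, r2_adj = fm$r2_adj,
               rmse = fm$rmse, rel_rmse = fm$rel_rmse, n = fm$n)
  }))
}

train_agb_model <- function(X, y, cfg, tag) {
  split <- split_calibration_validation(y, cfg$split_fraction,
                                        seed = derive_seed(cfg$scene$seed, paste0("split_", tag)))
  k <- min(cfg$cv_folds, length(split$cal))
  gs <- grid_search_cv(X[split$cal, , drop = FALSE], y[split$cal],
                       cfg$h_grid, cfg$gamma_grid, k = k,
                       seed = derive_seed(cfg$scene$seed, paste0("cv_", tag)))
  model <- train_lssvr(X[split$cal, , drop = FALSE], y[split$cal], gs$h, gs$gamma)
  pred <- predict(model, X)
  fits <- fit_table(y, pred, split, p = ncol(X), model_name = tag)
  list(model = model, split = split, gs = gs, pred = pred, fits = fits)
}

# per-stratum totals of a biomass map (Tg) over severity codes 1..3
stratum_mass_Tg <- function(map, severity, pixel_area_ha) {
  vapply(1:3, function(s) {
    sel <- severity == s & !is.na(map)
    sum(map[sel]) * pixel_area_ha * 1e-6
  }, numeric(1))
}

#' Run the full fire-carbon pipeline
#'
#' Executes every stage in order: scene simulation, LiDAR metric
#' rasterization, plot-calibrated LiDAR LS-SVR, H50 correction, pixel
#' sampling, optical LS-SVR models (pre/post), wall-to-wall biomass maps,
#' dilution-bias correction, consumption and emission accounting for the
#' three method pairs, and the uncertainty budget. A config determines
#' every output byte; rerunning with the same config reproduces the run
#' exactly.
#'
#' @param config An `fc_pipeline_config`, or the path of a YAML file for
#'   [load_pipeline_config()].
#' @param out_dir Optional run directory; when given (and
#'   `write_outputs`), maps (ASCII grids), tables (CSV) and the report
#'   (JSON) are written there.
#' @param quiet Suppress stage messages.
#' @return An `fc_run` list: `scene`, `metrics`, `models`, `maps`,
#'   `fits`, `report` (consumption/emissions by stratum and method
#'   pair), `cc` (combustion completeness), `uncertainty` (budget), and
#'   bookkeeping (`sample_idx`, `h50_ref`, `plots_used`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "fc_pipeline_config"))
  cfg <- config
  seed <- cfg$scene$seed
  say <- function(...) if (!quiet) message(sprintf("[firecarb %s] ", format(Sys.time(), "%H:%M:%S")), ...)

  say("stage 1/8: simulating scene")
  scene <- simulate_scene(cfg$scene, quiet = quiet)

  say("stage 2/8: rasterizing LiDAR metrics")
  metrics <- rasterize_metrics(scene)

  say("stage 3/8: LiDAR biomass model (field plots)")
  keep <- filter_plots(scene$plots$plots)
  plot_idx <- keep$plot_id
  plot_X <- t(vapply(scene$plot_tiles[plot_idx], cell_metrics,
                     numeric(length(fc_metric_names))))
  colnames(plot_X) <- fc_metric_names
  y_plots <- keep$plot_agb_Mg_ha
  lidar_feats <- feature_select(as.data.frame(plot_X), y_plots, "expert",
                                expert_features = cfg$lidar_features)
  lid <- train_agb_model(plot_X[, lidar_feats, drop = FALSE], y_plots, cfg, "lidar")

  say("stage 4/8: LiDAR AGB maps and H50 correction")
  map_lidar <- agb_map_from_metrics(metrics, lid$model, "lidar")
  unb <- scene$severity == 0L
  h50_ref <- fit_h50_aucw_reference(metrics$H50[unb], metrics$AUCW[unb])
  metrics_corr <- correct_h50(metrics, h50_ref, scene$burned)
  map_lidar_corr <- agb_map_from_metrics(metrics_corr, lid$model, "lidar_corrected")

  say("stage 5/8: optical models (pre/post)")
  terr <- list(elevation = scene$dem, slope = scene$slope, aspect = scene$aspect)
  fs_pre <- feature_stack(scene$refl_pre, terr$elevation, terr$slope, terr$aspect)
  fs_post <- feature_stack(scene$refl_post, terr$elevation, terr$slope, terr$aspect)
  mask <- (scene$severity <= 1L) & !is.na(map_lidar)
  sample_idx <- stratified_histogram_sample(map_lidar, mask,
                                            n = min(cfg$n_samples, sum(mask)),
                                            bins = cfg$sample_bins,
                                            seed = derive_seed(seed, "pixsample"))
  tt_pre <- build_training_table(sample_idx, fs_pre, map_lidar, cfg$optical_features)
  tt_post <- build_training_table(sample_idx, fs_post, map_lidar, cfg$optical_features)
  opt_pre <- train_agb_model(as.matrix(tt_pre[cfg$optical_features]), tt_pre$agb,
                             cfg, "landsat_pre")
  opt_post <- train_agb_model(as.matrix(tt_post[cfg$optical_features]), tt_post$agb,
                              cfg, "landsat_post")

  say("stage 6/8: wall-to-wall maps and bias correction")
  map_pre <- predict_agb_map(opt_pre$model, fs_pre, "landsat_pre")
  map_post <- predict_agb_map(opt_post$model, fs_post, "landsat_post")
  pred_plots <- predict(lid$model, plot_X[, lidar_feats, drop = FALSE])
  map_lidar_bc <- bias_correct(map_lidar, y_plots, pred_plots)
  map_lidar_corr_bc <- bias_correct(map_lidar_corr, y_plots, pred_plots)
  map_pre_bc <- bias_correct(map_pre, tt_pre$agb, opt_pre$pred)
  map_post_bc <- bias_correct(map_post, tt_post$agb, opt_post$pred)

  say("stage 7/8: consumption, emissions, combustion completeness")
  deltas <- list(
    "landsat_pre-landsat_post"    = consumption_map(map_pre_bc, map_post_bc),
    "landsat_pre-lidar"           = consumption_map(map_pre_bc, map_lidar_bc),
    "landsat_pre-lidar_corrected" = consumption_map(map_pre_bc, map_lidar_corr_bc))
  pre_mass <- stratum_mass_Tg(map_pre_bc, scene$severity, cfg$pixel_area_ha)
  report <- do.call(rbind, lapply(names(deltas), function(pair) {
    agg <- aggregate_by_stratum(deltas[[pair]], scene$severity, cfg$pixel_area_ha)
    agg$C_TgC <- carbon_release(agg$dB_Tg, cfg$carbon_fraction)
    agg$CO2e_Tg <- co2_equivalent(agg$C_TgC)
    cc <- combustion_completeness(agg$dB_Tg[1:3], pre_mass)
    agg$CC <- c(as.numeric(cc),
                as.numeric(combustion_completeness(sum(agg$dB_Tg[1:3]), sum(pre_mass))))
    cbind(pair = pair, agg)
  }))

  say("stage 8/8: uncertainty budget")
  fits <- rbind(lid$fits, opt_pre$fits, opt_post$fits)
  gf <- function(m, col) fits[fits$model == m & fits$set == "combined", col]
  rmse1 <- gf("lidar", "rmse"); rel1 <- gf("lidar", "rel_rmse")
  budget <- list(
    rmse1_abs = rmse1, rmse1_rel = rel1,
    rmse2_pre_abs = gf("landsat_pre", "rmse"), rmse2_pre_rel = gf("landsat_pre", "rel_rmse"),
    rmse2_post_abs = gf("landsat_post", "rmse"), rmse2_post_rel = gf("landsat_post", "rel_rmse"))
  budget$sigma_pre_abs <- compose_two_step_error(budget$rmse1_abs, budget$rmse2_pre_abs)
  budget$sigma_pre_rel <- compose_two_step_error(budget$rmse1_rel, budget$rmse2_pre_rel)
  budget$sigma_post_abs <- compose_two_step_error(budget$rmse1_abs, budget$rmse2_post_abs)
  budget$sigma_post_rel <- compose_two_step_error(budget$rmse1_rel, budget$rmse2_post_rel)

  resid_raster <- map_pre_bc - map_lidar
  resid_raster[!mask] <- NA_real_
  cg <- tryCatch(
    fit_correlogram(resid_raster, cfg$scene$cell_size_m,
                    max_lag_m = cfg$max_lag_m, n_lag_bins = cfg$n_lag_bins),
    firecarb_too_few_cells = function(e) {
      warning("too few residual pixels for a correlogram; assuming uncorrelated error")
      structure(list(phi = 1e-6, empirical = NULL, model = "exponential"),
                class = "fc_correlogram")
    })
  budget$phi_m <- cg$phi
  # paired residual correlation of the two optical maps at shared samples
  common <- intersect(tt_pre$cell, tt_post$cell)
  ia <- match(common, tt_pre$cell); ib <- match(common, tt_post$cell)
  r_pair <- stats::cor(opt_pre$pred[ia] - tt_pre$agb[ia],
                       opt_post$pred[ib] - tt_post$agb[ib])
  sigma_post_by_pair <- c("landsat_pre-landsat_post" = budget$sigma_post_abs,
                          "landsat_pre-lidar" = budget$rmse1_abs,
                          "landsat_pre-lidar_corrected" = budget$rmse1_abs)
  cell <- cfg$scene$cell_size_m
  se_rows <- do.call(rbind, lapply(1:3, function(s) {
    sel <- which(scene$severity == s & !is.na(deltas[[1]]))
    coords <- cbind((col(scene$severity)[sel]) * cell, (row(scene$severity)[sel]) * cell)
    se_pre <- stratum_mean_se(budget$sigma_pre_abs, coords, cg)
    do.call(rbind, lapply(names(deltas), function(pair) {
      se_post <- stratum_mean_se(sigma_post_by_pair[[pair]], coords, cg)
      cov <- if (pair == "landsat_pre-landsat_post") r_pair * se_pre * se_post else 0
      var_d <- difference_variance(se_pre^2, se_post^2, cov)
      data.frame(pair = pair, stratum = fc_severity_levels[s + 1],
                 se_mean_pre = se_pre, se_mean_post = se_post,
                 U_dB_Tg = sqrt(var_d) * length(sel) * cfg$pixel_area_ha * 1e-6)
    }))
  }))
  # site totals: burned strata combine; stratum errors add in quadrature
  tot <- do.call(rbind, lapply(names(deltas), function(pair) {
    u <- se_rows$U_dB_Tg[se_rows$pair == pair]
    data.frame(pair = pair, stratum = "total_burned",
               se_mean_pre = NA_real_, se_mean_post = NA_real_,
               U_dB_Tg = sqrt(sum(u^2)))
  }))
  se_rows <- rbind(se_rows, tot)
  report <- merge(report, se_rows[c("pair", "stratum", "U_dB_Tg")],
                  by = c("pair", "stratum"), sort = FALSE)
  report$U_C_TgC <- report$U_dB_Tg * cfg$carbon_fraction
  report$U_CO2e_Tg <- report$U_C_TgC * 44 / 12
  ord <- order(match(report$pair, names(deltas)),
               match(report$stratum, c(fc_severity_levels[-1], "total_burned")))
  report <- report[ord, ]
  rownames(report) <- NULL

  maps <- list(lidar = map_lidar, lidar_corrected = map_lidar_corr,
               landsat_pre = map_pre, landsat_post = map_post,
               lidar_bc = map_lidar_bc, lidar_corrected_bc = map_lidar_corr_bc,
               landsat_pre_bc = map_pre_bc, landsat_post_bc = map_post_bc)

  run <- structure(list(
    config = cfg, scene = scene, metrics = metrics, metrics_corrected = metrics_corr,
    h50_ref = h50_ref, plots_used = keep, sample_idx = sample_idx,
    models = list(lidar = lid, landsat_pre = opt_pre, landsat_post = opt_post),
    maps = maps, deltas = deltas, fits = fits, report = report,
    cc = stats::setNames(report$CC, paste(report$pair, report$stratum, sep = ":")),
    uncertainty = budget, correlogram = cg
  ), class = "fc_run")

  if (!is.null(out_dir) && cfg$write_outputs) write_run(run, out_dir)
  run
}

#' Write the artifacts of a pipeline run
#'
#' Maps as ASCII grids, the fit and emission tables as CSV, and the full
#' report (tables rendered at 2 decimals, plus the uncertainty budget)
#' as JSON.
#'
#' @param run An `fc_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cell <- run$config$scene$cell_size_m
  for (nm in names(run$maps))
    write_asc(run$maps[[nm]], file.path(out_dir, paste0("agb_", nm, ".asc")), cell)
  write_asc(run$scene$severity + 0, file.path(out_dir, "severity.asc"), cell)
  utils::write.csv(run$fits, file.path(out_dir, "model_fits.csv"), row.names = FALSE)
  utils::write.csv(render_report(run$report), file.path(out_dir, "emissions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    emissions = render_report(run$report),
    model_fits = run$fits,
    uncertainty = run$uncertainty,
    h50_reference = run$h50_ref[c("a", "b", "r2", "n")],
    n_samples = length(run$sample_idx),
    n_plots_used = nrow(run$plots_used)
  ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}
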