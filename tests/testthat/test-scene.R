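test_that("generated tree lists hit the target plot biomass within 5%", {
  cfg <- scene_config()
  for (target in c(50, 195.8, 500)) {
    tr <- generate_trees(target, "conifer", cfg, seed = 11)
    agb <- sum(tr$agb_kg) / 1000 / 0.09
    expect_gte(agb, target * 0.95)
    expect_lte(agb, target * 1.05)
    expect_true(all(tr$dbh_cm >= 10 & tr$dbh_cm <= 145))
    expect_true(all(tr$agb_kg > 0))
  }
})

test_that("per-tree biomass follows the allometric identity", {
  cfg <- scene_config()
  h <- height_from_dbh(10, "conifer", cfg)
  a <- cfg$allometry$conifer
  expect_equal(tree_agb(10, h, "conifer", cfg),
               a[["alpha"]] * 10^a[["beta"]] * h^a[["delta"]])
  expect_equal(height_from_dbh(0, "conifer", cfg), 1.3)
})

test_that("campaign mean biomass matches the configured stratified design", {
  cfg <- scene_config()
  pl <- generate_field_plots(cfg, n_plots = 1000, seed = 77)
  agb <- pl$plots$plot_agb_Mg_ha
  # closed-form mixture mean of the stratified design as the oracle
  mids <- (cfg$campaign_edges[-1] + cfg$campaign_edges[-5]) / 2
  mu <- sum(cfg$campaign_shares * mids)
  se <- sd(agb) / sqrt(length(agb))
  expect_lt(abs(mean(agb) - mu), 2 * se + 2)  # +2 Mg/ha for the sparse plots
  # the design spans the campaign envelope every time
  expect_lt(min(agb), 90)
  expect_gt(max(agb), 450)
})

test_that("point density contract holds on unburned tiles", {
  cfg <- scene_config(point_density = 20)
  tr <- generate_trees(195.8, "conifer", cfg, seed = 3)
  tile <- simulate_point_cloud(tr, cfg, severity = 0, seed = 5)
  n <- length(tile$height_m)
  expect_lt(abs(n - 18000), 5 * sqrt(18000))
  expect_true(all(tile$height_m >= -0.5))
  expect_true(all(tile$intensity >= 0))
  # canopy returns brighter than ground on average
  canopy <- tile$height_m > 2
  expect_gt(mean(tile$intensity[canopy]), mean(tile$intensity[!canopy]))
})

test_that("treeless cells yield pure ground returns", {
  cfg <- scene_config(point_density = 5)
  tile <- simulate_point_cloud(data.frame(), cfg, severity = 0, seed = 2)
  expect_true(all(tile$height_m < 2))
  expect_equal(unname(height_metrics(tile)["cover_ratio"]), 0)
})

test_that("zero requested density gives a flagged empty tile", {
  cfg <- scene_config(point_density = 0)
  tile <- simulate_point_cloud(data.frame(), cfg, severity = 0, seed = 2)
  expect_true(tile$empty)
  expect_length(tile$height_m, 0)
})

test_that("high-severity snag mode collapses canopy returns but keeps top height", {
  cfg <- scene_config(point_density = 20)
  tr <- generate_trees(300, "conifer", cfg, seed = 9)
  pre <- simulate_point_cloud(tr, cfg, severity = 0, seed = 4)
  post <- simulate_point_cloud(tr, cfg, severity = 3, seed = 4)
  n_pre <- sum(pre$height_m > 2); n_post <- sum(post$height_m > 2)
  expect_gte(1 - n_post / n_pre, 0.70)
  expect_equal(max(post$height_m), max(pre$height_m))
})

test_that("plot filtering drops GPS failures and low cover, boundaries exact", {
  cfg <- scene_config()
  pl <- generate_field_plots(cfg, n_plots = 71, seed = 13)
  kept <- filter_plots(pl)
  expect_equal(nrow(kept$plots), 65)
  expect_equal(nrow(filter_plots(pl$plots, Inf, 0)), 71)            # identity
  df <- data.frame(plot_id = 1:3, gps_error_m = c(0.2, 0.2, 3),
                   fractional_cover = c(0.10, 0.09, 0.5))
  out <- filter_plots(df)
  expect_equal(out$plot_id, 1L)                                     # FC = 0.10 retained
  expect_error(filter_plots(df[2, ]), class = "firecarb_empty_calibration")
  # order preserved
  pl2 <- filter_plots(pl$plots)
  expect_false(is.unsorted(pl2$plot_id))
})

test_that("scene truth is mass-monotone with severity-ordered consumption", {
  sc <- tiny_scene()
  cfg <- sc$config
  expect_true(all(sc$agb_post <= sc$agb_pre + 1e-12))
  cf <- (sc$agb_pre - sc$agb_post) / sc$agb_pre
  expect_equal(max(abs(cf - cfg$consumption_fractions[sc$severity + 1L])), 0,
               tolerance = 1e-12)
  m <- vapply(0:3, function(s) mean(cf[sc$severity == s]), numeric(1))
  expect_true(all(diff(m) > 0))
  # class fractions inside the perimeter match the configuration
  frac <- as.numeric(table(factor(sc$severity[sc$burned], 0:3))) / sum(sc$burned)
  expect_equal(frac, unname(cfg$severity_fractions), tolerance = 0.01)
})

test_that("identical seed reproduces the scene and its tiles exactly", {
  cfg <- scene_config(grid_rows = 6, grid_cols = 6, point_density = 4, seed = 55)
  s1 <- simulate_scene(cfg); s2 <- simulate_scene(cfg)
  expect_identical(s1$agb_pre, s2$agb_pre)
  expect_identical(s1$severity, s2$severity)
  expect_identical(s1$refl_pre, s2$refl_pre)
  expect_identical(scene_tile(s1, 17), scene_tile(s2, 17))
})

test_that("unburned cells keep their reflectance across dates up to noise", {
  sc <- tiny_scene()
  unb <- sc$severity == 0
  d <- abs(sc$refl_pre$B5[unb] - sc$refl_post$B5[unb])
  expect_lt(mean(d), 4 * sc$config$reflectance_noise)
  # burned cells lose NIR and gain SWIR on the postfire date
  hi <- sc$severity == 3
  expect_lt(mean(sc$refl_post$B5[hi] - sc$refl_pre$B5[hi]), 0)
  expect_gt(mean(sc$refl_post$B6[hi] - sc$refl_pre$B6[hi]), 0)
})

test_that("reflectance response is monotone in biomass without noise", {
  cfg <- scene_config(grid_rows = 2, grid_cols = 2, reflectance_noise = 0, seed = 1)
  fake <- structure(list(config = cfg,
                         agb_pre = matrix(c(0, 50, 200, 600), 2, 2),
                         severity = matrix(0L, 2, 2),
                         dem = matrix(1000, 2, 2)),
                    class = "fc_scene")
  refl <- simulate_reflectance(fake, "pre")
  ndii <- vegetation_indices(refl)$NDII
  expect_true(all(diff(ndii[order(fake$agb_pre)]) > 0))
  # a bare cell shows the soil spectrum exactly (no canopy, no noise)
  expect_equal(refl$B5[1, 1], 0.26, tolerance = 1e-9)
})

test_that("NDII tracks true biomass over unburned cells at default noise", {
  sc <- simulate_scene(scene_config(grid_rows = 30, grid_cols = 30,
                                    point_density = 0.5, seed = 23))
  unb <- sc$severity == 0
  ndii <- vegetation_indices(sc$refl_pre)$NDII
  expect_gt(cor(ndii[unb], sc$agb_pre[unb]), 0.7)
})

test_that("rasters, tiles and plot tables round-trip through their text formats", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1.5, -2.25, NA, 4), 2, 2)
  write_asc(m, file.path(dir, "m.asc"))
  m2 <- read_asc(file.path(dir, "m.asc"))
  expect_equal(m, m2, ignore_attr = TRUE)

  tile <- random_tile(50, seed = 8)
  write_tile_xyz(tile, file.path(dir, "t.xyz.gz"))
  t2 <- read_tile_xyz(file.path(dir, "t.xyz.gz"))
  expect_equal(t2$height_m, tile$height_m)
  expect_equal(t2$intensity, tile$intensity)
  expect_equal(t2$range_m, tile$range_m)
  expect_equal(t2$return_number, tile$return_number)

  pl <- generate_field_plots(scene_config(), n_plots = 10, seed = 3)
  write_plots_csv(pl$plots, file.path(dir, "p.csv"))
  p2 <- utils::read.csv(file.path(dir, "p.csv"))
  expect_equal(p2$agb_Mg_ha, pl$plots$plot_agb_Mg_ha)
  expect_equal(p2$gps_error_m, pl$plots$gps_error_m)
})

test_that("infeasible biomass targets are signalled", {
  cfg <- scene_config()
  cfg$max_trees <- 3
  expect_error(generate_trees(600, "conifer", cfg, seed = 1),
               class = "firecarb_infeasible_target")
})
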