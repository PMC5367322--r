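# hand-built point-cloud tile with full control over every field
make_tile <- function(height, intensity = rep(1, length(height)),
                      range_m = rep(600, length(height)),
                      return_number = rep(1L, length(height)),
                      area_m2 = 900, cell_id = NA_integer_) {
  structure(list(height_m = height, intensity = intensity, range_m = range_m,
                 return_number = return_number, cell_id = cell_id,
                 area_m2 = area_m2, x = NULL, y = NULL,
                 empty = length(height) == 0L),
            class = "fc_tile")
}

# random canopy-ish tile for property suites
random_tile <- function(n = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_tile(height = c(stats::runif(n %/% 2, 0, 30), stats::rnorm(n - n %/% 2, 0, 0.05)),
            intensity = stats::runif(n, 0, 100),
            range_m = stats::runif(n, 550, 650),
            return_number = sample.int(4L, n, replace = TRUE))
}

# small scene shared across tests (built once per test run)
tiny_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_scene(scene_config(grid_rows = 16, grid_cols = 16,
                                            point_density = 5, seed = 101))
    cache
  }
})

# small hyperparameter grids that keep test-time model fits quick
test_h_grid <- 10^seq(-1, 2, length.out = 6)
test_gamma_grid <- 10^seq(-1, 4, length.out = 6)
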