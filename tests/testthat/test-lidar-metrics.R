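test_that("intensity range normalization follows the inverse-square law", {
  tile <- make_tile(c(5, 10), intensity = c(100, 100), range_m = c(600, 1200))
  out <- normalize_intensity(tile, reference_range_m = 600)
  expect_equal(out$intensity, c(100, 400))
  # identity at the reference range
  out2 <- normalize_intensity(make_tile(5, 100, 600), reference_range_m = 600)
  expect_equal(out2$intensity, 100)
  # rank order preserved at equal range
  set.seed(4)
  tl <- make_tile(runif(50, 0, 20), intensity = runif(50, 0, 80),
                  range_m = rep(700, 50))
  expect_equal(order(normalize_intensity(tl, 600)$intensity), order(tl$intensity))
  bad <- make_tile(1, 1, range_m = numeric(0))
  expect_error(normalize_intensity(bad), class = "firecarb_no_range")
})

test_that("height metrics match hand-computed values", {
  m <- height_metrics(make_tile(c(3, 4, 5, 6, 7)))
  expect_equal(unname(m["H50"]), 5)
  expect_equal(unname(m["canopy_depth"]), 4)
  expect_equal(unname(m["cover_ratio"]), 1)
  m2 <- height_metrics(make_tile(c(rep(0.5, 6), 3, 5, 9, 11)))
  expect_equal(unname(m2["cover_ratio"]), 0.4)
  expect_error(height_metrics(make_tile(numeric(0))), class = "firecarb_empty_tile")
  # no canopy returns: canopy statistics zero, cover ratio normal
  m3 <- height_metrics(make_tile(c(0, 0.5, 1)))
  expect_equal(unname(m3["H50"]), 0)
  expect_equal(unname(m3["cover_ratio"]), 0)
})

test_that("height percentile chain is monotone on random tiles", {
  for (i in 1:200) {
    m <- height_metrics(random_tile(sample(5:400, 1), seed = i))
    q <- m[c("H25", "H50", "H75", "H90", "H99")]
    expect_true(!is.unsorted(q))
  }
})

test_that("intensity metrics: energy fractions and density weighting", {
  # uniform intensity, half the returns canopy
  tile <- make_tile(c(rep(1, 5), rep(10, 5)), intensity = rep(1, 10))
  m <- intensity_metrics(tile)
  expect_equal(unname(m["FC_energy"]), 0.5)
  expect_equal(unname(m["CRS"]), 5)
  # accumulated intensity is a monotone chain bounded by 1
  mt <- intensity_metrics(random_tile(300, seed = 42))
  ai <- mt[c("AI_H25", "AI_H50", "AI_H75", "AI_H90", "AI_H99")]
  expect_true(!is.unsorted(ai))
  expect_lte(max(ai), 1)
  # dwCRS invariant under duplicating every return
  t1 <- random_tile(100, seed = 7)
  t2 <- make_tile(rep(t1$height_m, 2), rep(t1$intensity, 2),
                  rep(t1$range_m, 2), rep(t1$return_number, 2))
  expect_equal(intensity_metrics(t2)[["dwCRS"]], intensity_metrics(t1)[["dwCRS"]])
})

test_that("energy ratios are defined as zero for zero total intensity", {
  tile <- make_tile(c(1, 5), intensity = c(0, 0))
  m <- intensity_metrics(tile)
  expect_equal(unname(m["FC_energy"]), 0)
  expect_equal(unname(m["AI_H50"]), 0)
})

test_that("pseudowaveforms conserve energy at any bin width", {
  tile <- make_tile(3.2, intensity = 5)
  wf <- build_pseudowaveform(tile)
  expect_equal(sum(wf$amplitude > 0), 1)
  expect_equal(max(wf$amplitude), 5)
  expect_equal(wf$total_energy, 5)
  for (i in 1:25) {
    tl <- random_tile(sample(10:300, 1), seed = 100 + i)
    w1 <- build_pseudowaveform(tl, 0.5)
    w2 <- build_pseudowaveform(tl, 0.25)
    expect_equal(sum(w1$amplitude), sum(tl$intensity), tolerance = 1e-9)
    expect_equal(sum(w2$amplitude), sum(w1$amplitude), tolerance = 1e-9)
  }
})

test_that("waveform metrics: median energy height interpolates symmetric profiles", {
  # equal amplitude centred at 3 m and 7 m: the median energy sits at 5 m
  wf <- structure(list(bin_edges = c(1, 5, 9), amplitude = c(4, 4),
                       total_energy = 8, bin_width_m = 4, n_pulses = 10),
                  class = "fc_pseudowaveform")
  m <- waveform_metrics(wf)
  expect_equal(unname(m["HOME"]), 5)
  # all energy below the canopy threshold: AUCW is zero
  low <- build_pseudowaveform(make_tile(c(0.2, 1.1), intensity = c(3, 2)))
  expect_equal(unname(waveform_metrics(low)["AUCW"]), 0)
  expect_error(waveform_metrics(structure(list(bin_edges = 0:1, amplitude = 0,
                                               total_energy = 0, bin_width_m = 1,
                                               n_pulses = 1),
                                          class = "fc_pseudowaveform")),
               class = "firecarb_zero_energy")
})

test_that("AUCW strictly decreases when canopy energy is deleted", {
  tl <- random_tile(400, seed = 21)
  a1 <- waveform_metrics(build_pseudowaveform(tl))[["AUCW"]]
  canopy <- tl$height_m > 2
  tl$intensity[canopy] <- tl$intensity[canopy] * 0.6
  a2 <- waveform_metrics(build_pseudowaveform(tl))[["AUCW"]]
  expect_lt(a2, a1)
  # a bin straddling the 2 m threshold can hold a little unscaled energy
  expect_equal(a2 / a1, 0.6, tolerance = 1e-3)
})

test_that("metrics are invariant under return-order permutation", {
  tl <- random_tile(150, seed = 31)
  set.seed(99); p <- sample(150)
  tp <- make_tile(tl$height_m[p], tl$intensity[p], tl$range_m[p], tl$return_number[p])
  expect_equal(cell_metrics(tl), cell_metrics(tp))
})

test_that("cover and energy fractions hit 1 when every return is canopy", {
  tl <- make_tile(runif(40, 5, 20), intensity = runif(40, 1, 10))
  m <- cell_metrics(tl)
  expect_equal(unname(m["cover_ratio"]), 1)
  expect_equal(unname(m["FC_energy"]), 1)
})

test_that("rasterized metric stacks equal the per-tile oracle and ignore order", {
  tiles <- lapply(1:6, function(i) {
    t <- random_tile(80, seed = 300 + i); t$cell_id <- i; t
  })
  stack <- rasterize_metrics(tiles, nrow = 2, ncol = 3)
  shuffled <- rasterize_metrics(tiles[c(4, 2, 6, 1, 3, 5)], nrow = 2, ncol = 3)
  expect_identical(stack, shuffled)
  for (i in 1:6) {
    oracle <- cell_metrics(tiles[[i]])
    got <- vapply(names(oracle), function(nm) stack[[nm]][i], numeric(1))
    expect_equal(got, oracle)
  }
  tiles[[1]]$cell_id <- 99L
  expect_error(rasterize_metrics(tiles, 2, 3), class = "firecarb_grid_mismatch")
})

test_that("AUCW tracks simulated canopy cover on unburned cells", {
  sc <- tiny_scene()
  mets <- rasterize_metrics(sc)
  unb <- sc$severity == 0 & !is.na(mets$AUCW)
  expect_gt(cor(mets$AUCW[unb], mets$cover_ratio[unb]), 0.9)
})
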