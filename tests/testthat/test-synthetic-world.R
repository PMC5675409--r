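test_that("the same configuration and seed give a bit-identical world", {
  cfg <- world_config(seed = 11, grid_shape = c(6, 6), n_years = 3)
  w1 <- make_world(cfg)
  w2 <- make_world(cfg)
  expect_identical(w1$red$values, w2$red$values)
  expect_identical(w1$stations, w2$stations)
  expect_identical(w1$truth$npp_annual, w2$truth$npp_annual)
  w3 <- make_world(world_config(seed = 12, grid_shape = c(6, 6), n_years = 3))
  expect_false(identical(w1$truth$npp_annual, w3$truth$npp_annual))
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(n_years = 1), "n_years")
  expect_error(world_config(grid_shape = c(0, 5)), "grid_shape")
  expect_error(world_config(n_stations = 1), "n_stations")
  expect_error(world_config(precip_annual_mean = -10), "precip_annual_mean")
  expect_error(world_config(npp_precip_coupling = -1), "coupling")
  expect_error(make_world(list(seed = 1)), "world_config")
})

test_that("noiseless pure-precipitation coupling gives r = 1 at every vegetated pixel", {
  w <- noiseless_world()
  ann <- w$truth$npp_annual
  precip_y <- climate_yearly(w$truth$precipitation, fun = "sum")
  veg <- which(w$landcover > 0, arr.ind = TRUE)
  rs <- apply(veg, 1, function(ij)
    cor(ann[ij[1], ij[2], ], precip_y$values[ij[1], ij[2], ]))
  expect_true(all(abs(rs - 1) < 1e-12))
})

test_that("July-September hold at least half the annual precipitation at every pixel", {
  w <- make_world(world_config(seed = 1, grid_shape = c(20, 20), n_years = 13))
  total <- climate_yearly(w$truth$precipitation, fun = "sum")
  jas <- climate_yearly(w$truth$precipitation, months = 7:9, fun = "sum")
  share <- jas$values / total$values
  expect_true(all(share >= 0.5))
})

test_that("column-mean latent productivity is non-decreasing west to east", {
  for (seed in 1:3) {
    w <- make_world(world_config(seed = seed, grid_shape = c(12, 12),
                                 n_years = 4, precip_gradient = 0.4))
    veg <- w$landcover > 0
    for (y in 1:4) {
      ann <- w$truth$npp_annual[, , y]
      colmean <- vapply(seq_len(ncol(ann)), function(j)
        mean(ann[veg[, j], j]), numeric(1))     # vegetated column means
      colmean <- colmean[!is.nan(colmean)]
      expect_true(all(diff(colmean) >= -1e-9))
    }
  }
})

test_that("NDVI recomputed from reflectance matches the generating NDVI", {
  w <- tiny_world()
  ndvi <- compute_ndvi(w$red$values, w$nir$values)
  # back out the generating NDVI from the recorded latent productivity
  latent <- w$truth$npp_monthly$values
  target <- latent * (0.85 / max(latent))
  target[array(w$landcover == 0, dim(target))] <- 0.05
  expect_lt(max(abs(ndvi - target)), 1e-10)
})

test_that("reflectance stays physical and rasters share one grid", {
  w <- tiny_world()
  expect_true(all(w$red$values > 0 & w$red$values < 1))
  expect_true(all(w$nir$values > 0 & w$nir$values < 1))
  expect_true(grasscasa:::grids_identical(w$red$grid, w$nir$grid))
  expect_identical(dim(w$landcover), c(w$grid$rows, w$grid$cols))
  expect_identical(unname(w$truth$couplings["precip"]),
                   w$config$npp_precip_coupling)
})

test_that("stations sit on pixel centres inside the grid and carry valid records", {
  w <- tiny_world()
  st <- unique(w$stations[c("x", "y")])
  cell <- locate_pixel(w$grid, st$x, st$y)
  expect_equal(nrow(cell), w$config$n_stations)
  expect_true(all(w$stations$precip_mm >= 0))
  expect_true(all(w$stations$sunshine_h >= 0 & w$stations$sunshine_h <= 744))
  expect_equal(nrow(w$stations), w$config$n_stations * w$config$n_years * 12)
})

test_that("validation plots recover latent NPP exactly when noiseless", {
  w <- noiseless_world()
  plots <- make_validation_plots(w, n_plots = 46, obs_noise_sd = 0,
                                 year = 3, through_month = 7)
  expect_equal(nrow(plots), 46L)
  expect_equal(biomass_to_npp(plots$agb, plots$bgb), plots$true_npp,
               tolerance = 1e-12)
  expect_error(make_validation_plots(w, n_plots = 0), "n_plots")
  expect_error(make_validation_plots(w, n_plots = 5, year = 99), "span")
})

test_that("livestock series has one value per county-year and never goes negative", {
  w <- make_world(world_config(seed = 3, grid_shape = c(9, 9), n_years = 13))
  stock <- make_livestock_series(w, trend = 0)
  expect_equal(nrow(stock), 9L * 13L)
  for (cid in unique(stock$county)) {
    s <- stock$standard_sheep[stock$county == cid]
    expect_equal(length(s), 13L)
    expect_true(all(s == s[1]))                     # trend 0 -> constant
  }
  crash <- make_livestock_series(w, trend = -1e9)
  expect_true(all(crash$sheep >= 0))
  expect_true(all(crash$standard_sheep >= 0))
  expect_true(any(crash$sheep == 0))
})
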