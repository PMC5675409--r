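test_that("NDVI follows its definition and flags degenerate reflectance", {
  expect_equal(compute_ndvi(0.08, 0.24), 0.5)
  expect_equal(compute_ndvi(0.3, 0.3), 0)
  expect_true(is.na(compute_ndvi(0, 0)))
  expect_error(compute_ndvi(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(compute_ndvi(0.1, 1.5), "\\[0, 1\\]")
})

test_that("monthly compositing takes the per-pixel maximum and keeps nodata minimal", {
  grid <- raster_grid(2, 2)
  arr <- array(c(0.2, 0.1, NA, 0.3,
                 0.5, 0.05, NA, 0.1,
                 0.3, 0.2, NA, NA), c(2, 2, 3))
  stk <- monthly_stack(arr, grid, 1L, 6L, "ndvi")
  out <- composite_monthly(stk)
  expect_equal(length(out$year), 1L)
  expect_equal(out$values[1, 1, 1], 0.5)
  expect_equal(out$values[2, 1, 1], 0.2)
  expect_true(is.na(out$values[1, 2, 1]))          # nodata in all inputs
  expect_equal(out$values[2, 2, 1], 0.3)           # max over the valid two
  # identical layers compose to themselves
  same <- monthly_stack(array(0.4, c(2, 2, 3)), grid, 1L, 6L)
  expect_true(all(composite_monthly(same)$values == 0.4))
})

test_that("simple ratio is exact and strictly monotone on [-1, 1)", {
  expect_equal(compute_sr(0), 1)
  expect_equal(compute_sr(0.5), 3)
  expect_equal(compute_sr(-1), 0)
  expect_true(is.na(compute_sr(1)))
  nd <- seq(-1, 0.99, by = 0.01)
  expect_true(all(diff(compute_sr(nd)) > 0))
})

test_that("FPAR rescaling maps the class bounds to 0.001/0.95 and clamps", {
  expect_equal(fpar_from_ndvi(0.1, 0.1, 0.8), 0.001)
  expect_equal(fpar_from_ndvi(0.8, 0.1, 0.8), 0.95)
  expect_equal(fpar_from_ndvi(0.45, 0.1, 0.8), (0.001 + 0.95) / 2)
  # adversarial inputs, including the +-1 extremes, stay inside the bounds
  nd <- c(-1, -0.5, 0, 0.0999, 0.1, 0.5, 0.8, 0.9, 1)
  f <- fpar_from_ndvi(nd, 0.1, 0.8)
  expect_true(all(f >= 0.001 & f <= 0.95))
  sr <- compute_sr(c(-1, 0, 0.5, 0.9, 0.99))
  fs <- fpar_from_sr(sr, 1.2, 20)
  expect_true(all(fs >= 0.001 & fs <= 0.95))
  expect_equal(fpar_from_sr(1.2, 1.2, 20), 0.001)
  expect_equal(fpar_from_sr(20, 1.2, 20), 0.95)
  expect_equal(fpar_from_sr(50, 1.2, 20), 0.95)    # beyond sr_max: clamped
  expect_error(fpar_from_ndvi(0.5, 0.8, 0.1), "ndvi_min < ndvi_max")
})

test_that("the combined FPAR is the arithmetic mean of the two estimates", {
  expect_equal(compute_fpar(0.3, 0.3), 0.3)
  expect_equal(compute_fpar(0.2, 0.4), 0.3)
  expect_equal(compute_fpar(0.001, 0.95), 0.4755)
})

test_that("class bounds are NDVI percentiles with SR evaluated at them", {
  grid <- raster_grid(10, 10)
  set.seed(9)
  arr <- array(runif(100 * 24, 0.1, 0.9), c(10, 10, 24))
  stk <- monthly_stack(arr, grid, rep(1:2, each = 12), rep(1:12, 2), "ndvi")
  lc <- matrix(1L, 10, 10)
  cp <- calibrate_class_bounds(stk, lc)
  samples <- as.vector(arr)
  expect_equal(cp$ndvi_min[cp$name == "grassland"],
               unname(quantile(samples, 0.05)), tolerance = 1e-12)
  expect_equal(cp$ndvi_max[cp$name == "grassland"],
               unname(quantile(samples, 0.95)), tolerance = 1e-12)
  # uniform(0.1, 0.9): 5th/95th percentiles near 0.14 and 0.86
  expect_lt(abs(cp$ndvi_min[cp$name == "grassland"] - 0.14), 0.01)
  expect_lt(abs(cp$ndvi_max[cp$name == "grassland"] - 0.86), 0.01)
  # SR bounds by construction
  expect_equal(cp$sr_min[cp$name == "grassland"],
               compute_sr(cp$ndvi_min[cp$name == "grassland"]))
  # constant NDVI -> degenerate bounds
  flat <- monthly_stack(array(0.4, c(10, 10, 24)), grid,
                        rep(1:2, each = 12), rep(1:12, 2), "ndvi")
  expect_error(calibrate_class_bounds(flat, lc), "degenerate")
  # too few samples -> error naming the class
  few <- monthly_stack(array(runif(100), c(10, 10, 1)), grid, 1L, 7L, "ndvi")
  lc_few <- matrix(0L, 10, 10); lc_few[1, 1:5] <- 1L
  expect_error(calibrate_class_bounds(few, lc_few), "grassland.*5 valid")
})

test_that("first temperature stress scalar follows its quadratic and frost cutoff", {
  expect_equal(temp_stress_1(20), 0.8 + 0.4 - 0.2)
  expect_equal(temp_stress_1(0), 0.8)
  expect_equal(temp_stress_1(20, t = -15), 0)       # month below -10 degC
  expect_equal(temp_stress_1(20, t = -10), 0)
  expect_gt(temp_stress_1(20, t = -9.9), 0)
  expect_true(all(temp_stress_1(seq(-50, 90, by = 5)) >= 0))
})

test_that("second temperature stress scalar matches its double-logistic form", {
  f <- function(t, t_opt) 1.1814 /
    (1 + exp(0.2 * (t_opt - 10 - t))) / (1 + exp(0.3 * (-t_opt - 10 + t)))
  for (t_opt in c(5, 15, 25)) {
    for (t in c(-20, 0, t_opt, t_opt + 5)) {
      expect_equal(temp_stress_2(t, t_opt), f(t, t_opt), tolerance = 1e-12)
    }
    # cold limit: vanishes
    expect_lt(temp_stress_2(-80, t_opt), 1e-5)
    # hot asymmetry: 13 degC above optimum is worse than the optimum
    expect_lt(temp_stress_2(t_opt + 13, t_opt), temp_stress_2(t_opt, t_opt))
    # cap: never exceeds the optimum value once t > t_opt + 10
    expect_lte(temp_stress_2(t_opt + 10.5, t_opt), temp_stress_2(t_opt, t_opt))
  }
})

test_that("moisture stress spans [0.5, 1] with the dry limit at 0.5", {
  expect_equal(moisture_stress(50, 50), 1)
  expect_equal(moisture_stress(0, 50), 0.5)
  expect_equal(moisture_stress(25, 50), 0.75)
  expect_equal(moisture_stress(10, 0), 0.5)         # no demand = driest limit
  expect_true(all(moisture_stress(runif(20, 0, 100), runif(20, 0, 100)) >= 0.5))
})

test_that("Thornthwaite PET is zero at or below freezing and grows with warmth", {
  tm <- c(-18, -15, -5, 3, 10, 16, 20, 18, 11, 3, -8, -16)
  pet <- thornthwaite_pet(tm, latitude = 44)
  expect_equal(length(pet), 12L)
  expect_true(all(pet[tm <= 0] == 0))
  expect_true(pet[7] > pet[5])                      # July demand > May
  expect_true(all(pet >= 0))
})

test_that("the soil bucket keeps EET within supply and demand", {
  set.seed(2)
  pr <- matrix(runif(48, 0, 80), 4, 12)
  tm <- matrix(rep(c(-10, -5, 0, 8, 14, 18, 21, 19, 12, 5, -3, -8), each = 4),
               4, 12)
  pet <- thornthwaite_pet(tm, 44)
  eet <- bucket_eet(pr, pet, capacity_mm = 100)
  expect_true(all(eet >= 0))
  expect_true(all(eet <= pet + 1e-12))
  expect_true(all(eet <= pr + 100 + 1e-12))         # supply bound
  # with zero demand nothing evaporates
  expect_true(all(bucket_eet(pr, pet * 0) == 0))
})

test_that("light-use efficiency multiplies stress scalars into eps_max", {
  expect_equal(light_use_efficiency(1, 1, 1, 0.542), 0.542)
  expect_equal(light_use_efficiency(1, 1, 1, 0.429), 0.429)
  expect_equal(light_use_efficiency(0, 1, 1, 0.542), 0)
  expect_equal(light_use_efficiency(1, 0.5, 0.8, 0.542), 0.5 * 0.8 * 0.542)
})

test_that("APAR and monthly NPP follow their products and bounds", {
  expect_equal(compute_apar(100, 0.5), 25)
  expect_equal(compute_apar(100, 0), 0)
  expect_equal(compute_apar(100, 1), 50)            # upper bound 0.5 * SOL
  expect_equal(compute_npp_month(25, 0.542), 13.55)
  expect_equal(compute_npp_month(25, 0), 0)
  expect_true(is.na(compute_npp_month(NA, 0.5)))
})

test_that("full-grid CASA equals a per-pixel scalar reference on a 10x10 grid", {
  w <- make_world(world_config(seed = 31, grid_shape = c(10, 10), n_years = 3))
  ndvi <- w$red
  ndvi$values <- array(compute_ndvi(w$red$values, w$nir$values),
                       dim(w$red$values))
  ndvi$variable <- "ndvi"
  climate <- list(temperature = w$truth$temperature,
                  precipitation = w$truth$precipitation,
                  solar = w$truth$precipitation)    # placeholder, replaced next
  sol <- w$truth$precipitation
  for (i in seq_along(sol$year))
    sol$values[, , i] <- matrix(
      solar_from_sunshine(rep(150, 100), sol$month[i], 44), 10, 10)
  sol$variable <- "solar"
  climate$solar <- sol
  fit <- run_casa(ndvi, climate, w$landcover, latitude = 44)
  cp <- fit$class_params

  # scalar reference: compose the exported primitives pixel by pixel
  n_t <- length(ndvi$year)
  for (px in list(c(2, 3), c(5, 5), c(9, 10), c(1, 1))) {
    r <- px[1]; cc <- px[2]
    cls <- w$landcover[r, cc]
    k <- which(cp$class_id == cls)
    nd <- ndvi$values[r, cc, ]
    tc <- climate$temperature$values[r, cc, ]
    pr <- climate$precipitation$values[r, cc, ]
    so <- climate$solar$values[r, cc, ]
    if (cp$eps_max[k] <= 0) {
      expect_true(all(fit$npp$values[r, cc, ] == 0))
      next
    }
    fp <- compute_fpar(
      fpar_from_ndvi(nd, cp$ndvi_min[k], cp$ndvi_max[k]),
      fpar_from_sr(compute_sr(nd), cp$sr_min[k], cp$sr_max[k]))
    npp_ref <- numeric(n_t)
    pet_all <- numeric(n_t)
    for (y in unique(ndvi$year)) {
      sel <- which(ndvi$year == y)
      pet_all[sel] <- thornthwaite_pet(tc[sel], 44)
    }
    eet_all <- as.vector(bucket_eet(matrix(pr, 1), matrix(pet_all, 1), 100))
    for (i in seq_len(n_t)) {
      y <- ndvi$year[i]
      sel <- which(ndvi$year == y)
      t_opt <- tc[sel[which.max(nd[sel])]]
      eps <- light_use_efficiency(
        temp_stress_1(t_opt, tc[i]),
        temp_stress_2(tc[i], t_opt),
        moisture_stress(eet_all[i], pet_all[i]),
        cp$eps_max[k])
      npp_ref[i] <- compute_npp_month(compute_apar(so[i], fp[i]), eps)
      if (ndvi$month[i] %in% c(12, 1, 2)) npp_ref[i] <- 0
    }
    expect_lt(max(abs(fit$npp$values[r, cc, ] - npp_ref)), 1e-9)
  }
})

test_that("with unit stress scalars NPP is proportional to eps_max by class", {
  # constant SOL and FPAR, all scalars 1: grassland/shrub NPP ratio 0.542/0.429
  npp_grass <- compute_npp_month(compute_apar(120, 0.5),
                                 light_use_efficiency(1, 1, 1, 0.542))
  npp_shrub <- compute_npp_month(compute_apar(120, 0.5),
                                 light_use_efficiency(1, 1, 1, 0.429))
  expect_equal(npp_grass / npp_shrub, 0.542 / 0.429, tolerance = 1e-12)
})

test_that("CASA output is non-negative with winter identically zero", {
  w <- tiny_world()
  ndvi <- w$red
  ndvi$values <- array(compute_ndvi(w$red$values, w$nir$values),
                       dim(w$red$values))
  ndvi$variable <- "ndvi"
  climate <- build_climate_fields(w$stations, w$grid)
  fit <- run_casa(ndvi, climate, w$landcover)
  expect_true(all(fit$npp$values >= 0))
  winter <- fit$npp$month %in% c(12, 1, 2)
  expect_true(all(fit$npp$values[, , winter] == 0))
  expect_true(all(fit$fpar$values >= 0 & fit$fpar$values <= 0.95))
  # eps bounded by the Teps2 peak times eps_max
  expect_true(all(fit$eps$values <= 1.2 * 0.542))
})
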