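test_that("pearson_r reproduces exact linear relations and the covariance formula", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 11, 10, 13, 12)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 3), -1)
  set.seed(61)
  for (rep in 1:20) {
    a <- rnorm(13); b <- rnorm(13)
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_r(a, b), num / den, tolerance = 1e-12)
    expect_equal(pearson_r(a, b), pearson_r(b, a))   # symmetry
  }
  expect_true(is.na(pearson_r(rep(1, 5), rnorm(5))))
  expect_error(pearson_r(1:2, 1:2), ">= 3")
})

test_that("partial_r handles trivial control structures", {
  expect_equal(partial_r(0.6, 0, 0), 0.6)            # uncorrelated control
  expect_equal(partial_r(0.4 * 0.5, 0.4, 0.5), 0)    # fully mediated
  expect_true(is.na(partial_r(0.5, 1, 0.2)))         # collinear control
  expect_true(is.na(partial_r(0.5, 0.2, -1)))
  # invariant to swapping x1 and x2 (r13 and r23 exchange)
  expect_equal(partial_r(0.5, 0.3, 0.7), partial_r(0.5, 0.7, 0.3))
})

test_that("partial_r equals the residual-regression oracle on random triples", {
  set.seed(71)
  for (rep in 1:200) {
    n <- 30
    x3 <- rnorm(n)
    x1 <- 0.5 * x3 + rnorm(n)
    x2 <- -0.3 * x3 + rnorm(n)
    r12 <- cor(x1, x2); r13 <- cor(x1, x3); r23 <- cor(x2, x3)
    got <- partial_r(r12, r13, r23)
    oracle <- cor(resid(lm(x1 ~ x3)), resid(lm(x2 ~ x3)))
    expect_equal(got, oracle, tolerance = 1e-10)
    expect_lte(abs(got), 1)
  }
})

test_that("correlation maps recover the generating couplings on a noiseless world", {
  w <- noiseless_world()
  ann <- monthly_stack(w$truth$npp_annual, w$grid,
                       seq_len(w$config$n_years), 12L, "npp_annual")
  precip_y <- climate_yearly(w$truth$precipitation, fun = "sum")
  temp_y <- climate_yearly(w$truth$temperature, fun = "mean")
  veg <- w$landcover > 0
  cmap <- correlation_map(ann, precip_y, mask = veg)
  expect_true(all(abs(cmap$r[veg] - 1) < 1e-9))
  expect_true(all(is.na(cmap$r[!veg])))              # constant pixels: nodata
  expect_equal(cmap$kind, "correlation")
  # at zero noise NPP is exactly collinear with precipitation, so the
  # temperature partial is degenerate (control collinear -> nodata)
  pmap0 <- correlation_map(ann, temp_y, control = precip_y, mask = veg)
  expect_true(all(is.na(pmap0$r[veg])))
})

test_that("with temperature acting only through precipitation its partial is sign-neutral", {
  w <- make_world(world_config(seed = 19, grid_shape = c(10, 10),
                               n_years = 13, noise_sd = 0.05,
                               npp_temp_coupling = 0))
  ann <- monthly_stack(w$truth$npp_annual, w$grid, 1:13, 12L, "npp_annual")
  precip_y <- climate_yearly(w$truth$precipitation, fun = "sum")
  temp_y <- climate_yearly(w$truth$temperature, fun = "mean")
  veg <- w$landcover > 0
  pmap <- correlation_map(ann, temp_y, control = precip_y, mask = veg)
  expect_equal(pmap$kind, "partial")
  expect_equal(pmap$controlled, "precipitation")
  expect_true(median(abs(pmap$r[veg])) < 0.3)
  expect_true(all(pmap$p[veg] >= 0 & pmap$p[veg] <= 1))
})

test_that("correlation maps validate their inputs", {
  w <- noiseless_world()
  ann <- monthly_stack(w$truth$npp_annual, w$grid,
                       seq_len(w$config$n_years), 12L, "npp_annual")
  precip_y <- climate_yearly(w$truth$precipitation, fun = "sum")
  short <- monthly_stack(precip_y$values[, , 1:3], w$grid, 1:3, 12L, "p")
  expect_error(correlation_map(ann, short), "different years")
  other <- monthly_stack(array(1, c(2, 2, 6)), raster_grid(2, 2), 1:6, 12L, "p")
  expect_error(correlation_map(ann, other), "grid mismatch")
})

test_that("significance follows the t transform of r", {
  set.seed(81)
  grid <- raster_grid(2, 2)
  n <- 13
  arr_x <- array(rnorm(4 * n), c(2, 2, n))
  arr_y <- array(rnorm(4 * n), c(2, 2, n))
  xm <- monthly_stack(arr_x, grid, 1:n, 12L, "npp")
  ym <- monthly_stack(arr_y, grid, 1:n, 12L, "precipitation")
  m <- correlation_map(xm, ym)
  for (i in 1:2) for (j in 1:2) {
    ct <- cor.test(arr_x[i, j, ], arr_y[i, j, ])
    expect_equal(m$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(m$p[i, j], ct$p.value, tolerance = 1e-10)
  }
})

test_that("county table has the Table-1 shape and reduces to pixel r", {
  w <- noiseless_world()
  npp <- w$truth$npp_monthly
  tab <- county_table(npp, w$truth$precipitation, w$truth$temperature,
                      w$counties, mask = w$landcover > 0)
  expect_equal(nrow(tab), 9L)
  expect_true(all(c("AP", "AMT", "SpP", "SpMT", "SuP", "SuMT", "AuP",
                    "AuMT") %in% names(tab)))
  expect_true(all(abs(tab$AP - 1) < 1e-9))           # pure precip coupling
  expect_true(all(tab$AP_sig == "**"))
  # a county of one pixel equals the pixel-level coefficient
  counties1 <- matrix(1L, 10, 10); counties1[4, 7] <- 2L
  tab1 <- county_table(npp, w$truth$precipitation, w$truth$temperature,
                       counties1)
  npp_y <- climate_yearly(npp, 1:12, "sum")
  pr_y <- climate_yearly(w$truth$precipitation, 1:12, "sum")
  expect_equal(tab1$AP[tab1$county == 2],
               pearson_r(npp_y$values[4, 7, ], pr_y$values[4, 7, ]),
               tolerance = 1e-12)
  # identical counties give identical rows
  flat <- county_table(npp, w$truth$precipitation, w$truth$temperature,
                       matrix(rep(1:2, each = 50), 10, 10))
  expect_equal(flat$AP[1], flat$AP[2], tolerance = 1e-9)
})

test_that("map summaries report sign fractions and a partitioning histogram", {
  grid <- raster_grid(4, 4)
  mk <- function(rvals) {
    structure(list(r = matrix(rvals, 4, 4),
                   p = matrix(0.01, 4, 4), n_years = 13,
                   kind = "correlation", target = "precipitation",
                   controlled = NA_character_, grid = grid),
              class = "attribution_map")
  }
  s <- map_summary(mk(rep(0.5, 16)))
  expect_equal(s$frac_positive, 1)
  expect_equal(s$frac_negative, 0)
  s2 <- map_summary(mk(rep(c(0.5, -0.5), 8)))
  expect_equal(s2$frac_positive, 0.5)
  expect_equal(s2$frac_negative, 0.5)
  expect_equal(sum(s2$histogram$count), s2$n_valid)
  expect_equal(nrow(s2$histogram), 20L)
  set.seed(91)
  s3 <- map_summary(mk(runif(16, -1, 1)))
  expect_equal(s3$frac_positive + s3$frac_negative, 1)
  expect_equal(sum(s3$histogram$count), 16)
})
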