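test_that("synthetic fields are deterministic, masked and zero-calibrated", {
  spec <- obs_gen_spec(seed = 3)
  f1 <- generate_obs_field(spec)
  f2 <- generate_obs_field(spec)
  expect_identical(f1$field$values, f2$field$values)   # same seed, same field
  expect_false(identical(
    f1$field$values, generate_obs_field(obs_gen_spec(seed = 4))$field$values))
  # nonnegative, hard-zero outside the warm band
  expect_true(all(f1$field$values >= 0))
  latm <- matrix(f1$field$lat, spec$nlat, spec$nlon)
  expect_true(all(f1$field$values[abs(latm) > spec$warm_lat] == 0))
  # overall zero fraction matches the requested value (exact up to ties)
  expect_equal(mean(f1$field$values == 0), spec$zero_fraction,
               tolerance = 0.05)
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_obs_field(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("zero noise reproduces the noise-free truth exactly", {
  spec <- obs_gen_spec(sigma = 0, n_hotspots = 1, seed = 5)
  f <- generate_obs_field(spec)
  expect_identical(f$field$values, f$truth$values)
  expect_equal(nrow(f$hotspots), 1)
})

test_that("noisy-vs-truth misfit matches the lognormal closed form", {
  # Var(exp(sigma Z - sigma^2/2)) = exp(sigma^2) - 1, so
  # RMSE^2 = mean(truth^2) * (exp(sigma^2) - 1) over the valid mask
  spec <- obs_gen_spec(sigma = 0.1, seed = 7)   # 90 x 180 = 16200 cells
  f <- generate_obs_field(spec)
  r <- rmse_misfit(f$field, f$truth)
  m <- f$truth$mask
  closed_form <- sqrt(mean(f$truth$values[m]^2) * (exp(spec$sigma^2) - 1))
  expect_equal(r, closed_form, tolerance = 0.05)
})

test_that("sparse sampling is exact at full coverage and seed-stable", {
  spec <- obs_gen_spec(seed = 11)
  f <- generate_obs_field(spec)$field
  n_all <- sum(f$mask)
  pts <- sample_sparse_points(f, n_all, seed = 1)
  expect_equal(sort(pts$value), sort(f$values[f$mask]))
  expect_identical(sample_sparse_points(f, 50, seed = 2),
                   sample_sparse_points(f, 50, seed = 2))
  expect_error(sample_sparse_points(f, n_all + 1), "valid cells")
  # a 10% sample keeps the bloom-intensity percentile close to the full
  # field: 95% of replicates within 15%, all within 20% (100 replicates)
  p90_full <- bloom_intensity_p90(f)
  errs <- vapply(1:100, function(k) {
    sub <- sample_sparse_points(f, round(0.1 * n_all), seed = k)
    v <- sub$value[sub$value > 0]
    unname(stats::quantile(v, 0.9, type = 7)) / p90_full - 1
  }, numeric(1))
  expect_lt(unname(stats::quantile(abs(errs), 0.95)), 0.15)
  expect_lt(max(abs(errs)), 0.20)
})

test_that("regridding bins points to nearest cells with cell means", {
  spec <- obs_gen_spec(seed = 13)
  f <- generate_obs_field(spec)$field
  # single point -> a single valid cell holding its value
  one <- data.frame(lat = 10.2, lon = -120.3, value = 42)
  r1 <- regrid_to_model(one, f)
  expect_equal(sum(r1$mask), 1)
  expect_equal(r1$values[r1$mask], 42)
  # two points in one cell average
  two <- data.frame(lat = c(10.1, 10.2), lon = c(-120.2, -120.3),
                    value = c(1, 3))
  r2 <- regrid_to_model(two, f)
  expect_equal(r2$values[r2$mask], 2)
  # out-of-grid points are dropped with a message
  expect_message(regrid_to_model(
    data.frame(lat = c(0, 95), lon = c(0, 0), value = c(1, 2)), f),
    "dropped 1")
  # round trip: sampling every valid cell and regridding restores the field
  pts <- sample_sparse_points(f, sum(f$mask), seed = 1)
  rt <- regrid_to_model(pts, f)
  expect_equal(rt$values[f$mask], f$values[f$mask], tolerance = 1e-12)
  expect_true(all(rt$mask[f$values > 0]))
})
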