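eq_area <- function(v) matrix(1, nrow(v), ncol(v))

test_that("rmse_misfit is a unit-checked metric", {
  a <- gridded_field(matrix(c(1, 3), 1), "mmol N m-2 yr-1", matrix(1, 1, 2))
  b <- gridded_field(matrix(c(2, 2), 1), "mmol N m-2 yr-1", matrix(1, 1, 2))
  expect_equal(rmse_misfit(a, a), 0)
  # constant offset c gives |c|
  a5 <- gridded_field(a$values + 5, a$units, a$area)
  expect_equal(rmse_misfit(a, a5), 5)
  # 2-cell toy: model (1,3) vs obs (2,2) -> sqrt((1+1)/2) = 1
  expect_equal(rmse_misfit(a, b), 1)
  # metric axioms: symmetry, identity of indiscernibles, triangle inequality
  set.seed(1)
  for (k in 1:10) {
    x <- gridded_field(matrix(runif(12), 3), "u", matrix(1, 3, 4))
    y <- gridded_field(matrix(runif(12), 3), "u", matrix(1, 3, 4))
    z <- gridded_field(matrix(runif(12), 3), "u", matrix(1, 3, 4))
    expect_equal(rmse_misfit(x, y), rmse_misfit(y, x))
    expect_gt(rmse_misfit(x, y), 0)
    expect_lte(rmse_misfit(x, z),
               rmse_misfit(x, y) + rmse_misfit(y, z) + 1e-12)
  }
  # unit and grid congruence are enforced, never silently converted
  cc <- gridded_field(matrix(c(2, 2), 1), "mg C m-2", matrix(1, 1, 2))
  expect_error(rmse_misfit(a, cc), "unit mismatch")
  dd <- gridded_field(matrix(1, 2, 2), "mmol N m-2 yr-1", matrix(1, 2, 2))
  expect_error(rmse_misfit(a, dd), "congruent")
  # mask is respected; empty joint mask errors
  am <- gridded_field(matrix(c(1, 3), 1), a$units, matrix(1, 1, 2),
                      mask = matrix(c(TRUE, FALSE), 1))
  bm <- gridded_field(matrix(c(9, 9), 1), a$units, matrix(1, 1, 2),
                      mask = matrix(c(FALSE, TRUE), 1))
  expect_equal(rmse_misfit(am, a), 0)   # differing cell is masked out
  expect_error(rmse_misfit(am, bm), "empty joint")
})

test_that("bloom intensity is the upper decile of positive values", {
  v <- matrix(0, 10, 20)
  v[1:5, ] <- seq_len(100)              # values 1..100 plus zeros
  f <- gridded_field(v, "mg C m-2", eq_area(v))
  # brute-force oracle: linear-interpolation percentile of 1..100
  expect_equal(bloom_intensity_p90(f), 90.1)
  # inserting more zeros changes nothing (positivity filter)
  v2 <- rbind(v, matrix(0, 3, 20))
  f2 <- gridded_field(v2, "mg C m-2", eq_area(v2))
  expect_equal(bloom_intensity_p90(f2), 90.1)
  # uniform positive field returns that value
  u <- gridded_field(matrix(7, 2, 2), "mg C m-2", matrix(1, 2, 2))
  expect_equal(bloom_intensity_p90(u), 7)
  # all-zero field errors
  z <- gridded_field(matrix(0, 2, 2), "mg C m-2", matrix(1, 2, 2))
  expect_error(bloom_intensity_p90(z), "positive")
  # the alternative reading is exposed but distinct
  expect_gt(bloom_intensity_p90(f, method = "mean_top_decile"), 90.1)
})

test_that("chlorophyll conversion and oligotrophic area fraction", {
  p <- ecosystem_params()
  area <- c(1, 2, 3)
  f0 <- chlorophyll_field(c(0, 0, 0), c(0, 0, 0), area, p)
  expect_true(all(f0$values == 0))
  expect_identical(f0$units, "mg Chl a m-3")
  f1 <- chlorophyll_field(c(0.6, 0, 0.2), c(0.4, 0, 0.1), area, p)
  expect_equal(f1$values[1], 1.59)      # 1 mmol N m^-3 -> 1.59 mg Chl a m^-3
  expect_equal(as.numeric(chlorophyll_field(c(2 * 0.6), c(2 * 0.4), 1, p)$values),
               2 * f1$values[1])        # linearity
  # toy areas (1,2,3) with chl (0.05, 0.1, 0.05): fraction = (1+3)/6
  chl <- gridded_field(c(0.05, 0.1, 0.05), "mg Chl a m-3", area)
  expect_equal(oligotrophic_area_fraction(chl), 4 / 6)
  expect_equal(oligotrophic_area_fraction(
    gridded_field(c(0.5, 0.9), "mg Chl a m-3", c(1, 1))), 0)
  # equal-area cells, half below threshold
  expect_equal(oligotrophic_area_fraction(
    gridded_field(c(0.01, 0.5), "mg Chl a m-3", c(1, 1))), 0.5)
  # monotone non-decreasing in the threshold
  set.seed(2)
  v <- gridded_field(runif(50, 0, 0.2), "mg Chl a m-3", runif(50, 1, 2))
  fr <- vapply(seq(0.01, 0.2, by = 0.01),
               function(th) oligotrophic_area_fraction(v, th), numeric(1))
  expect_true(all(diff(fr) >= 0))
  # wrong units refused
  expect_error(oligotrophic_area_fraction(
    gridded_field(c(1, 2), "mg C m-2", c(1, 1))), "units")
})

test_that("exponential decay fitting recovers known timescales", {
  t <- 0:200
  f <- fit_exponential_decay_timescale(exp(-t / 500), t)
  expect_equal(f$tau_yr, 500, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # constant series: infinite timescale flagged
  expect_equal(fit_exponential_decay_timescale(rep(2, 50), 1:50)$tau_yr, Inf)
  # 1% multiplicative noise, fixed seed: within 2% of the 800-yr truth
  set.seed(42)
  y <- exp(-(0:199) / 800) * (1 + 0.01 * rnorm(200))
  expect_equal(fit_exponential_decay_timescale(y, 0:199)$tau_yr, 800,
               tolerance = 0.02)
  expect_error(fit_exponential_decay_timescale(c(1, 0, 1), 1:3), "10 points")
  expect_error(fit_exponential_decay_timescale(-(1:10), 1:10), "positive")
})

test_that("analytic niche-closure timescale", {
  expect_equal(niche_closure_timescale(5.5, 70), 1100)
  expect_equal(niche_closure_timescale(5.5, 200), 385)
  expect_equal(niche_closure_timescale(0, 100), 0)
  expect_error(niche_closure_timescale(-1, 100), ">= 0")
  expect_error(niche_closure_timescale(5.5, 0), "> 0")
})

test_that("diagnostics series flags undefined ratios and adds area fractions", {
  g <- box_geometry()
  cfg <- build_config("CONTR")
  run <- run_model(initial_state(g), g, cfg, years = 3)
  d <- diagnostics_series(run)
  expect_true(all(c("oligo_frac", "biomass_fixation_ratio") %in% names(d)))
  expect_true(all(d$oligo_frac >= 0 & d$oligo_frac <= 1))
  ok <- d$fixation_TgN_yr > 0
  expect_equal(d$biomass_fixation_ratio[ok],
               d$biomass_diaz_TgC[ok] / d$fixation_TgN_yr[ok])
  # zero-fixation years are flagged undefined, not divided
  run2 <- run
  run2$annual$fixation_TgN_yr[2] <- 0
  d2 <- diagnostics_series(run2)
  expect_true(is.na(d2$biomass_fixation_ratio[2]))
})
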