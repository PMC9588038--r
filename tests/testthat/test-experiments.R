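test_that("paradigm presets satisfy the experiment parameter relations", {
  cc <- build_config("CONTR")
  expect_equal(cc$params$theta_d, cc$params$theta_o)
  expect_equal(cc$params$k_P_d, cc$params$k_P)
  expect_true(cc$denitrification_enabled)

  gz <- build_config("GRAZ")
  expect_equal(gz$params$theta_d, 0.1)
  expect_equal(gz$params$theta_o, 0.3)
  expect_equal(gz$params$k_P_d, gz$params$k_P)

  ol <- build_config("OLIGO")
  expect_lt(ol$params$k_P_d, ol$params$k_P)
  expect_equal(ol$params$theta_d, ol$params$theta_o)

  dc <- build_config("DECAY")
  expect_false(dc$denitrification_enabled)
  expect_equal(dc$params$theta_d, dc$params$theta_o)

  # violating overrides are rejected with the offending key named
  expect_error(build_config("OLIGO", list(k_P_d = 0.1)), "k_P_d")
  expect_error(build_config("GRAZ", list(theta_d = 0.5)), "theta_d")
  expect_error(build_config("CONTR", list(theta_d = 0.1)), "theta_d")
  expect_error(build_config("DECAY", list(denitrification_enabled = TRUE)),
               "denitrification")
  expect_error(build_config("CONTR", list(nonsense = 1)), "unknown")
  # legal overrides pass through
  ov <- build_config("GRAZ", list(theta_d = 0.05, dt = 0.25))
  expect_equal(ov$params$theta_d, 0.05)
  expect_equal(ov$dt, 0.25)
})

test_that("identical configuration and seed reproduce runs bit-identically", {
  g <- box_geometry()
  cfg <- build_config("GRAZ")
  r1 <- run_model(initial_state(g), g, cfg, years = 5)
  r2 <- run_model(initial_state(g), g, cfg, years = 5)
  expect_identical(r1$annual, r2$annual)
  expect_identical(as.numeric(r1$state_final), as.numeric(r2$state_final))
  expect_identical(r1$chl, r2$chl)
})

test_that("spin-up reports drift honestly and scenario guards its paradigm", {
  g <- box_geometry()
  # a deliberately short cap cannot converge and must warn, not silently pass
  cfg <- build_config("CONTR",
                      list(spinup = list(max_years = 200, block_years = 100)))
  expect_warning(sp <- spinup_to_equilibrium(cfg, g), "drift tolerance")
  expect_false(sp$converged)
  expect_true(all(is.finite(sp$drift)))
  expect_equal(sp$years, 200)
  # paradigm mismatch is an error
  expect_error(run_scenario(build_config("OLIGO"), sp), "mismatch")
  # zero-amplitude ramp reproduces the continued pre-industrial run
  cfg0 <- build_config("CONTR",
                       list(warming = list(dT_surface = 0, mix_reduction = 0)))
  sc0 <- run_scenario(cfg0, sp)
  cont <- run_model(sp$state_final, g, cfg, years = 350)
  expect_equal(sc0$annual$fixation_TgN_yr, cont$annual$fixation_TgN_yr,
               tolerance = 1e-12)
  expect_equal(as.numeric(sc0$state_final), as.numeric(cont$state_final),
               tolerance = 1e-12)
})

test_that("sensitivity scans keep their bookkeeping promises", {
  g <- box_geometry()
  # short spin-ups: members are flagged not-converged and excluded from the
  # response means, and the table is ordered by parameter value
  cfg <- build_config("GRAZ",
                      list(spinup = list(max_years = 200, block_years = 100)))
  tab <- suppressMessages(
    sensitivity_scan(cfg, "theta_d", c(0.12, 0.08, 0.10), g))
  expect_equal(tab$value, c(0.08, 0.10, 0.12))
  expect_false(any(tab$converged))
  expect_true(is.na(attr(tab, "response")$dfix_per_step))
  expect_equal(attr(tab, "response")$step, 0.02)
  # degenerate single-member scan: response undefined, reported as such
  cfg_o <- build_config("OLIGO",
                        list(spinup = list(max_years = 200, block_years = 100)))
  expect_message(
    tab1 <- sensitivity_scan(cfg_o, "k_P_d", 0.01, g), "undefined")
  expect_true(is.na(attr(tab1, "response")$dfix_per_step))
  expect_equal(attr(tab1, "response")$step, 0.0088)
})

test_that("tipping-point detection finds constructed jumps and ignores flat scans", {
  flat <- data.frame(value = seq(0.02, 0.1, by = 0.02),
                     biomass_outside_TgC = rep(40, 5))
  expect_true(is.na(detect_tipping_point(flat)))
  jump <- data.frame(value = seq(0.02, 0.12, by = 0.02),
                     biomass_outside_TgC = c(50, 48, 45, 0.1, 0.05, 0.02))
  expect_equal(detect_tipping_point(jump), 0.08)
  # order of rows must not matter
  expect_equal(detect_tipping_point(jump[sample(nrow(jump)), ]), 0.08)
  # collapse at the low end is reported on the collapsed side too
  rev_jump <- data.frame(value = seq(0.02, 0.12, by = 0.02),
                         biomass_outside_TgC = c(0.01, 0.02, 30, 35, 40, 41))
  expect_equal(detect_tipping_point(rev_jump), 0.04)
  expect_error(detect_tipping_point(flat[1:3, ]), ">= 5")
})
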