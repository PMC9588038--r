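# Dynamical oracles: closed-form ecology checked against the integrated model.

test_that("chemostat R*: equilibrium nitrate matches k_N m / (J_max - m)", {
  cfg <- build_config("CONTR")
  p <- cfg$params
  # single light-saturated column, ordinary phytoplankton only, weak
  # vertical exchange so transport losses stay << mortality
  g1 <- single_box_geometry(w_mix = 1, J0 = 1)
  s <- initial_state(g1, no3_surface = 5, po4_surface = 0.5,
                     no3_deep = 25, po4_deep = 25 / 16,
                     phy_o = 0.1, phy_d = 0, zoo = 0, det = 0)
  r <- run_model(s, g1, cfg, years = 800)
  no3_eq <- r$state_final[1, "NO3", "surface"]
  rstar <- p$k_N * p$mortality / (p$J_O_max - p$mortality)
  expect_gt(r$state_final[1, "PhyO", "surface"], 0.01)  # survivor, not washout
  expect_equal(no3_eq, rstar, tolerance = 0.01)
})

test_that("competitive exclusion: diazotroph decay rate equals the growth deficit", {
  # N-replete single box, no grazing: ordinary phytoplankton pin PO4 at
  # their P*, where the diazotroph net rate is J_D(P*) - m = -(1 - C_d) m
  cfg <- build_config("CONTR")
  p <- cfg$params
  g1 <- single_box_geometry(w_mix = 1, J0 = 1)
  s <- initial_state(g1, no3_surface = 20, po4_surface = 0.5,
                     no3_deep = 30, po4_deep = 1,
                     phy_o = 0.2, phy_d = 0.01, zoo = 0, det = 0)
  r <- run_model(s, g1, cfg, years = 16, dt = 0.125)
  b <- r$annual$biomass_diaz_TgC
  expect_true(all(diff(b[4:16]) < 0))
  fit <- fit_exponential_decay_timescale(b[5:16], 5:16)
  tau_pred_yr <- 1 / ((1 - p$C_d) * p$mortality * 365)
  expect_equal(fit$tau_yr, tau_pred_yr, tolerance = 0.05)
  expect_gt(fit$r_squared, 0.999)
})

test_that("OLIGO calibration gives diazotrophs the lower phosphate R*", {
  p <- build_config("OLIGO")$params
  m <- p$mortality
  rstar_d <- p$k_P_d * m / (p$J_D_max - m)
  rstar_o <- p$k_P * m / (p$J_O_max - m)
  expect_lt(rstar_d, rstar_o)
  # whereas without the affinity advantage (CONTR) the handicap loses
  pc <- build_config("CONTR")$params
  expect_gt(pc$k_P_d * m / (pc$J_D_max - m), pc$k_P * m / (pc$J_O_max - m))
})

test_that("long closed-domain runs conserve phosphorus and close the N budget", {
  g <- box_geometry()
  for (paradigm in c("CONTR", "DECAY")) {
    cfg <- build_config(paradigm)
    s0 <- initial_state(g)
    mb0 <- mass_budget(s0, g, cfg$params)
    r <- run_model(s0, g, cfg, years = 60)
    mb1 <- mass_budget(r$state_final, g, cfg$params)
    expect_lt(abs(mb1$P_mol - mb0$P_mol) / mb0$P_mol, 1e-10)
    src_mol <- sum(r$annual$fixation_TgN_yr - r$annual$denit_TgN_yr) / 14 * 1e12
    expect_lt(abs(mb1$N_mol - mb0$N_mol - src_mol) / mb0$N_mol, 1e-9)
    expect_equal(r$clipped_mol, 0)
    if (paradigm == "DECAY") expect_true(all(r$annual$denit_TgN_yr == 0))
  }
})

test_that("warming ramp reduces mixing and warms the surface as specified", {
  g <- box_geometry()
  cfg <- build_config("OLIGO")
  cfg$scenario <- "warming"
  cfg$year0 <- 1800
  f0 <- forcing_at(0, g, cfg)                      # 1800: ramp at zero
  fmid <- forcing_at(175 * 365, g, cfg)            # 1975: halfway, w = 0.25
  fend <- forcing_at(350 * 365, g, cfg)            # 2150: ramp complete
  expect_equal(f0$w, 0)
  expect_equal(fmid$w, 0.25)
  expect_equal(fend$w, 1)
  expect_equal(fend$temp_s - g$boxes$temp,
               rep(cfg$warming$dT_surface, nrow(g$boxes)))
  expect_equal(fend$q_vert / f0$q_vert,
               rep(1 - cfg$warming$mix_reduction, nrow(g$boxes)))
  # pre-industrial scenario: no ramp at any time
  cfg$scenario <- "preindustrial"
  expect_equal(forcing_at(350 * 365, g, cfg)$w, 0)
})
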