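test_that("monod limitation obeys its identities and domain checks", {
  k <- 0.7
  expect_equal(monod(0, k), 0)
  expect_equal(monod(k, k), 0.5)
  expect_equal(monod(3 * k, k), 0.75)
  # monotone increasing in concentration
  conc <- seq(0, 10, by = 0.1)
  expect_true(all(diff(monod(conc, k)) > 0))
  expect_true(all(monod(conc, k) >= 0 & monod(conc, k) < 1))
  expect_error(monod(-1, k), "concentration")
  expect_error(monod(1, 0), "half-saturation")
})

test_that("growth rates implement Liebig's minimum and the diazotroph rules", {
  p <- ecosystem_params()
  # nitrate exhausted -> no ordinary growth whatever the other resources
  expect_equal(growth_rate_ordinary(10, 0, 5, p), 0)
  # half-saturation identity on the phosphate leg
  expect_equal(growth_rate_ordinary(10, 100, p$k_P, p), p$J_O_max / 2,
               tolerance = 1e-6)
  # light-limited branch of the minimum
  expect_equal(growth_rate_ordinary(0.1, 100, 100, p), 0.1, tolerance = 1e-3)
  # never exceeds any argument of the minimum
  for (J in c(0.05, 0.3, 2)) {
    r <- growth_rate_ordinary(J, 0.5, 0.02, p)
    expect_lte(r, J)
    expect_lte(r, p$J_O_max * monod(0.5, p$k_N) + 1e-15)
    expect_lte(r, p$J_O_max * monod(0.02, p$k_P) + 1e-15)
  }

  # temperature cutoff shuts diazotrophs off completely
  expect_equal(growth_rate_diazotroph(10, 100, 10, p), 0)
  expect_equal(growth_rate_diazotroph(10, p$k_P_d, 25, p), p$J_D_max / 2,
               tolerance = 1e-6)
  # nitrate independence: the signature takes no NO3 at all, and the
  # assembled tendencies agree (checked in the tendencies block below)
  expect_equal(growth_rate_diazotroph(10, 0.5, 25, p),
               min(10, p$J_D_max * monod(0.5, p$k_P_d)))
})

test_that("grazing flux is linear in prey with printed parameters", {
  p <- ecosystem_params()
  expect_equal(grazing_rate(1, 0, 0.3, p), 0)
  # mu_max = 0.4, theta_o = 0.3: 0.4 * 1 * 0.3 * 2 = 0.24
  expect_equal(grazing_rate(1, 2, 0.3, p), 0.24)
  # preference ratio at equal biomass: theta_d / theta_o = 1/3
  gr <- build_config("GRAZ")$params
  expect_equal(grazing_rate(1, 1, gr$theta_d, gr) /
                 grazing_rate(1, 1, gr$theta_o, gr), 1 / 3)
  expect_error(grazing_rate(-1, 1, 0.3, p), ">= 0")
  expect_error(grazing_rate(1, 1, 1.3, p), "theta")
})

test_that("tendencies close the nitrogen budget and conserve phosphorus", {
  cfg <- build_config("CONTR")
  p <- cfg$params
  # single closed box: pointwise closure, no transport
  g1 <- single_box_geometry(w_mix = 0)
  for (seed in 1:5) {
    s <- random_state(g1, seed)
    td <- tendencies(s, g1, p, cfg)
    dN <- sum(td$dstate[1, c(1, 3:6), 1]) + sum(td$dstate[1, c(1, 3:6), 2])
    # surface and deep volumes differ; weight accordingly
    dN_w <- sum(td$dstate[1, c(1, 3:6), 1]) * g1$V_s +
      sum(td$dstate[1, c(1, 3:6), 2]) * g1$V_d
    expect_equal(dN_w, td$fixation[1] * g1$V_s - td$denit[1] * g1$V_d,
                 tolerance = 1e-12)
    dP_w <- (td$dstate[1, 2, 1] + sum(td$dstate[1, 3:6, 1]) / p$r_NP) * g1$V_s +
      (td$dstate[1, 2, 2] + sum(td$dstate[1, 3:6, 2]) / p$r_NP) * g1$V_d
    expect_equal(dP_w / (g1$V_s + g1$V_d), 0, tolerance = 1e-18)
  }
  # full geometry: global closure including transport
  g <- box_geometry()
  for (seed in 6:8) {
    s <- random_state(g, seed)
    td <- tendencies(s, g, p, cfg)
    dN_glob <- sum((td$dstate[, 1, 1] + rowSums(td$dstate[, 3:6, 1])) * g$V_s) +
      sum((td$dstate[, 1, 2] + rowSums(td$dstate[, 3:6, 2])) * g$V_d)
    src <- sum(td$fixation * g$V_s) - sum(td$denit * g$V_d)
    expect_equal(dN_glob, src, tolerance = 1e-9 * abs(src) + 1e-6)
    dP_glob <- sum((td$dstate[, 2, 1] + rowSums(td$dstate[, 3:6, 1]) / p$r_NP) * g$V_s) +
      sum((td$dstate[, 2, 2] + rowSums(td$dstate[, 3:6, 2]) / p$r_NP) * g$V_d)
    scale_P <- sum(abs(td$dstate[, 2, 1]) * g$V_s) +
      sum(abs(td$dstate[, 2, 2]) * g$V_d)
    expect_lt(abs(dP_glob) / scale_P, 1e-12)
  }
})

test_that("tendencies respect configuration switches", {
  g <- box_geometry()
  s <- random_state(g, 11)
  # DECAY nulls the denitrification flux in every box
  td_d <- tendencies(s, g, config = build_config("DECAY"))
  expect_true(all(td_d$denit == 0))
  td_c <- tendencies(s, g, config = build_config("CONTR"))
  expect_true(any(td_c$denit > 0))
  # diazotroph growth is NO3-independent: changing NO3 leaves the
  # PhyD growth term unchanged (loss terms subtracted out)
  s2 <- s
  s2[, "NO3", "surface"] <- 10
  cfg <- build_config("CONTR")
  gd1 <- td_c$dstate[, "PhyD", "surface"] +
    td_c$grazing[, "PhyD"] + cfg$params$mortality * s[, "PhyD", "surface"]
  td2 <- tendencies(s2, g, config = cfg)
  gd2 <- td2$dstate[, "PhyD", "surface"] +
    td2$grazing[, "PhyD"] + cfg$params$mortality * s2[, "PhyD", "surface"]
  expect_equal(gd1, gd2, tolerance = 1e-12)
  # ... while fixation responds to NO3 (less fixation when NO3 is replete)
  expect_true(all(td2$fixation <= td_c$fixation + 1e-15))
  # empty ocean: nothing moves
  s0 <- initial_state(g); s0[] <- 0
  td0 <- tendencies(s0, g, config = cfg)
  expect_true(all(td0$dstate == 0))
  # invalid states are rejected
  sbad <- s; sbad[1, 1, 1] <- NaN
  expect_error(tendencies(sbad, g, config = cfg), "non-finite")
  sneg <- s; sneg[1, 1, 1] <- -1
  expect_error(tendencies(sneg, g, config = cfg), "negative")
})

test_that("the RK4 stepper is convergent, conservative and guards negatives", {
  g <- box_geometry()
  cfg <- build_config("CONTR")
  s0 <- initial_state(g)
  # zero tendencies leave the state unchanged
  sz <- initial_state(g); sz[] <- 0
  st <- step_state(sz, g, config = cfg, dt = 1)
  expect_identical(as.numeric(st$state), as.numeric(sz))
  # halving the step changes a 1-year trajectory by < 1e-6 relative
  r1 <- run_model(s0, g, cfg, years = 1, dt = 0.5)$state_final
  r2 <- run_model(s0, g, cfg, years = 1, dt = 0.25)$state_final
  expect_lt(max(abs(r1 - r2)) / max(abs(r2)), 1e-6)
  # phosphorus conserved over a closed-domain year
  p <- cfg$params
  mb0 <- mass_budget(s0, g, p)
  mb1 <- mass_budget(r1, g, p)
  expect_lt(abs(mb1$P_mol - mb0$P_mol) / mb0$P_mol, 1e-10)
  # a too-large step on a stiff transient raises the clip error
  g1 <- single_box_geometry()
  s <- initial_state(g1, no3_surface = 20, po4_surface = 0.5,
                     no3_deep = 30, po4_deep = 1,
                     phy_o = 0.2, phy_d = 0.01, zoo = 0, det = 0)
  expect_error(run_model(s, g1, cfg, years = 1, dt = 5), "reduce dt")
  expect_error(step_state(s0, g, config = cfg, dt = -1), "positive")
})

test_that("the compiled integrator reproduces the R reference bitwise-close", {
  g <- box_geometry()
  cfg <- build_config("GRAZ")
  s0 <- initial_state(g)
  rc <- run_model(s0, g, cfg, years = 1, dt = 1, engine = "cpp",
                  record_snapshots = TRUE)
  rr <- run_model(s0, g, cfg, years = 1, dt = 1, engine = "R",
                  record_snapshots = TRUE)
  expect_equal(as.numeric(rc$state_final), as.numeric(rr$state_final),
               tolerance = 1e-12)
  expect_equal(rc$annual$fixation_TgN_yr, rr$annual$fixation_TgN_yr,
               tolerance = 1e-10)
  expect_equal(rc$annual$denit_TgN_yr, rr$annual$denit_TgN_yr,
               tolerance = 1e-10)
  expect_equal(unname(rc$chl), unname(rr$chl), tolerance = 1e-10)
  expect_equal(as.numeric(rc$snapshots), as.numeric(rr$snapshots),
               tolerance = 1e-10)
})

test_that("mass budget converts units correctly", {
  p <- ecosystem_params()
  # 1 mmol N m^-3 in 1 m^3 is 14 mg N
  g <- single_box_geometry(area = 1, z_surface = 1, z_deep = 1)
  s <- initial_state(g); s[] <- 0
  s[1, "NO3", "surface"] <- 1
  mb <- mass_budget(s, g, p)
  expect_equal(mb$N_mol, 1e-3)
  expect_equal(mb$N_Tg * 1e12, 14e-3)  # grams
  # empty state -> all zeros
  s0 <- initial_state(g); s0[] <- 0
  mb0 <- mass_budget(s0, g, p)
  expect_true(all(unlist(mb0) == 0))
  # two-box toy: excess P in N equivalents matches hand arithmetic
  g2 <- box_geometry()
  s2 <- initial_state(g2); s2[] <- 0
  s2[1, "PO4", "surface"] <- 1     # mol P: 1e-3 * V_s[1]
  s2[2, "NO3", "surface"] <- 8     # mol N: 8e-3 * V_s[2]
  mb2 <- mass_budget(s2, g2, p)
  hand <- 16 * (1e-3 * g2$V_s[1]) - 8e-3 * g2$V_s[2]
  expect_equal(mb2$excess_P_molN, hand, tolerance = 1e-12)
})

test_that("excess-P rescaling hits its target and preserves the pattern", {
  g <- box_geometry()
  p <- ecosystem_params()
  s <- initial_state(g)
  s2 <- rescale_excess_p(s, g, p, 5.5e15)
  expect_equal(mass_budget(s2, g, p)$excess_P_molN, 5.5e15,
               tolerance = 1e-6 * 5.5e15)
  # only PO4 changes, and the deficit pattern is scaled, not shifted
  expect_identical(s2[, -2, ], s[, -2, ])
  d1 <- s[, "PO4", ] - s[, "NO3", ] / p$r_NP
  d2 <- s2[, "PO4", ] - s2[, "NO3", ] / p$r_NP
  ratio <- d2[abs(d1) > 1e-9] / d1[abs(d1) > 1e-9]
  expect_lt(diff(range(ratio)), 1e-9)
})
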