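test_that("specific growth rate combines Monod terms and H2 inhibition", {
  big <- c(S1 = 1e12, Yeast = 1e12, S2 = 1e12, H2l = 0)
  expect_equal(growth_rate(big, tm_p), 0.9, tolerance = 1e-9)
  # full inhibition wins regardless of substrates
  expect_equal(growth_rate(c(big[1:3], H2l = 1.44), tm_p), 0)
  # glucose at half saturation halves the rate
  half <- c(S1 = 5.7, Yeast = 1e12, S2 = 1e12, H2l = 0)
  expect_equal(growth_rate(half, tm_p), 0.45, tolerance = 1e-9)
  expect_error(growth_rate(c(S1 = -1, Yeast = 1, S2 = 1, H2l = 0), tm_p),
               "'S1'")
  expect_error(growth_rate(c(S1 = 1, Yeast = 1, S2 = NA, H2l = 0), tm_p),
               "'S2'")
  # bounded by mu_max along a whole trajectory
  expect_true(all(ref_sim()$trajectory$mu <= tm_p$mu_max + 1e-12))
})

test_that("sterile gas-free state has an identically zero derivative", {
  oc <- operating_conditions()
  y0 <- initial_state(tm_p, tm_cc, oc)
  y0["X"] <- 0
  kla <- kla_for_flow(oc$q_n2, tm_cc)
  d <- fermentation_rhs(0, y0, tm_p, tm_cc, oc, kla)[[1]]
  expect_true(all(d == 0))
})

test_that("rate decomposition sums exactly to the ODE right-hand side", {
  sim <- ref_sim()
  oc <- sim$conditions
  for (i in c(120, 260, 430)) {
    y <- unlist(sim$trajectory[i, 2:21])
    rb <- rate_breakdown(y, tm_p, tm_cc, oc, sim$kla, sim$k_ab)
    d <- fermentation_rhs(0, y, tm_p, tm_cc, oc, sim$kla, sim$k_ab)[[1]]
    expect_equal(d[["X"]], (rb$mu - tm_p$mu_d) * y[["X"]],
                 tolerance = 1e-12)
    expect_equal(d[["S1"]], -rb$q_glu * y[["X"]], tolerance = 1e-12)
    expect_equal(d[["Act"]], rb$r_act, tolerance = 1e-12)
    expect_equal(d[["Lact"]], rb$r_lact, tolerance = 1e-12)
    expect_equal(d[["H2l"]],
                 -rb$transfer_h2 + rb$r_h2_prod - rb$r_h2_cons,
                 tolerance = 1e-12)
    expect_equal(d[["H2g"]],
                 (oc$v_l / oc$v_g) * rb$transfer_h2 -
                   (rb$q_g / oc$v_g) * y[["H2g"]],
                 tolerance = 1e-12)
    # 2 mol H2 consumed per mol H2S formed, the thiosulfate stoichiometry
    expect_equal(rb$r_h2_cons / rb$r_h2s_prod, 2, tolerance = 1e-12)
    expect_gte(rb$q_g, oc$q_n2)
  }
  # without biomass all biological rates vanish and outflow equals inflow
  y0 <- initial_state(tm_p, tm_cc, oc)
  y0["X"] <- 0
  rb0 <- rate_breakdown(y0, tm_p, tm_cc, oc, sim$kla)
  expect_equal(rb0$r_act + rb0$r_h2_prod + rb0$r_h2s_prod, 0)
  expect_equal(rb0$q_g, oc$q_n2)
})

test_that("dissolved H2 steady state equals production excess over transfer", {
  # at steady state the oversaturation [H2] - [H2]* is P_net / KlaH2
  sim <- ref_sim()
  oc <- sim$conditions
  y <- unlist(sim$trajectory[250, 2:21])
  rb <- rate_breakdown(y, tm_p, tm_cc, oc, sim$kla)
  h2_star <- henry_equilibrium(y[["H2g"]], "h2", tm_cc)
  y["H2l"] <- h2_star + (rb$r_h2_prod - rb$r_h2_cons) / sim$kla[["h2"]]
  rb2 <- rate_breakdown(y, tm_p, tm_cc, oc, sim$kla)
  # production itself shifts with H2l (inhibition), so solve the fixed point
  for (k in 1:50) {
    y["H2l"] <- h2_star + (rb2$r_h2_prod - rb2$r_h2_cons) / sim$kla[["h2"]]
    rb2 <- rate_breakdown(y, tm_p, tm_cc, oc, sim$kla)
  }
  d <- fermentation_rhs(0, y, tm_p, tm_cc, oc, sim$kla)[[1]]
  expect_equal(d[["H2l"]], 0, tolerance = 1e-8)
})

test_that("non-finite states are rejected with a diagnostic", {
  oc <- operating_conditions()
  y0 <- initial_state(tm_p, tm_cc, oc)
  y0["X"] <- Inf
  expect_error(fermentation_rhs(0, y0, tm_p, tm_cc, oc,
                                kla_for_flow(6, tm_cc)),
               "non-finite")
})
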