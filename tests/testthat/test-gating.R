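test_that("transition rates follow the DYK cube edge structure", {
  gp <- gatingParameters()
  r <- gatingRates(gp)

  # zero ligand: no IP3-binding flux out of the empty state
  tr <- transitionRates(c(0, 0, 0), c = 0.05, ip3 = 0, gp)
  expect_equal(tr$rate[tr$site == "ip3"], 0)

  # binding rates are proportional to the concentration at the subunit
  tr <- transitionRates(c(1, 1, 0), c = 120, ip3 = 0.07, gp)
  expect_equal(tr$rate[tr$site == "inh"], r[["a_inh_ip3"]] * 120)
  expect_equal(tr$rate[tr$site == "act"], r[["b_act"]])

  # fully bound state at zero ligand: the three unbinding edges only
  tr <- transitionRates(c(1, 1, 1), c = 0, ip3 = 0, gp)
  expect_equal(sum(tr$rate),
               r[["b_act"]] + r[["b_inh_ip3"]] + r[["b_ip3_inh"]])

  # state dependence of the pairs: the IP3 pair follows h, the
  # inhibition pair follows i
  tr <- transitionRates(c(0, 0, 1), c = 1, ip3 = 1, gp)
  expect_equal(tr$rate[tr$site == "ip3"], r[["a_ip3_inh"]])
  expect_equal(tr$rate[tr$site == "inh"], r[["b_inh_noip3"]])

  # every state has exactly 3 outgoing transitions, each flipping one site
  states <- subunitStates()
  for (s in 1:8) {
    tr <- transitionRates(states[s, ], c = 0.3, ip3 = 0.1, gp)
    expect_identical(nrow(tr), 3L)
    flips <- abs(tr$i - states[s, 1]) + abs(tr$a - states[s, 2]) +
      abs(tr$h - states[s, 3])
    expect_equal(flips, rep(1, 3))
    expect_true(all(tr$rate >= 0))
  }

  expect_error(transitionRates(c(0, 0, 0), c = -1, ip3 = 0.1, gp),
               "negative")
  expect_error(transitionRates(c(0, 0, 0), c = 1, ip3 = -0.1, gp),
               "negative")
  expect_error(transitionRates(c(2, 0, 0), c = 1, ip3 = 0.1, gp),
               "binary")
})

test_that("detailed-balance residual is zero iff the loop closes", {
  expect_lt(detailedBalanceResidual(gatingParameters()), 1e-12)
  expect_equal(detailedBalanceResidual(symmetricRates()), 0)

  # scaling K_inh_ip3 by 1.1 leaves a residual of exactly log(1.1)
  r <- gatingRates(gatingParameters())
  r[["b_inh_ip3"]] <- r[["b_inh_ip3"]] * 1.1
  expect_equal(detailedBalanceResidual(r), log(1.1), tolerance = 1e-12)

  # the class constructor refuses unbalanced sets and names the constants
  expect_error(gatingParameters(b_ip3_noninh = 1), "detailed-balance")
  expect_error(gatingParameters(b_ip3_noninh = 1), "K_inh_noip3")
  # ... and refuses inhibition that does not weaken with IP3
  expect_error(gatingParameters(b_inh_ip3 = 0.001, b_ip3_noninh = NULL),
               "K_inh_ip3")
})

test_that("subunit equilibrium matches the product-form oracle", {
  gp <- gatingParameters()

  # no IP3: the i = 1 half of the cube is empty
  p <- subunitEquilibrium(c = 0.1, ip3 = 0, gp)
  expect_equal(sum(p[subunitStates()[, "i"] == 1]), 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # symmetric rates at half-occupancy: uniform distribution on the cube
  p <- subunitEquilibrium(c = 1, ip3 = 1, symmetricRates())
  expect_equal(unname(p), rep(1 / 8, 8), tolerance = 1e-12)

  # independent detailed-balance (Boltzmann product) oracle
  for (cc in c(0.02, 0.07, 0.5, 5)) {
    for (pp in c(0.01, 0.07, 0.5)) {
      expect_equal(subunitEquilibrium(cc, pp, gp),
                   dbEquilibriumOracle(cc, pp, gatingRates(gp)),
                   tolerance = 1e-10)
    }
  }
})

test_that("equilibrium is generator-invariant and edge-balanced", {
  gp <- gatingParameters()
  for (cc in c(0.05, 0.3, 2)) {
    p <- subunitEquilibrium(cc, 0.07, gp)
    Q <- ip3rpuff:::subunitGenerator(cc, 0.07, gp)
    # stationarity: pi Q = 0
    expect_lt(max(abs(p %*% Q)), 1e-10)
    # pairwise detailed balance on every cube edge
    for (s in 1:8) {
      for (t in 1:8) {
        if (s < t && Q[s, t] > 0) {
          flux_out <- p[s] * Q[s, t]
          flux_in <- p[t] * Q[t, s]
          expect_equal(flux_out, flux_in, tolerance = 1e-8,
                       ignore_attr = TRUE)
        }
      }
    }
  }
})

test_that("activating-site occupancy is c / (c + K_act) at any IP3", {
  gp <- gatingParameters()
  K_act <- dissociationConstants(gp)[["K_act"]]
  for (pp in c(0, 0.05, 1)) {
    for (cc in c(0.01, 0.25, 3)) {
      expect_equal(siteOccupancy("act", cc, pp, gp), cc / (cc + K_act),
                   tolerance = 1e-10)
    }
  }
})

test_that("half-occupancy concentrations recover the dissociation constants", {
  gp <- gatingParameters()
  K <- dissociationConstants(gp)
  expect_equal(halfOccupancyCa("act", ip3 = 0.07, gp), K[["K_act"]],
               tolerance = 1e-8)
  expect_equal(halfOccupancyCa("act", ip3 = 1, gp), K[["K_act"]],
               tolerance = 1e-8)
  # with no IP3 the subunit never binds IP3, so inhibition half-occupancy
  # sits at K_inh_noip3
  expect_equal(halfOccupancyCa("inh", ip3 = 0, gp), K[["K_inh_noip3"]],
               tolerance = 1e-8)
})

test_that("open probability is the 3-of-4 binomial of the 110 substate", {
  gp <- gatingParameters()
  expect_equal(channelOpenProbability(c = 0.5, ip3 = 0, gp), 0)
  for (cc in c(0.1, 0.3)) {
    p <- subunitEquilibrium(cc, 0.2, gp)[["110"]]
    expect_equal(channelOpenProbability(cc, 0.2, gp),
                 p^4 + 4 * p^3 * (1 - p))
  }
  # monotone in the per-subunit probability
  p_grid <- seq(0, 1, by = 0.01)
  f <- p_grid^4 + 4 * p_grid^3 * (1 - p_grid)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("dose-response is bell-shaped and its peak shifts right with IP3", {
  gp <- gatingParameters()
  c_grid <- 10^seq(-3, 3, length.out = 200)
  ip3_levels <- c(0.02, 0.1, 0.5, 2)
  peaks <- numeric(length(ip3_levels))
  for (j in seq_along(ip3_levels)) {
    tab <- openProbabilityCurve(c_grid, ip3 = ip3_levels[j], gp)
    po <- tab$p_open
    # unimodal: the finite-difference sign changes exactly once
    signs <- sign(diff(po))
    signs <- signs[signs != 0]
    expect_identical(sum(diff(signs) != 0), 1L)
    peaks[j] <- tab$c_uM[which.max(po)]
  }
  expect_true(all(diff(peaks) > 0))
  # higher IP3 raises the curve
  lo <- openProbabilityCurve(c_grid, ip3 = 0.02, gp)$p_open
  hi <- openProbabilityCurve(c_grid, ip3 = 0.5, gp)$p_open
  expect_true(all(hi >= lo))
})
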