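test_that("identical configurations give bit-identical traces", {
  cfg <- quickConfig(duration = 5, burn_in = 1, seed = 11L)
  t1 <- simulateCluster(cfg)
  t2 <- simulateCluster(cfg)
  expect_identical(traceFrame(t1), traceFrame(t2))

  # different seed, different trajectory (compare the subunit counters,
  # which move even when no channel happens to open in the window)
  t3 <- simulateCluster(quickConfig(duration = 30, burn_in = 0, seed = 12L))
  t4 <- simulateCluster(quickConfig(duration = 30, burn_in = 0, seed = 13L))
  expect_false(identical(traceFrame(t3), traceFrame(t4)))

  # recording grid is exactly duration / record_dt + 1 samples from 0
  expect_identical(length(traceColumn(t1, "time")),
                   as.integer(cfg@duration / cfg@record_dt) + 1L)
  expect_equal(traceColumn(t1, "time")[1], 0)
})

test_that("without IP3 the open state is unreachable", {
  cfg <- quickConfig(duration = 20, burn_in = 0, seed = 3L, ip3 = 0)
  tr <- simulateCluster(cfg)
  expect_true(all(traceColumn(tr, "n_open") == 0L))
  expect_true(all(traceColumn(tr, "n_avail") == 0L))
  expect_true(all(traceColumn(tr, "n111") == 0L))
  # the microdomain never leaves rest
  expect_equal(traceColumn(tr, "c"),
               rep(cfg@domain@c0, length(traceColumn(tr, "time"))))
})

test_that("one-step outcome frequencies follow the per-step law", {
  # A subunit prepared in (1,1,0) at fixed concentrations can, in one
  # step, stay put, unbind IP3, unbind the activating Ca2+, or bind the
  # inhibiting Ca2+.  The engine rule is three independent Bernoulli
  # draws with a redraw when two or more fire; the observed outcome
  # frequencies are compared to the closed-form law by chi-square,
  # pooling outcomes whose expected count is below 5.
  gp <- gatingParameters()
  dom <- microdomainParameters(c0 = 0.5, c1 = 0.1, c_high = 1, k = 100)
  cfg <- simulationConfig(n_channels = 1L, ip3 = 0.07, gating = gp,
                          domain = dom, dt = 1e-3, record_dt = 1e-3,
                          duration = 1, burn_in = 0, seed = 1L)
  start <- clusterState(cfg)
  start@subunits[1, ] <- c(6L, 0L, 0L, 0L)  # one subunit at (1,1,0)
  tr <- transitionRates(c(1, 1, 0), c = dom@c0, ip3 = cfg@ip3, gp)
  p <- tr$rate * cfg@dt
  q <- 1 - p
  w <- c(none = prod(q), ip3 = p[1] * q[2] * q[3],
         act = q[1] * p[2] * q[3], inh = q[1] * q[2] * p[3])
  prob <- w / sum(w)

  set.seed(99)
  n_rep <- 20000L
  # outcome codes after one step: stay 6, i-flip 2, a-flip 4, h-flip 7
  out <- integer(4)
  for (r in seq_len(n_rep)) {
    nxt <- stepCluster(start, cfg)
    j <- match(nxt@subunits[1, 1], c(6L, 2L, 4L, 7L))
    out[j] <- out[j] + 1L
  }
  expected <- n_rep * prob
  pool <- expected < 5
  if (any(pool)) {
    observed <- c(out[!pool], sum(out[pool]))
    expected <- c(expected[!pool], sum(expected[pool]))
  } else {
    observed <- out
  }
  chi <- sum((observed - expected)^2 / expected)
  p_val <- pchisq(chi, df = length(observed) - 1L, lower.tail = FALSE)
  expect_gt(p_val, 0.001)
})

test_that("compiled engine reproduces equilibrium occupancies when clamped", {
  # One channel with negligible coupling (c1 tiny) and a pore level barely
  # above rest: every subunit effectively feels a constant c = c0, so the
  # long-run occupancies must match the analytic 8-state equilibrium.
  # The recorded counters give three marginals to check.  Tolerances are
  # set by the autocorrelation of the slow IP3 site (minutes of simulated
  # time per effective sample), not by the sampling rate.
  gp <- gatingParameters()
  c0 <- 0.3
  ip3 <- 0.02
  dom <- microdomainParameters(c0 = c0, c1 = 1e-6, c_high = c0 * 1.01,
                               k = 100)
  cfg <- simulationConfig(n_channels = 1L, ip3 = ip3, gating = gp,
                          domain = dom, dt = 1e-4, record_dt = 0.1,
                          duration = 20000, burn_in = 100, seed = 5L)
  tr <- simulateCluster(cfg)
  pi <- subunitEquilibrium(c0, ip3, gp)

  expect_equal(mean(traceColumn(tr, "n111")) / 4, pi[["111"]],
               tolerance = 0.3)
  expect_equal(mean(traceColumn(tr, "n011")) / 4, pi[["011"]],
               tolerance = 0.3)

  # availability marginal: P(at least 3 of 4 subunits have IP3 bound)
  p_i <- sum(pi[subunitStates()[, "i"] == 1])
  p_avail <- p_i^4 + 4 * p_i^3 * (1 - p_i)
  expect_equal(mean(traceColumn(tr, "n_avail")), p_avail,
               tolerance = 0.1)
})

test_that("single-site dwell times are exponential with the configured rate", {
  gp <- gatingParameters()
  b_inh <- gatingRates(gp)[["b_inh_ip3"]]
  d <- simulateDwellTimes(1e4, "inh", state = c(1, 1, 1), c = 0,
                          params = gp, dt = 1e-5, seed = 7L)
  # Kolmogorov-Smirnov against the exponential law
  ks <- suppressWarnings(stats::ks.test(d, "pexp", rate = b_inh))
  expect_gt(ks$p.value, 0.001)
  # reciprocal mean recovers the de-inhibition rate
  expect_equal(1 / mean(d), b_inh, tolerance = 0.05)

  # a frozen site with zero rate has no dwell time
  expect_error(simulateDwellTimes(10, "act", state = c(0, 0, 0), c = 0),
               "zero rate")
})

test_that("halving dt leaves the long-run mean open count unchanged", {
  run_mean <- function(dt, seeds) {
    vapply(seeds, function(s) {
      cfg <- simulationConfig(duration = 60, burn_in = 5, seed = s, dt = dt)
      mean(traceColumn(simulateCluster(cfg), "n_open"))
    }, numeric(1))
  }
  m1 <- run_mean(1e-5, 1:4)
  m2 <- run_mean(5e-6, 5:8)
  se <- sqrt(stats::var(m1) / 4 + stats::var(m2) / 4)
  expect_lt(abs(mean(m1) - mean(m2)), 4 * se + 0.01)
})

test_that("R reference stepper maintains cluster-state invariants", {
  gp <- gatingParameters()
  dom <- microdomainParameters(c0 = 0.3, c1 = 1, c_high = 25, k = 100)
  cfg <- simulationConfig(n_channels = 2L, ip3 = 0.3, gating = gp,
                          domain = dom, dt = 2e-5, record_dt = 1e-3,
                          duration = 1, burn_in = 0, seed = 2L)
  set.seed(2)
  state <- clusterState(cfg)
  # start with one channel open so both concentration scales are in play
  state@subunits[1, ] <- c(6L, 6L, 6L, 0L)
  state@n_open <- 1L
  state@c <- stationaryConcentration(1, dom)
  expect_no_error({
    for (i in 1:400) {
      state <- stepCluster(state, cfg)
      validObject(state)               # includes the 3-of-4 consistency
      stopifnot(state@c >= dom@c0 - 1e-12,
                state@c <= stationaryConcentration(2, dom) + 1e-9)
    }
  })
  expect_equal(state@t, 400 * cfg@dt)
})

test_that("configuration validity enforces the time-step and scale rules", {
  expect_error(simulationConfig(dt = 1e-3), "dt too large")
  expect_error(simulationConfig(record_dt = 5e-6), "record_dt")
  expect_error(simulationConfig(record_dt = 1.5e-5), "integer multiple")
  expect_error(simulationConfig(duration = 0), "duration")
  expect_error(simulationConfig(n_channels = 50L,
                                domain = microdomainParameters(c1 = 3)),
               "c_high")
})

test_that("sweep with one cell and one replicate equals a direct run", {
  cfg <- quickConfig(duration = 30, burn_in = 2, seed = 17L)
  tab <- sweepSimulations(cfg, replicates = 1L)
  st <- eventStatistics(detectEvents(simulateCluster(cfg)),
                        trace_duration = cfg@duration)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$n_events, nEvents(st))
  expect_equal(tab$mean_lifetime, meanLifetime(st))
  expect_equal(tab$mean_ipi, meanIpi(st))
  expect_equal(tab$median_amplitude, medianAmplitude(st))
})
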