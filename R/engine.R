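#' Construct a cluster simulation configuration
#'
#' Defaults describe the reference setup: 20 channels, IP3 = 0.07 uM
#' (within the 50--100 nM range optimal for oscillations), the shipped
#' gating and microdomain parameter sets, stochastic step dt = 1e-5 s
#' (largest rate a_act * c_high = 9600/s, so the per-step transition
#' probability stays below 0.1), sampling every 1 ms (100 samples across
#' a 100 ms puff), 400 s recorded after a 10 s discarded burn-in.
#'
#' @param n_channels number of channels in the cluster.
#' @param ip3 IP3 concentration, uM.
#' @param gating a [GatingParameters-class] object.
#' @param domain a [MicrodomainParameters-class] object.
#' @param dt stochastic time step, s.
#' @param record_dt sampling interval, s (integer multiple of \code{dt}).
#' @param duration recorded duration, s.
#' @param burn_in discarded initial transient, s.
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(duration = 10, seed = 7)
#' @export
simulationConfig <- function(n_channels = 20L, ip3 = 0.07,
                             gating = gatingParameters(),
                             domain = microdomainParameters(),
                             dt = 1e-5, record_dt = 1e-3,
                             duration = 400, burn_in = 10, seed = 1L) {
  new("SimulationConfig", n_channels = as.integer(n_channels), ip3 = ip3,
      gating = gating, domain = domain, dt = dt, record_dt = record_dt,
      duration = duration, burn_in = burn_in, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d channels, ip3 = %g uM, k = %g /s, seed = %d\n",
              object@n_channels, object@ip3, object@domain@k, object@seed))
  cat(sprintf("  dt = %g s, record_dt = %g s, duration = %g s (+%g s burn-in)\n",
              object@dt, object@record_dt, object@duration, object@burn_in))
})

#' Initial cluster state
#'
#' All subunits fully unbound (state 000) and the microdomain at rest.
#'
#' @param config a [SimulationConfig-class] object.
#' @return a [ClusterState-class] object at t = 0.
#' @export
clusterState <- function(config) {
  new("ClusterState",
      subunits = matrix(0L, config@n_channels, 4L),
      c = config@domain@c0, n_open = 0L, t = 0)
}

setMethod("show", "ClusterState", function(object) {
  cnt <- stateCounters(object)
  cat(sprintf("ClusterState: t = %.6g s, %d/%d channels open, c = %.4g uM\n",
              object@t, object@n_open, nrow(object@subunits), object@c))
  cat(sprintf("  N111 = %d, N011 = %d, N_avail = %d\n",
              cnt[["n111"]], cnt[["n011"]], cnt[["n_avail"]]))
})

#' Advance the cluster by one stochastic step (reference implementation)
#'
#' Pure-R reference for one fixed time step of the kinetic Monte Carlo
#' scheme, with the identical semantics to the compiled engine behind
#' [simulateCluster()]: every subunit's three candidate transitions fire
#' independently with probability rate * dt (redrawing the subunit's step
#' in the rare case that two fire at once), all subunits see start-of-step
#' concentrations and channel statuses (synchronous update), then channel
#' open states are recomputed by the 3-of-4 rule, the microdomain jump
#' rule is applied if the open count changed, and the concentration is
#' relaxed over dt.  Uses R's RNG; intended for testing and illustration,
#' not production runs.
#'
#' @param state a [ClusterState-class] object.
#' @param config a [SimulationConfig-class] object.
#' @return the updated [ClusterState-class].
#' @seealso [simulateCluster()] for full runs.
#' @export
stepCluster <- function(state, config) {
  gp <- config@gating
  dom <- config@domain
  dt <- config@dt
  states <- subunitStates()
  open <- rowSums(state@subunits == .OPEN_CODE) >= 3L
  d <- domainState(state@c, state@n_open)
  sub <- state@subunits
  for (ch in seq_len(config@n_channels)) {
    conc <- subunitConcentration(open[[ch]], d, dom)
    for (u in 1:4) {
      tr <- transitionRates(states[sub[ch, u] + 1L, ], conc, config@ip3, gp)
      p <- tr$rate * dt
      if (any(p > 1))
        stop("configuration error: rate * dt > 1, reduce dt")
      repeat {
        fire <- runif(3L) < p
        if (sum(fire) <= 1L) break
      }
      if (any(fire)) {
        w <- which(fire)
        sub[ch, u] <- .stateCode(tr$i[w], tr$a[w], tr$h[w])
      }
    }
  }
  n_open <- sum(rowSums(sub == .OPEN_CODE) >= 3L)
  d <- onOpenCountChange(d, n_open, dom)
  d <- advanceConcentration(d, dt, dom)
  new("ClusterState", subunits = sub, c = d$c,
      n_open = as.integer(n_open), t = state@t + dt)
}

#' Simulate a cluster of IP3R channels
#'
#' Runs the fixed-time-step kinetic Monte Carlo simulation of the channel
#' cluster coupled to the coarse-grained microdomain and returns the
#' sampled [Trace-class].  The run starts from the all-unbound state with
#' the microdomain at rest; \code{burn_in} seconds are simulated and
#' discarded before recording starts at trace time 0.  The compiled engine
#' (default) uses a xoshiro256++ generator seeded from \code{config@seed},
#' so identical configurations give bit-identical traces; it also skips
#' ahead exactly (geometric waiting times) through quiescent stretches in
#' which every channel is closed and the microdomain has relaxed to rest,
#' which is what makes 400 s runs take seconds.  \code{method = "R"} runs
#' the slow pure-R reference stepper ([stepCluster()]) instead, for tiny
#' cross-validation runs only.
#'
#' @param config a [SimulationConfig-class] object.
#' @param method "cpp" (compiled engine) or "R" (reference stepper).
#' @return a [Trace-class] object.
#' @examples
#' cfg <- simulationConfig(duration = 5, burn_in = 1, seed = 42)
#' tr <- simulateCluster(cfg)
#' max(traceColumn(tr, "n_open"))
#' @export
simulateCluster <- function(config, method = c("cpp", "R")) {
  method <- match.arg(method)
  validObject(config)
  if (method == "cpp") {
    res <- .sim_cluster_cpp(
      gating = unname(config@gating@rates),
      c0 = config@domain@c0, c1 = config@domain@c1,
      c_high = config@domain@c_high, k = config@domain@k,
      ip3 = config@ip3, n_channels = config@n_channels,
      dt = config@dt, record_dt = config@record_dt,
      duration = config@duration, burn_in = config@burn_in,
      seed = config@seed)
  } else {
    res <- .simulateClusterR(config)
  }
  new("Trace", time = res$time, n_open = as.integer(res$n_open),
      c = res$c, n111 = as.integer(res$n111), n011 = as.integer(res$n011),
      n_avail = as.integer(res$n_avail), config = config)
}

## Pure-R driver mirroring the compiled engine's recording scheme.
.simulateClusterR <- function(config) {
  set.seed(config@seed)
  dt <- config@dt
  rec_every <- as.integer(round(config@record_dt / dt))
  burn_steps <- as.integer(round(config@burn_in / dt))
  n_steps <- burn_steps + as.integer(round(config@duration / dt))
  n_rec <- (n_steps - burn_steps) %/% rec_every + 1L
  state <- clusterState(config)
  out <- list(time = numeric(n_rec), n_open = integer(n_rec),
              c = numeric(n_rec), n111 = integer(n_rec),
              n011 = integer(n_rec), n_avail = integer(n_rec))
  rec <- function(idx, step) {
    cnt <- stateCounters(state)
    out$time[idx] <<- (step - burn_steps) * dt
    out$n_open[idx] <<- state@n_open
    out$c[idx] <<- state@c
    out$n111[idx] <<- cnt[["n111"]]
    out$n011[idx] <<- cnt[["n011"]]
    out$n_avail[idx] <<- cnt[["n_avail"]]
  }
  if (burn_steps == 0L) rec(1L, 0L)
  for (step in seq_len(n_steps)) {
    state <- stepCluster(state, config)
    if (step >= burn_steps && (step - burn_steps) %% rec_every == 0L)
      rec((step - burn_steps) %/% rec_every + 1L, step)
  }
  out
}

#' Extract a sampled column from a trace
#'
#' @param trace a [Trace-class] object.
#' @param column one of "time", "n_open", "c", "n111", "n011", "n_avail".
#' @return the sampled vector.
#' @export
traceColumn <- function(trace,
                        column = c("time", "n_open", "c", "n111", "n011",
                                   "n_avail")) {
  stopifnot(is(trace, "Trace"))
  slot(trace, match.arg(column))
}

#' @describeIn traceColumn all sampled columns as a data.frame with the
#'   canonical column names \code{time_s}, \code{n_open}, \code{c_uM},
#'   \code{n111}, \code{n011}, \code{n_avail}.
#' @export
traceFrame <- function(trace) {
  stopifnot(is(trace, "Trace"))
  data.frame(time_s = trace@time, n_open = trace@n_open, c_uM = trace@c,
             n111 = trace@n111, n011 = trace@n011, n_avail = trace@n_avail)
}

setMethod("show", "Trace", function(object) {
  n <- length(object@time)
  cat(sprintf("Trace: %d samples over %.6g s (record_dt = %g s)\n", n,
              if (n) object@time[n] else 0, object@config@record_dt))
  cat(sprintf("  n_open: max %d, mean %.3g; c: max %.4g uM; seed %d\n",
              if (n) max(object@n_open) else NA_integer_,
              if (n) mean(object@n_open) else NA_real_,
              if (n) max(object@c) else NA_real_, object@config@seed))
})

#' Single-site dwell times under the engine's per-step law
#'
#' Simulates waiting times of one transition of a single subunit with the
#' other two sites frozen, under the engine's fixed-step Bernoulli law
#' (the waiting time is geometric in steps of dt, with mean exactly
#' 1/rate).  Used to recover rate constants from dwell-time statistics,
#' e.g. the de-inhibition rate b_inh_ip3 from a subunit initialized in
#' (1,1,1) at c = 0, where no rebinding can occur.
#'
#' @param n number of dwell times to draw.
#' @param site which site's transition to watch: "inh", "act" or "ip3".
#' @param state binary triple \code{c(i, a, h)} the subunit is held in.
#' @param c Ca2+ concentration, uM.
#' @param ip3 IP3 concentration, uM.
#' @param params a [GatingParameters-class] object.
#' @param dt stochastic time step, s.
#' @param seed optional integer seed (uses R's RNG).
#' @return numeric vector of n dwell times, s.
#' @examples
#' d <- simulateDwellTimes(1e4, "inh", state = c(1, 1, 1), c = 0, seed = 1)
#' 1 / mean(d)  # recovers b_inh_ip3 = 2 /s
#' @export
simulateDwellTimes <- function(n, site = c("inh", "act", "ip3"),
                               state = c(1, 1, 1), c = 0, ip3 = 0.07,
                               params = gatingParameters(), dt = 1e-5,
                               seed = NULL) {
  site <- match.arg(site)
  if (!is.null(seed)) set.seed(seed)
  tr <- transitionRates(state, c, ip3, params)
  rate <- tr$rate[match(site, tr$site)]
  if (rate <= 0)
    stop("the watched transition has zero rate; dwell time is undefined")
  p <- rate * dt
  if (p > 1) stop("configuration error: rate * dt > 1, reduce dt")
  (rgeom(n, p) + 1) * dt
}

#' Sweep simulations over collapse rate and IP3
#'
#' Runs independent replicate simulations for every (k, ip3) cell of a
#' grid, detects release events with the gap-closure rule, pools events
#' across replicates, and tabulates the event statistics.  Replicate r of
#' cell g uses seed \code{config@seed + (r - 1) + 1000 * (g - 1)}, so one
#' cell with one replicate reproduces a direct [simulateCluster()] run
#' with the configured seed.
#'
#' @param config base [SimulationConfig-class]; per-cell values of k and
#'   ip3 override the ones it carries.
#' @param k collapse rates to sweep, 1/s (default: the config's).
#' @param ip3 IP3 concentrations to sweep, uM (default: the config's).
#' @param replicates independent seeds per cell.
#' @param gap_window event gap-closure window, s.
#' @return data.frame with one row per (k, ip3) cell: event count, mean
#'   and standard error of lifetime, interpuff interval and dormancy, and
#'   the median lifetime and median peak amplitude.
#' @export
sweepSimulations <- function(config = simulationConfig(), k = NULL,
                             ip3 = NULL, replicates = 4L,
                             gap_window = 0.5) {
  if (length(k) == 0L) k <- config@domain@k
  if (length(ip3) == 0L) ip3 <- config@ip3
  stopifnot(replicates >= 1L)
  grid <- expand.grid(k = k, ip3 = ip3, KEEP.OUT.ATTRS = FALSE)
  se <- function(x) if (length(x) >= 2L) sd(x) / sqrt(length(x)) else NA_real_
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    dom <- config@domain
    dom@k <- grid$k[g]
    lifetimes <- amplitudes <- ipis <- dorms <- numeric(0)
    for (r in seq_len(replicates)) {
      cfg <- simulationConfig(
        n_channels = config@n_channels, ip3 = grid$ip3[g],
        gating = config@gating, domain = dom, dt = config@dt,
        record_dt = config@record_dt, duration = config@duration,
        burn_in = config@burn_in,
        seed = config@seed + (r - 1L) + 1000L * (g - 1L))
      st <- eventStatistics(detectEvents(simulateCluster(cfg), gap_window),
                            trace_duration = cfg@duration)
      lifetimes <- c(lifetimes, st@lifetimes)
      amplitudes <- c(amplitudes, st@amplitudes)
      ipis <- c(ipis, st@ipis)
      dorms <- c(dorms, st@dormancies)
    }
    data.frame(
      k = grid$k[g], ip3 = grid$ip3[g], n_events = length(lifetimes),
      mean_lifetime = if (length(lifetimes)) mean(lifetimes) else NA_real_,
      se_lifetime = se(lifetimes),
      mean_ipi = if (length(ipis)) mean(ipis) else NA_real_,
      se_ipi = se(ipis),
      mean_dormancy = if (length(dorms)) mean(dorms) else NA_real_,
      se_dormancy = se(dorms),
      median_lifetime = if (length(lifetimes)) median(lifetimes) else NA_real_,
      median_amplitude = if (length(amplitudes)) median(amplitudes) else NA_real_
    )
  })
  do.call(rbind, rows)
}
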