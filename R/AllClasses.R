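#' @useDynLib ip3rpuff, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slotNames slot
#' @importFrom stats rgeom runif median sd setNames
#' @importFrom utils modifyList write.table read.table
NULL

## Order in which the ten rate constants are stored and serialized.
## Pairs are (on-rate a [1/(uM s)], off-rate b [1/s]) for:
## activating Ca site; inhibiting Ca site with/without IP3 bound;
## IP3 site with the inhibiting site empty/occupied.
.GATING_FIELDS <- c(
  "a_act", "b_act",
  "a_inh_ip3", "b_inh_ip3",
  "a_inh_noip3", "b_inh_noip3",
  "a_ip3_noninh", "b_ip3_noninh",
  "a_ip3_inh", "b_ip3_inh"
)

.DOMAIN_FIELDS <- c("c0", "c1", "c_high", "k")

#' DeYoung-Keizer subunit gating parameters
#'
#' Holds the five binding/unbinding rate pairs of the DeYoung-Keizer (DYK)
#' subunit cube: the activating Ca2+ site, the inhibiting Ca2+ site (two
#' pairs, depending on whether IP3 is bound), and the IP3 site (two pairs,
#' depending on whether the inhibiting site is occupied).  On-rates are in
#' 1/(uM s), off-rates in 1/s.  Validity enforces strict positivity, the
#' thermodynamic loop (detailed-balance) constraint
#' \code{K_ip3_noninh * K_inh_ip3 == K_ip3_inh * K_inh_noip3}, and that
#' inhibition is weaker when IP3 is bound (\code{K_inh_ip3 > K_inh_noip3}).
#'
#' @slot rates named numeric vector of the ten rate constants.
#' @seealso [gatingParameters()], [dissociationConstants()],
#'   [detailedBalanceResidual()]
#' @export
setClass("GatingParameters", representation(rates = "numeric"))

setValidity("GatingParameters", function(object) {
  r <- object@rates
  if (!identical(names(r), .GATING_FIELDS))
    return(sprintf("rates must be named exactly: %s",
                   paste(.GATING_FIELDS, collapse = ", ")))
  if (any(!is.finite(r)) || any(r <= 0))
    return("all rate constants must be finite and strictly positive")
  K <- .dissociationConstants(r)
  if (K[["K_inh_ip3"]] <= K[["K_inh_noip3"]])
    return("K_inh_ip3 must exceed K_inh_noip3 (inhibition must weaken when IP3 is bound)")
  res <- abs(log((K[["K_ip3_noninh"]] * K[["K_inh_ip3"]]) /
                 (K[["K_ip3_inh"]] * K[["K_inh_noip3"]])))
  if (res > 1e-6)
    return(sprintf(paste0(
      "detailed-balance violation (|log residual| = %.3g > 1e-6): ",
      "K_ip3_noninh * K_inh_ip3 must equal K_ip3_inh * K_inh_noip3 ",
      "(K_ip3_noninh = %.6g, K_inh_ip3 = %.6g, K_ip3_inh = %.6g, K_inh_noip3 = %.6g)"),
      res, K[["K_ip3_noninh"]], K[["K_inh_ip3"]],
      K[["K_ip3_inh"]], K[["K_inh_noip3"]]))
  TRUE
})

#' Coarse-grained calcium microdomain parameters
#'
#' The two-scale microdomain description: closed channels in the cluster feel
#' a coupling concentration \code{c0 + c1 * n_open} (linear in the number of
#' open channels), an open channel feels the fixed pore concentration
#' \code{c_high}, and after a decrease in the open-channel count the coupling
#' concentration relaxes exponentially toward its new plateau at collapse
#' rate \code{k}.  Large \code{k} stands in for a slow mobile buffer (EGTA)
#' accelerating removal of residual Ca2+.
#'
#' @slot c0 resting concentration, uM.
#' @slot c1 coupling concentration per open channel, uM.
#' @slot c_high pore concentration at an open channel, uM.
#' @slot k collapse (equilibration) rate, 1/s.
#' @seealso [microdomainParameters()], [stationaryConcentration()],
#'   [advanceConcentration()]
#' @export
setClass("MicrodomainParameters",
         representation(c0 = "numeric", c1 = "numeric",
                        c_high = "numeric", k = "numeric"))

setValidity("MicrodomainParameters", function(object) {
  v <- c(c0 = object@c0, c1 = object@c1, c_high = object@c_high, k = object@k)
  if (any(lengths(list(object@c0, object@c1, object@c_high, object@k)) != 1L))
    return("all microdomain parameters must be scalars")
  if (any(!is.finite(v)) || any(v <= 0))
    return("c0, c1, c_high and k must be finite and strictly positive")
  if (object@c_high <= object@c0 + object@c1)
    return("c_high must exceed c0 + c1 (pore/domain scale separation)")
  TRUE
})

#' Cluster simulation configuration
#'
#' Full specification of a stochastic cluster run: channel count, IP3
#' concentration, gating and microdomain parameters, the fixed stochastic
#' time step \code{dt}, the sampling interval \code{record_dt}, the recorded
#' duration, the discarded burn-in, and the RNG seed.
#'
#' @slot n_channels integer number of channels in the cluster.
#' @slot ip3 IP3 concentration, uM.
#' @slot gating a [GatingParameters-class] object.
#' @slot domain a [MicrodomainParameters-class] object.
#' @slot dt stochastic time step, s.
#' @slot record_dt sampling interval of the recorded trace, s (an integer
#'   multiple of \code{dt}).
#' @slot duration recorded duration, s.
#' @slot burn_in discarded initial transient, s.
#' @slot seed integer RNG seed, logged in every output.
#' @seealso [simulationConfig()], [simulateCluster()]
#' @export
setClass("SimulationConfig",
         representation(n_channels = "integer", ip3 = "numeric",
                        gating = "GatingParameters",
                        domain = "MicrodomainParameters",
                        dt = "numeric", record_dt = "numeric",
                        duration = "numeric", burn_in = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@n_channels < 1L) return("n_channels must be >= 1")
  if (!is.finite(object@ip3) || object@ip3 < 0) return("ip3 must be >= 0")
  if (object@dt <= 0) return("dt must be > 0")
  if (object@record_dt < object@dt) return("record_dt must be >= dt")
  m <- object@record_dt / object@dt
  if (abs(m - round(m)) > 1e-8)
    return("record_dt must be an integer multiple of dt")
  if (object@duration <= 0) return("duration must be > 0")
  if (object@burn_in < 0) return("burn_in must be >= 0")
  dom <- object@domain
  if (dom@c_high <= dom@c0 + dom@c1 * object@n_channels)
    return(paste0("c_high must exceed c0 + c1 * n_channels: the pore ",
                  "concentration must dominate the coupling scale"))
  p <- maxTransitionRate(object@gating, dom@c_high, object@ip3) * object@dt
  if (p > 0.1)
    return(sprintf(paste0("dt too large: maximum per-step transition ",
                          "probability %.3g > 0.1; reduce dt"), p))
  TRUE
})

#' Sampled simulation trace
#'
#' Time series recorded by [simulateCluster()]: the number of open channels,
#' the microdomain coupling concentration, and three gating-state counters
#' (subunits in the fully bound state 111, subunits in state 011 that lost
#' IP3 while activated and inhibited, and channels with at least three
#' IP3-bound subunits, i.e. channels still available for opening).
#'
#' @slot time sample times, s (starting at 0 after burn-in).
#' @slot n_open open-channel count per sample.
#' @slot c microdomain coupling concentration per sample, uM.
#' @slot n111,n011 subunit-state counters per sample.
#' @slot n_avail channels with >= 3 IP3-bound subunits per sample.
#' @slot config the [SimulationConfig-class] that produced the trace.
#' @seealso [simulateCluster()], [detectEvents()], [writeTrace()]
#' @export
setClass("Trace",
         representation(time = "numeric", n_open = "integer", c = "numeric",
                        n111 = "integer", n011 = "integer",
                        n_avail = "integer", config = "SimulationConfig"))

setValidity("Trace", function(object) {
  n <- length(object@time)
  if (any(lengths(list(object@n_open, object@c, object@n111, object@n011,
                       object@n_avail)) != n))
    return("all trace columns must have the same length")
  if (n > 1 && any(diff(object@time) <= 0))
    return("sample times must be strictly increasing")
  if (n > 0 && object@time[1] < 0) return("sample times must be >= 0")
  nc <- object@config@n_channels
  if (n > 0) {
    if (any(object@n_open < 0L) || any(object@n_open > nc))
      return("n_open out of range [0, n_channels]")
    if (any(object@n111 < 0L) || any(object@n111 > 4L * nc) ||
        any(object@n011 < 0L) || any(object@n011 > 4L * nc))
      return("subunit counters out of range [0, 4 * n_channels]")
    if (any(object@n_avail < 0L) || any(object@n_avail > nc))
      return("n_avail out of range [0, n_channels]")
  }
  TRUE
})

#' Cluster gating state (reference implementation)
#'
#' Explicit state of the cluster used by the pure-R reference stepper
#' [stepCluster()]: one DYK state code per subunit (0..7, encoding the
#' binary triple (i, a, h) as \code{4 i + 2 a + h}), the microdomain
#' concentration, the open-channel count and the clock.
#'
#' @slot subunits integer matrix, n_channels x 4, of subunit state codes.
#' @slot c microdomain coupling concentration, uM.
#' @slot n_open number of open channels (>= 3 subunits in state 110).
#' @slot t elapsed time, s.
#' @seealso [clusterState()], [stepCluster()], [stateCounters()]
#' @export
setClass("ClusterState",
         representation(subunits = "matrix", c = "numeric",
                        n_open = "integer", t = "numeric"))

setValidity("ClusterState", function(object) {
  s <- object@subunits
  if (!is.numeric(s) || ncol(s) != 4L)
    return("subunits must be a numeric matrix with 4 columns")
  if (any(s != floor(s)) || any(s < 0) || any(s > 7))
    return("subunit codes must be integers in 0..7")
  if (object@c < 0) return("concentration must be >= 0")
  if (object@n_open != sum(rowSums(s == .OPEN_CODE) >= 3L))
    return("n_open inconsistent with the 3-of-4 open rule on subunits")
  TRUE
})

#' Release-event statistics
#'
#' Event-train statistics computed by [eventStatistics()] from the events
#' detected in a trace: per-event lifetimes and peak amplitudes, and the
#' inter-event measures for consecutive event pairs.  The interpuff interval
#' (IPI) is onset-to-onset; dormancy is the complementary end-to-next-onset
#' interval during which no channel is open, so mean IPI >= mean dormancy.
#' With fewer than two events the IPI and dormancy are undefined (NA).
#'
#' @slot lifetimes per-event lifetimes, s.
#' @slot amplitudes per-event peak open-channel counts.
#' @slot ipis onset-to-onset interpuff intervals, s.
#' @slot dormancies end-to-onset quiet intervals, s.
#' @slot trace_duration duration of the analyzed trace, s.
#' @seealso [eventStatistics()], [meanLifetime()], [eventHistogram()]
#' @export
setClass("EventStatistics",
         representation(lifetimes = "numeric", amplitudes = "numeric",
                        ipis = "numeric", dormancies = "numeric",
                        trace_duration = "numeric"))

setValidity("EventStatistics", function(object) {
  n <- length(object@lifetimes)
  if (length(object@amplitudes) != n)
    return("lifetimes and amplitudes must have equal length")
  if (n >= 2 && (length(object@ipis) != n - 1 ||
                 length(object@dormancies) != n - 1))
    return("ipis and dormancies must have one entry per consecutive event pair")
  if (any(object@lifetimes < 0)) return("lifetimes must be >= 0")
  if (n >= 2 && any(object@ipis < object@dormancies))
    return("each IPI must be >= the corresponding dormancy")
  TRUE
})
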