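## DYK subunit states are coded 0..7 as 4*i + 2*a + h, where i is the IP3
## site, a the activating Ca site and h the inhibiting Ca site (1 = bound).
## The open substate (1,1,0) has code 6.
.OPEN_CODE <- 6L

.stateCode <- function(i, a, h) as.integer(4L * i + 2L * a + h)

## Accept either a validated GatingParameters or a bare named rate vector
## (the latter deliberately skips validity, e.g. to quantify how far an
## unbalanced parameter set is from the thermodynamic constraint).
.asRates <- function(params) {
  if (is(params, "GatingParameters")) return(params@rates)
  if (is.numeric(params) && all(.GATING_FIELDS %in% names(params)))
    return(params[.GATING_FIELDS])
  stop("params must be a GatingParameters object or a named vector with ",
       "fields: ", paste(.GATING_FIELDS, collapse = ", "), call. = FALSE)
}

.dissociationConstants <- function(r) {
  c(K_act        = r[["b_act"]] / r[["a_act"]],
    K_inh_ip3    = r[["b_inh_ip3"]] / r[["a_inh_ip3"]],
    K_inh_noip3  = r[["b_inh_noip3"]] / r[["a_inh_noip3"]],
    K_ip3_noninh = r[["b_ip3_noninh"]] / r[["a_ip3_noninh"]],
    K_ip3_inh    = r[["b_ip3_inh"]] / r[["a_ip3_inh"]])
}

#' Construct DYK gating parameters
#'
#' Builds a [GatingParameters-class] object from the ten rate constants.
#' Defaults are the shipped calibration: dissociation constants
#' K_act = 0.25 uM, K_inh_ip3 = 16 uM, K_inh_noip3 = 0.111 uM,
#' K_ip3_inh = 0.7 uM, with K_ip3_noninh forced by the detailed-balance
#' loop (K_ip3_inh * K_inh_noip3 / K_inh_ip3 = 0.00486 uM); a de-inhibition
#' rate b_inh_ip3 = 2/s; an activation on-rate a_act = 30/(uM s) with a
#' shared on-rate across the two inhibition processes (a_inh_* =
#' 2/16 per uM per s); and IP3 on-rates a_ip3_noninh = 3,
#' a_ip3_inh = 0.45 per uM per s.  The IP3 on-rates are deliberately not
#' shared: re-binding of recovered subunits is faster than IP3 exchange on
#' inhibited subunits, which sets the post-burst recovery time without
#' touching the slow, burst-terminating IP3 loss (b_ip3_inh = 0.315/s).
#' IP3 binding/unbinding remains far slower than the Ca2+ processes,
#' which is what lets long bursts terminate by IP3 loss.
#'
#' @param a_act,b_act on/off rates of the activating Ca2+ site
#'   (a_act = 80/(uM s) by default; K_act = b_act / a_act = 0.25 uM).
#' @param a_inh_ip3,b_inh_ip3 on/off rates of the inhibiting Ca2+ site when
#'   IP3 is bound.
#' @param a_inh_noip3,b_inh_noip3 same, when IP3 is not bound.
#' @param a_ip3_noninh,b_ip3_noninh on/off rates of the IP3 site when the
#'   inhibiting site is empty.  \code{b_ip3_noninh = NULL} (default) derives
#'   it from the detailed-balance constraint.
#' @param a_ip3_inh,b_ip3_inh same, when the inhibiting site is occupied.
#' @return a validated [GatingParameters-class] object.
#' @examples
#' gp <- gatingParameters()
#' dissociationConstants(gp)
#' @export
gatingParameters <- function(a_act = 80, b_act = 20,
                             a_inh_ip3 = 2 / 16, b_inh_ip3 = 2,
                             a_inh_noip3 = 2 / 16,
                             b_inh_noip3 = 0.111 * 2 / 16,
                             a_ip3_noninh = 3, b_ip3_noninh = NULL,
                             a_ip3_inh = 0.45, b_ip3_inh = 0.7 * 0.45) {
  if (is.null(b_ip3_noninh)) {
    ## force the thermodynamic loop: K_ip3_noninh = K_ip3_inh*K_inh_noip3/K_inh_ip3
    K_ip3_inh <- b_ip3_inh / a_ip3_inh
    K_inh_noip3 <- b_inh_noip3 / a_inh_noip3
    K_inh_ip3 <- b_inh_ip3 / a_inh_ip3
    b_ip3_noninh <- a_ip3_noninh * K_ip3_inh * K_inh_noip3 / K_inh_ip3
  }
  rates <- c(a_act, b_act, a_inh_ip3, b_inh_ip3, a_inh_noip3, b_inh_noip3,
             a_ip3_noninh, b_ip3_noninh, a_ip3_inh, b_ip3_inh)
  names(rates) <- .GATING_FIELDS
  new("GatingParameters", rates = rates)
}

#' @describeIn gatingParameters extract the named vector of the ten rate
#'   constants.
#' @param object,params a [GatingParameters-class] object.
#' @export
gatingRates <- function(object) object@rates

#' Dissociation constants of a gating parameter set
#'
#' Returns the five dissociation constants K_x = b_x / a_x (uM) derived from
#' the rate pairs: activation, inhibition with/without IP3, and IP3 binding
#' without/with inhibition.
#'
#' @param object a [GatingParameters-class] object.
#' @return named numeric vector \code{K_act}, \code{K_inh_ip3},
#'   \code{K_inh_noip3}, \code{K_ip3_noninh}, \code{K_ip3_inh}.
#' @export
dissociationConstants <- function(object) {
  .dissociationConstants(.asRates(object))
}

setMethod("show", "GatingParameters", function(object) {
  K <- dissociationConstants(object)
  cat("DYK GatingParameters\n")
  cat(sprintf("  on/off rates [1/(uM s), 1/s]:\n"))
  r <- object@rates
  for (nm in c("act", "inh_ip3", "inh_noip3", "ip3_noninh", "ip3_inh"))
    cat(sprintf("    %-11s a = %-9.4g b = %-9.4g\n", nm,
                r[[paste0("a_", nm)]], r[[paste0("b_", nm)]]))
  cat("  dissociation constants [uM]:\n   ",
      paste(sprintf("%s = %.4g", names(K), K), collapse = ", "), "\n")
  cat(sprintf("  detailed-balance residual: %.3g\n",
              detailedBalanceResidual(object)))
})

#' The eight DYK subunit states
#'
#' @return an 8 x 3 integer matrix with columns \code{i}, \code{a}, \code{h}
#'   (IP3, activating Ca2+, inhibiting Ca2+ site occupancy), ordered by the
#'   state code \code{4 i + 2 a + h}.
#' @examples
#' subunitStates()[7, ]  # code 6: the open substate (1,1,0)
#' @export
subunitStates <- function() {
  s <- 0:7
  cbind(i = s %/% 4L, a = (s %/% 2L) %% 2L, h = s %% 2L)
}

.checkState <- function(state) {
  if (length(state) != 3L || any(!state %in% c(0, 1)))
    stop("state must be a binary triple (i, a, h)", call. = FALSE)
  as.integer(state)
}

#' Outgoing transition rates of a DYK subunit state
#'
#' For a subunit in binary state (i, a, h) at Ca2+ concentration \code{c}
#' and IP3 concentration \code{ip3}, returns the three outgoing transitions
#' (one per binding site).  Binding transitions have rate \code{a * c}
#' (Ca2+ sites) or \code{a * ip3} (IP3 site); unbinding transitions have
#' rate \code{b}.  The rate pair of the inhibiting site depends on the
#' current IP3 index i, and the pair of the IP3 site on the current
#' inhibition index h.
#'
#' @param state binary triple \code{c(i, a, h)}.
#' @param c Ca2+ concentration at the subunit, uM (>= 0).
#' @param ip3 IP3 concentration, uM (>= 0).
#' @param params a [GatingParameters-class] object.
#' @return a data.frame with columns \code{site} ("ip3", "act", "inh"),
#'   target state columns \code{i}, \code{a}, \code{h}, and \code{rate}
#'   (1/s).
#' @examples
#' transitionRates(c(1, 1, 0), c = 120, ip3 = 0.07, gatingParameters())
#' @export
transitionRates <- function(state, c, ip3, params) {
  state <- .checkState(state)
  if (!is.finite(c) || c < 0) stop("negative or non-finite Ca2+ concentration")
  if (!is.finite(ip3) || ip3 < 0) stop("negative or non-finite IP3 concentration")
  r <- .asRates(params)
  i <- state[1L]; a <- state[2L]; h <- state[3L]
  ip3_pair <- if (h == 1L) c(r[["a_ip3_inh"]], r[["b_ip3_inh"]])
              else c(r[["a_ip3_noninh"]], r[["b_ip3_noninh"]])
  inh_pair <- if (i == 1L) c(r[["a_inh_ip3"]], r[["b_inh_ip3"]])
              else c(r[["a_inh_noip3"]], r[["b_inh_noip3"]])
  rate <- c(
    ip3 = if (i == 0L) ip3_pair[1L] * ip3 else ip3_pair[2L],
    act = if (a == 0L) r[["a_act"]] * c else r[["b_act"]],
    inh = if (h == 0L) inh_pair[1L] * c else inh_pair[2L]
  )
  data.frame(
    site = c("ip3", "act", "inh"),
    i = c(1L - i, i, i),
    a = c(a, 1L - a, a),
    h = c(h, h, 1L - h),
    rate = unname(rate)
  )
}

#' Detailed-balance residual of a gating parameter set
#'
#' The thermodynamic loop constraint ties the two IP3 and the two
#' inhibition dissociation constants together.  This returns
#' \code{|log((K_ip3_noninh * K_inh_ip3) / (K_ip3_inh * K_inh_noip3))|},
#' which is 0 exactly when the loop constraint holds.
#'
#' @param params a [GatingParameters-class] object.
#' @return non-negative dimensionless residual.
#' @export
detailedBalanceResidual <- function(params) {
  K <- .dissociationConstants(.asRates(params))
  abs(log((K[["K_ip3_noninh"]] * K[["K_inh_ip3"]]) /
          (K[["K_ip3_inh"]] * K[["K_inh_noip3"]])))
}

#' Generator matrix of the 8-state subunit Markov chain
#'
#' @inheritParams transitionRates
#' @return 8 x 8 matrix Q with \code{Q[s, t]} the rate from state code s-1
#'   to t-1 (off-diagonal) and rows summing to zero.
#' @keywords internal
subunitGenerator <- function(c, ip3, params) {
  Q <- matrix(0, 8L, 8L)
  states <- subunitStates()
  for (s in 1:8) {
    tr <- transitionRates(states[s, ], c, ip3, params)
    targets <- .stateCode(tr$i, tr$a, tr$h) + 1L
    Q[s, targets] <- tr$rate
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of a DYK subunit
#'
#' Solves the stationary distribution of the 8-state continuous-time Markov
#' chain at fixed Ca2+ and IP3 concentrations by a direct linear solve of
#' the generator with a normalization row.
#'
#' @inheritParams transitionRates
#' @return numeric probability vector of length 8 (named by state code
#'   \code{i a h}), non-negative and summing to 1.
#' @examples
#' p <- subunitEquilibrium(c = 0.07, ip3 = 0.07, gatingParameters())
#' p[["110"]]  # open-substate probability
#' @export
subunitEquilibrium <- function(c, ip3, params) {
  Q <- subunitGenerator(c, ip3, params)
  A <- t(Q)
  A[8L, ] <- 1          # replace one balance equation by normalization
  b <- c(rep(0, 7L), 1)
  pi <- tryCatch(solve(A, b),
                 error = function(e) stop("degenerate subunit generator: ",
                                          conditionMessage(e), call. = FALSE))
  pi[pi < 0 & pi > -1e-9] <- 0   # clamp roundoff on unreachable states
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-10)
    stop("equilibrium solve failed (negative mass or normalization error)")
  states <- subunitStates()
  names(pi) <- apply(states, 1L, paste, collapse = "")
  pi
}

#' Marginal occupancy of one binding site at equilibrium
#'
#' @param site one of "ip3", "act", "inh".
#' @inheritParams transitionRates
#' @return probability that the site is occupied at equilibrium.
#' @export
siteOccupancy <- function(site = c("ip3", "act", "inh"), c, ip3, params) {
  site <- match.arg(site)
  pi <- subunitEquilibrium(c, ip3, params)
  col <- switch(site, ip3 = "i", act = "a", inh = "h")
  sum(pi[subunitStates()[, col] == 1L])
}

#' Half-occupancy Ca2+ concentration of a binding site
#'
#' Bisects over the Ca2+ concentration for the point where the equilibrium
#' marginal occupancy of the given site is one half.  For the activating
#' site this recovers K_act at any IP3 level; for the inhibiting site at
#' ip3 = 0 it recovers K_inh_noip3.
#'
#' @inheritParams siteOccupancy
#' @param lower,upper bracketing Ca2+ concentrations, uM.
#' @param tol relative bisection tolerance.
#' @return Ca2+ concentration in uM.
#' @export
halfOccupancyCa <- function(site = c("act", "inh"), ip3, params,
                            lower = 1e-6, upper = 1e4, tol = 1e-10) {
  site <- match.arg(site)
  f <- function(c) siteOccupancy(site, c, ip3, params) - 0.5
  if (f(lower) > 0 || f(upper) < 0)
    stop("half-occupancy not bracketed in [lower, upper]")
  while (upper / lower - 1 > tol) {
    mid <- sqrt(lower * upper)
    if (f(mid) < 0) lower <- mid else upper <- mid
  }
  sqrt(lower * upper)
}

#' Equilibrium open probability of an IP3R channel
#'
#' A channel opens when at least three of its four independent subunits are
#' in the open substate (1,1,0).  With p the equilibrium probability of that
#' substate, the open probability is \code{p^4 + 4 p^3 (1 - p)}.
#'
#' @inheritParams transitionRates
#' @return probability in [0, 1].
#' @examples
#' channelOpenProbability(c = 0.3, ip3 = 0.5, gatingParameters())
#' @export
channelOpenProbability <- function(c, ip3, params) {
  p <- subunitEquilibrium(c, ip3, params)[["110"]]
  p^4 + 4 * p^3 * (1 - p)
}

#' Open-probability dose-response table
#'
#' Tabulates the equilibrium channel open probability over a grid of Ca2+
#' and IP3 concentrations, as used for bell-shaped dose-response curves.
#' The default Ca2+ grid is logarithmic from 1e-3 to 1e3 uM (200 points),
#' spanning the decades over which the curve peaks and the peak shifts
#' rightward with increasing IP3.
#'
#' @param c_grid Ca2+ concentrations, uM.
#' @param ip3 one or more IP3 concentrations, uM.
#' @param params a [GatingParameters-class] object.
#' @return data.frame with columns \code{c_uM}, \code{ip3_uM},
#'   \code{p_open}.
#' @export
openProbabilityCurve <- function(c_grid = 10^seq(-3, 3, length.out = 200),
                                 ip3 = 0.07, params = gatingParameters()) {
  grid <- expand.grid(c_uM = c_grid, ip3_uM = ip3,
                      KEEP.OUT.ATTRS = FALSE)
  grid$p_open <- mapply(function(cc, pp) channelOpenProbability(cc, pp, params),
                        grid$c_uM, grid$ip3_uM)
  grid
}

#' Largest transition rate of a parameter set
#'
#' Upper bound on any single-subunit transition rate when Ca2+ can reach
#' \code{c_max} (the pore concentration) -- used to validate the stochastic
#' time step.
#'
#' @param params a [GatingParameters-class] object.
#' @param c_max largest Ca2+ concentration any subunit can feel, uM.
#' @param ip3 IP3 concentration, uM.
#' @return rate in 1/s.
#' @keywords internal
maxTransitionRate <- function(params, c_max, ip3) {
  r <- params@rates
  max(r[["a_act"]] * c_max, r[["a_inh_ip3"]] * c_max,
      r[["a_inh_noip3"]] * c_max,
      r[["a_ip3_noninh"]] * ip3, r[["a_ip3_inh"]] * ip3,
      r[["b_act"]], r[["b_inh_ip3"]], r[["b_inh_noip3"]],
      r[["b_ip3_noninh"]], r[["b_ip3_inh"]])
}
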