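#' Construct microdomain parameters
#'
#' Defaults: rest level c0 = 0.02 uM, coupling c1 = 2.2 uM per open
#' channel (several open channels drive the closed-channel concentration
#' to the ~10 uM scale), pore concentration c_high = 120 uM, collapse
#' rate k = 100/s (the buffered, puff regime; k = 10/s is the unbuffered,
#' wave regime).
#'
#' @param c0 rest concentration, uM.
#' @param c1 coupling concentration per open channel, uM.
#' @param c_high pore concentration felt by an open channel, uM.
#' @param k collapse rate of the residual microdomain, 1/s.
#' @return a validated [MicrodomainParameters-class] object.
#' @export
microdomainParameters <- function(c0 = 0.02, c1 = 2.2, c_high = 120,
                                  k = 100) {
  new("MicrodomainParameters", c0 = c0, c1 = c1, c_high = c_high, k = k)
}

setMethod("show", "MicrodomainParameters", function(object) {
  cat("MicrodomainParameters\n")
  cat(sprintf("  c0 = %g uM, c1 = %g uM/channel, c_high = %g uM, k = %g /s\n",
              object@c0, object@c1, object@c_high, object@k))
})

#' Microdomain state
#'
#' The coarse-grained domain state felt by closed channels: the current
#' coupling concentration and the open-channel count driving it.
#'
#' @param c concentration, uM.
#' @param n_open number of open channels.
#' @return a list with elements \code{c} and \code{n_open}.
#' @export
domainState <- function(c, n_open) {
  if (!is.finite(c) || c < 0) stop("concentration must be >= 0")
  n_open <- .checkCount(n_open)
  list(c = c, n_open = n_open)
}

.checkCount <- function(n_open) {
  if (length(n_open) != 1L || !is.finite(n_open) || n_open < 0 ||
      n_open != floor(n_open))
    stop("n_open must be a non-negative integer", call. = FALSE)
  as.integer(n_open)
}

#' Quasi-stationary coupling concentration
#'
#' The concentration felt by closed channels when \code{n_open} channels
#' are open, in the quasi-stationary limit: \code{c0 + c1 * n_open}
#' (linear in the open-channel count, reducing to the rest level when all
#' channels are shut).
#'
#' @param n_open number of open channels (non-negative integer, vectorized).
#' @param params a [MicrodomainParameters-class] object.
#' @return concentration in uM.
#' @examples
#' stationaryConcentration(5, microdomainParameters(c0 = 0.02, c1 = 3))
#' @export
stationaryConcentration <- function(n_open, params) {
  stopifnot(is(params, "MicrodomainParameters"))
  if (any(!is.finite(n_open)) || any(n_open < 0) ||
      any(n_open != floor(n_open)))
    stop("n_open must be non-negative integer(s)")
  params@c0 + params@c1 * n_open
}

#' Relax the microdomain concentration over a time step
#'
#' Exact closed-form update of the exponential collapse law
#' dc/dt = k (c_stat - c): \code{c' = c_stat + (c - c_stat) exp(-k dt)}
#' with \code{c_stat = stationaryConcentration(n_open)}.  Being the exact
#' solution, composing two half steps equals one full step to machine
#' precision, and the residual-Ca2+ half-life after full closure is
#' log(2)/k.
#'
#' @param state a domain state from [domainState()].
#' @param dt time step, s (> 0).
#' @param params a [MicrodomainParameters-class] object.
#' @return the updated domain state.
#' @export
advanceConcentration <- function(state, dt, params) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  c_stat <- stationaryConcentration(state$n_open, params)
  state$c <- c_stat + (state$c - c_stat) * exp(-params@k * dt)
  state
}

#' Update the domain on a change of open-channel count
#'
#' On an increase of the open-channel count the microdomain equilibrates
#' instantaneously upward: c jumps to
#' \code{max(c, stationaryConcentration(new_n_open))} (released Ca2+ is
#' never removed by an opening, hence the max).  On a decrease, c is left
#' unchanged at the transition instant -- the residual Ca2+ remains and
#' subsequent [advanceConcentration()] relaxes it toward the new, lower
#' plateau at rate k.
#'
#' @param state a domain state from [domainState()].
#' @param new_n_open the new open-channel count.
#' @param params a [MicrodomainParameters-class] object.
#' @return the updated domain state.
#' @export
onOpenCountChange <- function(state, new_n_open, params) {
  new_n_open <- .checkCount(new_n_open)
  if (new_n_open > state$n_open)
    state$c <- max(state$c, stationaryConcentration(new_n_open, params))
  state$n_open <- new_n_open
  state
}

#' Ca2+ concentration felt by a subunit
#'
#' The two-scale feedback rule: subunits of an open channel are exposed to
#' the pore nanodomain at the fixed concentration \code{c_high}; subunits
#' of closed channels feel the current coupling concentration of the
#' microdomain.
#'
#' @param channel_is_open logical flag for the subunit's channel.
#' @param state a domain state from [domainState()].
#' @param params a [MicrodomainParameters-class] object.
#' @return concentration in uM.
#' @export
subunitConcentration <- function(channel_is_open, state, params) {
  stopifnot(is.logical(channel_is_open), length(channel_is_open) == 1L)
  if (channel_is_open) params@c_high else state$c
}
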