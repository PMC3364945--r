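# Independent equilibrium oracle: for a parameter set satisfying the
# thermodynamic loop constraint, the stationary distribution of the subunit
# cube has the Boltzmann product form.  Each state's weight is the product
# of (binding rate / unbinding rate) factors along a canonical path from
# (0,0,0): first occupy h (no-IP3 inhibition pair), then i (pair selected
# by the current h), then a.  Detailed balance makes the result
# path-independent, so this never touches the package's linear solver.
dbEquilibriumOracle <- function(c, ip3, rates) {
  states <- expand.grid(h = 0:1, a = 0:1, i = 0:1)[, c("i", "a", "h")]
  w <- apply(states, 1L, function(s) {
    weight <- 1
    if (s[["h"]] == 1)
      weight <- weight * rates[["a_inh_noip3"]] * c / rates[["b_inh_noip3"]]
    if (s[["i"]] == 1) {
      pair <- if (s[["h"]] == 1) c("a_ip3_inh", "b_ip3_inh")
              else c("a_ip3_noninh", "b_ip3_noninh")
      weight <- weight * rates[[pair[1L]]] * ip3 / rates[[pair[2L]]]
    }
    if (s[["a"]] == 1)
      weight <- weight * rates[["a_act"]] * c / rates[["b_act"]]
    weight
  })
  pi <- w / sum(w)
  names(pi) <- apply(states[, c("i", "a", "h")], 1L, paste, collapse = "")
  pi[order(names(pi))]
}

# A fully symmetric rate vector (all rates 1): every dissociation constant
# is 1 uM, so at c = ip3 = 1 uM all 8 states are equally likely.  This set
# violates the class invariant K_inh_ip3 > K_inh_noip3 on purpose, hence a
# bare named vector rather than a GatingParameters object.
symmetricRates <- function() {
  r <- rep(1, 10)
  names(r) <- c("a_act", "b_act", "a_inh_ip3", "b_inh_ip3", "a_inh_noip3",
                "b_inh_noip3", "a_ip3_noninh", "b_ip3_noninh", "a_ip3_inh",
                "b_ip3_inh")
  r
}

# Short-duration config for engine tests.
quickConfig <- function(duration = 5, burn_in = 1, seed = 1L, ...) {
  simulationConfig(duration = duration, burn_in = burn_in, seed = seed, ...)
}
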