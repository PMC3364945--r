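---
title: "Puffs and waves from a cluster of IP3R channels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Puffs and waves from a cluster of IP3R channels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ip3rpuff)
```

## The model

`ip3rpuff` simulates calcium release from a single cluster of inositol
1,4,5-trisphosphate receptor (IP3R) channels on the ER membrane.  Two
coupled components are modelled:

**Subunit gating.**  Each channel has four identical subunits; each
subunit carries an IP3 binding site (index $i$), an activating Ca$^{2+}$
site ($a$), and an inhibiting Ca$^{2+}$ site ($h$), giving eight states
arranged on a cube (the DeYoung–Keizer scheme).  Binding transitions have
rate $a \cdot c$ (Ca$^{2+}$ sites) or $a \cdot [\mathrm{IP3}]$ (IP3 site);
unbinding transitions have rate $b$.  The inhibition rate pair depends on
whether IP3 is bound, and the IP3 rate pair depends on whether the subunit
is inhibited; thermodynamic consistency around the cube faces forces the
loop constraint
$$K_{\mathrm{ip3}}^{\mathrm{noninh}} \, K_{\mathrm{inh}}^{\mathrm{ip3}}
 = K_{\mathrm{ip3}}^{\mathrm{inh}} \, K_{\mathrm{inh}}^{\mathrm{noip3}},
 \qquad K_x = b_x / a_x,$$
which `GatingParameters` validity enforces to within $10^{-6}$ relative.
A channel is open while at least three of its four subunits are in the
open substate $(1,1,0)$.

**Microdomain.**  The Ca$^{2+}$ concentration felt by a subunit is
two-scale.  Subunits of an open channel see the pore nanodomain at the
fixed value $c_{\mathrm{high}}$.  Subunits of closed channels see the
cluster coupling concentration $c$, whose quasi-stationary value is linear
in the number of open channels, $c_{\mathrm{stat}} = c_0 + c_1 n_{\mathrm{open}}$.
On an increase of $n_{\mathrm{open}}$, $c$ jumps up instantaneously to
$\max(c, c_{\mathrm{stat}})$; after closings the residual Ca$^{2+}$ relaxes
exponentially, $\dot c = k (c_{\mathrm{stat}} - c)$, at the collapse rate
$k$.  Large $k$ stands in for a slow mobile buffer (EGTA) that removes
residual Ca$^{2+}$ quickly; small $k$ is the unbuffered case with
persistent residual microdomains.

This coarse-grained picture deliberately omits explicit buffer kinetics,
spatial concentration profiles, channel currents and source geometry; they
are folded into the four numbers $(c_0, c_1, c_{\mathrm{high}}, k)$.

## Why the two regimes differ

At $k = 100\,/\mathrm{s}$ the residual microdomain collapses within tens of
milliseconds.  Events are short (puffs): subunits of open channels inhibit
quickly at $c_{\mathrm{high}}$ and, once the last channel closes, Ca$^{2+}$
is gone before de-inhibition (rate $b_{\mathrm{inh}}^{\mathrm{ip3}} =
2\,/\mathrm{s}$) can re-open anything.  Puff termination is Ca$^{2+}$
inhibition.

At $k = 10\,/\mathrm{s}$ residual Ca$^{2+}$ outlives de-inhibition, so
channels re-open repeatedly and events become seconds-long bursts (the
wave regime).  The burst can only terminate through the slower process of
IP3 unbinding: inhibited subunits sit in $(1,1,1)$, where the IP3
dissociation constant is large ($K_{\mathrm{ip3}}^{\mathrm{inh}} =
0.7\,\mu$M, above stimulating IP3 levels), so they gradually lose IP3 and
accumulate in $(0,\cdot,1)$; channels with fewer than three IP3-bound
subunits cannot open.  The recorded counters `n111`, `n011` and `n_avail`
expose exactly this mechanism in every trace.

## Parameters, units, defaults

All concentrations are in uM, all rates in 1/s (on-rates in 1/(uM s)).

| parameter | default | meaning |
|---|---|---|
| `K_act` | 0.25 | activation threshold of the Ca site (half-occupancy) |
| `K_inh_noip3` | 0.111 | inhibition dissociation constant without IP3 |
| `K_ip3_inh` | 0.7 | IP3 dissociation constant of inhibited subunits |
| `b_inh_ip3` | 2 | de-inhibition rate of IP3-bound subunits |
| `K_inh_ip3` | 16 | inhibition dissociation constant at high IP3 |
| `K_ip3_noninh` | 0.00486 | forced by the loop constraint |
| `c0` | 0.02 | resting Ca concentration |
| `c1` | 2.2 | coupling concentration per open channel |
| `c_high` | 120 | pore concentration at an open channel |
| `k` | 100 | microdomain collapse rate (10 = unbuffered) |
| `n_channels` | 20 | channels per cluster |
| `ip3` | 0.07 | stimulating IP3 concentration |

The first four rows are anchored directly to reported single-channel
properties; the remaining kinetic freedom (the on-rates and
$K_{\mathrm{inh}}^{\mathrm{ip3}}$) is a calibration, discussed next.

## Calibration of the free rates

The dissociation constants above fix only rate *ratios*.  The shipped
on-rates were calibrated once, against the printed macroscopic behaviour
of the reference setup (20 channels, ip3 = 0.07 uM), and then frozen:

* median puff lifetime between 100 and 300 ms and median peak amplitude
  of 5–10 channels at $k = 100\,/\mathrm{s}$;
* mean interpuff interval near 4 s at $k = 100\,/\mathrm{s}$ and near 6 s
  at $k = 10\,/\mathrm{s}$;
* a one-order-of-magnitude drop of mean lifetime from $k = 10$ to
  $k = 100\,/\mathrm{s}$.

The calibration moved four quantities within their stated qualitative
constraints: the activation on-rate `a_act` (sets the trigger kinetics;
bounded above by the time-step rule), the inhibition scale `K_inh_ip3`
(kept well above `K_inh_noip3`, of order tens of uM), and the two IP3
on-rates, which remain the slowest processes in the model.  The IP3
on-rates are *not* shared between the inhibited and uninhibited branches
in the shipped defaults: IP3 *re*-binding of recovered subunits
(`a_ip3_noninh`) is faster than IP3 exchange on inhibited subunits
(`a_ip3_inh`), which controls how quickly the cluster regains openable
channels after a long burst without touching the burst-terminating IP3
loss rate.  Detailed balance constrains only the $K$ loop, so this split
is thermodynamically free; a single shared on-rate can be restored by
passing equal values to `gatingParameters()`.

## Numerical scheme

Time is discretized with a fixed step `dt` ($10^{-5}$ s by default).  In
each step, every subunit's three candidate transitions fire independently
with probability rate × `dt`; in the rare case that two fire in the same
step for the same subunit, that subunit's step is redrawn (the exact
conditional distribution is sampled directly with one uniform draw).  All
subunits see start-of-step concentrations and channel statuses
(synchronous update, which removes any dependence on subunit ordering);
channel open states are then recomputed, the microdomain jump rule is
applied, and the concentration is relaxed with the *exact* exponential
update over `dt` — there is no ODE integration error anywhere in the
scheme.

With the largest rate $a_{\mathrm{act}} c_{\mathrm{high}} \approx 10^4\,
/\mathrm{s}$, the default step keeps per-step transition probabilities
below 0.1; configuration validity rejects anything larger.  We accept
per-step probabilities up to about 0.1 rather than 0.01 because the
per-step law is sampled exactly (the discretization error of dwell-time
*means* vanishes identically; only the shape of sub-`dt` correlations is
affected).

Quiescent stretches — every channel closed and the microdomain within
$10^{-6}$ uM of rest — are advanced by exact geometric skip-ahead: per-step
outcomes are then i.i.d. per subunit, so the next state change is sampled
from the corresponding geometric law and the intervening steps are skipped.
The trajectory law is identical to naive stepping up to the $10^{-6}$ uM
quench; this is what reduces a 400 s run from $4 \times 10^7$ explicit
steps to seconds of wall time in the puff regime (tens of seconds in the
wave regime, where events and their relaxation tails dominate).  The RNG is
xoshiro256++ seeded from the integer config seed, so a configuration
reproduces its trace bit-for-bit.

The pure-R `stepCluster()` implements the identical per-step semantics and
serves as the reference for unit tests.

## Event detection conventions

A release event starts at the first sample with one or more open channels
and ends at the last closing that is followed by at least 500 ms of
quiet; shorter quiet gaps are absorbed into the event (gap-closure rule).
Consequences adopted here:

* the lifetime is the full first-opening-to-last-closing span, internal
  sub-window gaps included;
* the interpuff interval (IPI) is onset-to-onset; the dormancy is the
  end-to-next-onset quiet interval.  Whether the experimental IPI is
  onset-based is ambiguous, so both are always reported; onset-to-onset
  is the headline because dormancy is defined separately as the
  no-open-channel interval;
* events truncated by either trace end are discarded (the leading one has
  an unobserved onset, the trailing one an uncertifiable termination);
* detection operates on the sampled `n_open` series; openings shorter
  than `record_dt` (1 ms by default) can in principle be missed, which is
  shared with any sampled readout.

Histogram conventions: 100 ms bins for lifetimes, 0.5 s bins for IPI and
dormancy.

## What the simulator does and does not establish

The generator *is* the stated model: every trace is produced by the DYK
subunit chain coupled to the two-scale microdomain under the shipped
defaults — sample sizes (20 channels), stimulation (ip3 = 0.07 uM), and
the collapse-rate sweep {10, 20, 50, 100}/s are the conditions of the
reference setup, not tunables of the test suite.  A green statistical test
therefore establishes that the *model* reproduces the targeted
phenomenology.  It does not establish anything about real clusters beyond
the model's scope: no spatial structure within the cluster, no explicit
buffer or dye kinetics, no inter-cluster coupling (waves here means the
long-burst release mode of one cluster, the local engine of a global
wave), and no fluorescence convolution of amplitudes.

## Numerical and design choices worth knowing

* **Jump rule under residual Ca$^{2+}$:** re-opening when $c$ still
  exceeds the new stationary value keeps $c$ (a max rule) — released
  Ca$^{2+}$ cannot be removed by an opening.  Downward jumps never occur.
* **Relaxation after partial closings:** the exponential collapse relaxes
  toward $c_{\mathrm{stat}}(n_{\mathrm{open}})$ for *any* decrease, not
  only full closure, since the stationary relation is defined for every
  open count.
* **Initial condition:** all subunits unbound, microdomain at rest, and a
  10 s burn-in discarded before statistics — long enough for the fast
  (activation/inhibition) processes; the slow IP3 pool equilibrates over
  the first tens of seconds and contributes a small conservative bias
  toward fewer early events.
* **Freeze tolerance:** quenching $|c - c_0| < 10^{-6}$ uM changes rates
  by at most $a_{\mathrm{act}} \times 10^{-6} \approx 10^{-4}\,/\mathrm{s}$,
  orders of magnitude below any process in the model.
* **Degenerate inputs:** ip3 = 0 leaves the open substate unreachable
  (simulations stay silent); the equilibrium solver handles the reducible
  ip3 = 0 chain by clamping roundoff-negative probabilities of unreachable
  states.
* **Scaled-down replication:** published-style figures pool many long
  runs; the test suite pools 3–8 seeds of 150–400 s per condition so the
  whole suite stays within minutes.  Standard errors quoted by
  `sweepSimulations()` make the residual noise visible.

## Known limitations

* In this calibration the mean interpuff interval at $k = 10\,/\mathrm{s}$
  *decreases* between IP3 = 0.02 and 0.05 uM and is flat above, instead
  of increasing with IP3: at low IP3 the scarcity of trigger openings
  (lower IP3-site occupancy, shorter and less self-sustaining events)
  outweighs the IP3-unbinding refractoriness that grows with IP3.  The
  reproduction suite asserts the increasing behaviour and that assertion
  fails by design rather than being weakened; every accessible parameter
  set we examined, including the uncalibrated defaults, shows the same
  sign.  Mean *lifetime* does increase with IP3 throughout.

* The hidden single-channel fit is not reproduced; the shipped rates are
  one calibrated point in the constraint set, not a fit to patch-clamp
  data, and dose–response *shapes* (bell curve, rightward peak shift with
  IP3) rather than absolute open probabilities are the reliable outputs
  of the gating module.
* Amplitudes are open-channel counts, not fluorescence amplitudes.
* The event detector certifies termination only within a trace; runs
  shorter than a few expected IPIs yield few (or zero) usable events.
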