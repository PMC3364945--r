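Package: ip3rpuff
Title: Stochastic Simulation of Calcium Puffs and Waves from Clustered
    IP3 Receptor Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic Monte Carlo simulation of a cluster of inositol
    1,4,5-trisphosphate receptor (IP3R) channels with DeYoung-Keizer
    subunit gating coupled to a coarse-grained, non-stationary calcium
    microdomain.  The microdomain is described by two concentration
    scales (a fixed pore concentration felt by open channels and a
    coupling concentration that follows the number of open channels
    linearly) and collapses exponentially at a tunable rate after
    channels close, which stands in for the action of slow mobile
    calcium buffers such as EGTA.  The package provides the 8-state
    subunit equilibrium and open-probability dose-response, trace
    simulation for clusters of 20 channels, detection of release
    events with the 500 ms gap-closure rule, and lifetime, interpuff
    interval and dormancy statistics for studying how puffs terminate
    by calcium inhibition while long wave-like bursts terminate by
    IP3 unbinding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
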