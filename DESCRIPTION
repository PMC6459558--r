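Package: metanet
Title: Stochastic Network Models of Metastatic Dissemination
Version: 0.1.0
Authors@R:
    person("Metanet", "Developers", email = "metanet@example.org", role = c("aut", "cre"))
Description: Inference of relative metastatic dissemination rates from
    cross-sectional incidence data using a continuous-time Markov chain on a
    directed anatomical network. Sites (lymph node stations or organs) are
    binary (metastasis-free or colonised); a site is seeded either directly
    from the primary tumour or by secondary seeding from an upstream
    metastasis. The package enumerates the topologically reachable metastatic
    states, solves the master equation (matrix exponential or Euler forward),
    fits per-edge dissemination rates by maximum likelihood with tumour stage
    as a proxy for time, computes parametric-bootstrap confidence intervals,
    and derives seed-soil ratios from relative blood flows. A synthetic-cohort
    generator (exact categorical and Gillespie samplers) replaces clinical
    data for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
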