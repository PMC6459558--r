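# metanet — stochastic network models of metastatic dissemination

`metanet` is an R package for oncologists, cancer biologists and
biostatisticians who want to turn cross-sectional incidence data — per
patient: primary tumour T-stage plus positive/negative status of a handful
of metastatic sites — into **relative dissemination rates** along
anatomically admissible routes of spread.

## The model

Sites (lymph node stations or organs) are nodes of a directed network.
CTCs released by a positive source seed only the next site downstream
(capillary beds and lymph nodes filter almost everything), so distant
sites are reached by *secondary seeding* from intermediate metastases.
Each edge carries one rate: λ_v from the primary tumour into site v, and
φ_{u→v} between sites. Site status is binary and irreversible, and a
negative site v turns positive with rate

    r_v(S) = λ_v · [v primary-fed] + Σ_{u→v, S_u = 1} φ_{u→v},

so the state S ∈ {0,1}^N evolves as a continuous-time Markov chain whose
distribution obeys the master equation dP/dt = QP from the all-negative
initial state. Only topologically reachable states exist (12 of 16 for the
built-in tongue network, 18 of 32 for the ovarian one); a state violating
reachability is a *skip metastasis* and is excluded from fitting. Tumour
stage serves as a proxy for time (linearly, or in years via exponential
tumour growth), and rates are estimated by maximising
L(θ) = Π_j P_{s_j}(τ_j; θ) with Nelder–Mead over log-rates, with
parametric-bootstrap quantile intervals.

## Worked example

Simulate a 141-patient tongue-cancer cohort from known rates, then recover
them:

```r
library(metanet)
net   <- tongue_network()
space <- enumerate_reachable_states(net)
space
#> <state_space> 12 reachable states over sites I,II,III,IV
#>   1:0000  2:0010  3:0100  4:1000  5:0011  6:0110  7:1010  8:1100
#>   9:0111  10:1011  11:1110  12:1111

stmap <- stage_to_time("linear", c("T1", "T2", "T3", "T4"))
theta <- c(lambda_I = 0.09, lambda_II = 0.19, lambda_III = 0.04,
           phi_I = 0.09, phi_II = 0.21, phi_III = 0.07)
design <- cohort_design(c(T1 = 35, T2 = 35, T3 = 35, T4 = 36),
                        theta, stmap, seed = 1)
coh  <- sample_cohort(net, space, design)
filt <- exclude_unreachable(coh, space)
fit  <- fit_mle(filt$cohort, net, stmap, space = space)
fit  <- parametric_bootstrap(fit, filt$cohort, net, stmap, B = 100, seed = 1)
fit
#> <metanet_fit> n = 141  log-likelihood = -216.64943 (converged)
#>            estimate    lower    upper
#> lambda_I   8.29e-02 5.54e-02 1.06e-01
#> lambda_II  1.73e-01 1.29e-01 2.22e-01
#> lambda_III 4.24e-02 2.17e-02 6.63e-02
#> phi_I      1.00e-12 1.00e-12 3.60e-11
#> phi_II     1.68e-01 6.08e-02 3.24e-01
#> phi_III    2.31e-11 1.00e-12 5.77e-11
```

The direct seeding rates λ and the strongly identified station II→III flow
are recovered near their true values at n = 141, while φ_I and φ_III
collapse to the floor: this particular draw contains no patient pattern
that forces flow through those edges, the same weak identifiability that
small clinical cohorts show (rare station-IV events; station II fed by
both the primary and station I). At n = 5000 all well-identified rates are
recovered within a few percent — that simulation is the package's core
acceptance test.

Per-stage predictions for counselling a new patient:

```r
round(predict_marginals(fit, net, space, stmap, stage = "T2"), 3)
#>     I    II   III    IV
#> 0.153 0.292 0.124 0.000
```

i.e. a T2 primary carries ~29% probability of station II involvement under
the fitted model. Everything above is also available end-to-end via
`run_pipeline()` (JSON config → fit.json, excluded.csv, fractions.csv,
marginals.csv) or the CLI script `exec/metanet.R`
(`states | solve | simulate | fit | seed-soil | run` subcommands).

Seed–soil analysis: divide a fitted rate into an organ by the relative
blood flow to it, e.g.
`seed_soil_ratios(c(phi_2 = 0.092, phi_3 = 0.015, phi_4 = 0.004),
c(phi_2 = 0.065, phi_3 = 0.05, phi_4 = 0.012))` gives 1.42 / 0.30 / 0.33
for liver / bone / brain — the liver is ~5× more receptive to ovarian
cancer cells per unit of blood flow than bone or brain.

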