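---
title: "Inferring dissemination rates on anatomical networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dissemination rates on anatomical networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanet)
```

## The model

Metastatic dissemination is constrained by anatomy. Circulating tumour
cells (CTCs) released by a tumour follow the lymph or blood flow and are
filtered at the first capillary bed or lymph node they meet, so distant
sites are reached almost exclusively by *secondary seeding*: an established
metastasis sheds its own CTCs further downstream. metanet encodes this as a
directed network whose nodes are sites (lymph node stations or organs) and
whose edges are admissible routes of spread, each carrying one rate
parameter: $\lambda_v$ for an edge from the primary tumour into site $v$,
$\phi_{u \to v}$ for an edge between sites. A rate aggregates CTC release,
survival in transit and the probability of colonising the target — it is
the rate at which the downstream site turns positive given a positive
source.

Each site is binary (0 = free of metastases, 1 = colonised; sizes are
deliberately not modelled, they would multiply the parameter count) and
never reverts. The state of a patient is a binary string over the sites in
network order; with $N$ sites there are $2^N$ strings, but only the states
reachable from the all-negative state by activating one site at a time —
where the activated site has a primary edge or a positive upstream feeder —
can occur. For the built-in tongue network (stations I–IV; primary feeds
I, II, III; chain I→II→III→IV) 12 of 16 states are reachable; for the
ovarian network (regional LN, lung, liver, bone, brain) 18 of 32. The
missing states are exactly the *skip metastases* (e.g. station IV positive
with III negative).

Site activation is memoryless with rate equal to the sum of flow rates from
all positive feeders (the primary counts as always positive), so the state
process is a continuous-time Markov chain. Writing $P_i(t)$ for the
probability of state $i$, the distribution obeys the master equation

$$\frac{dP}{dt} = Q\,P, \qquad P(0) = \delta_{\text{all-negative}},$$

where the generator $Q$ has $Q_{ij} \ge 0$ the rate from state $j$ to state
$i$ (a single-site activation) and columns summing to zero. The
all-positive state is absorbing.

## Stage as a proxy for time

Cohorts are cross-sectional: per patient we see the primary tumour T-stage
and the per-site status at diagnosis, never event times. The stage is used
as a monotone proxy for time since tumour initiation. Two mappings are
provided:

* **linear** (default): stage $k$ of $K$ maps to time $k$ on an arbitrary
  scale. All inferred rates are then *relative*; only ratios and orderings
  are interpretable.
* **exponential_growth**: assuming exponential volume growth
  $V(t) = V_0 e^{\alpha t}$ of a spherical tumour, a stage with radius
  $R_i$ is reached at $t_i = 3\ln(R_i/R_0)/\alpha$ years. Defaults:
  $R_0 = 25\ \mu m$ (a single cell), $\alpha = 365\ln 2/40$ per year (a
  40-day volume doubling time), and tongue stage radii 2/4/6/8 cm, giving
  stage times

```{r}
stage_to_time("exponential_growth", c("T1", "T2", "T3", "T4"),
              growth = growth_params())
```

The two mappings give different absolute rates: in our simulations the
exponential map (whose stage times span a narrower range) systematically
shrinks the λ estimates to roughly 0.65–0.7× their linear-map values and
inflates the upstream-fed φ into station II by ~1.2–1.4×. Rates that are
well separated keep their relative order across the two maps, so
conclusions about *which* routes dominate are robust to the growth
assumption; rates that are nearly tied (the simulated world ties λ_I and
φ_I exactly) can swap, and an acceptance test that demands strict
whole-vector rank equality across the maps is deliberately left failing to
record this boundary of the robustness claim.

Ovarian substages T1a…T3c are mapped to 1…9 equally spaced; the spacing of
substages is not knowable from stage definitions alone, so this is a
configurable convention, not a claim.

## Likelihood, fitting, intervals

A patient with stage $s_j$ (time $\tau_j$) observed in state $i_j$
contributes $P_{i_j}(\tau_j;\theta)$; the cohort log-likelihood is the sum
of logs. Internally patients are aggregated into (stage, state) counts and
the master equation is solved once per distinct stage time, so the cost of
one likelihood evaluation does not grow with cohort size.

`fit_mle()` minimises the negative log-likelihood with Nelder–Mead over
*log-rates*: positivity comes from the parameterisation rather than from
constraints, and an estimate that wants to be zero simply runs off to a
very negative log-rate (a floor of $10^{-12}$ keeps the likelihood
finite). The default start is every rate at 0.1; `multistart = 5` draws
additional starts log-uniformly on $[10^{-3}, 1]$ and keeps the best final
likelihood. The fit is deterministic given the starting point(s).

`parametric_bootstrap()` redraws each patient's state from the fitted model
at their *observed* stage (conditioning on the stage design, as in a
regression-type bootstrap; whether the stages should also be redrawn is a
genuine modelling choice — we fix them), refits, and reports per-rate
empirical quantiles. The defaults, the 5% and 95% quantiles of $B = 100$
replicates, form a 90% equal-tailed interval; note that published tables of
this construction are sometimes labelled "95% CI". The nominal level is
configurable. Rates that are weakly identified (a site fed both by the
primary and by an upstream station, or a rare terminal site) show up
honestly as intervals spanning orders of magnitude, with lower quantiles
collapsing to zero when replicates happen to contain no event at the
terminal site.

`seed_soil_ratios()` divides a fitted rate into an organ by the relative
blood flow to that organ. Since the rate is flow × survival ×
colonisation, the ratio isolates the organ's receptiveness per arriving
cell (the "soil" of the seed–soil hypothesis). Ratios are returned at full
precision; two-decimal rounding is a display choice.

## Numerical choices

* **Solver.** The master equation is linear, so the matrix exponential
  $e^{Qt}P(0)$ (via the Matrix package) is exact and is the default and the
  accuracy oracle. The Euler forward scheme is retained as the historically
  faithful method. A first-order scheme needs a very small step to reach
  the package's accuracy contract (Euler-vs-exponential agreement within
  $10^{-6}$); the default is $h = 10^{-6}$, made affordable by evaluating
  the Euler iterate $(I + hQ)^k P(0)$ with binary matrix powers —
  algebraically the same recursion, at $O(\log k)$ matrix products. Halving
  $h$ moves the solution by less than $10^{-7}$.
* **Conservation.** Distributions are checked to sum to one within
  $10^{-9}$; sub-round-off negatives are clamped and renormalised, anything
  larger raises an error rather than being silently renormalised — a large
  deviation means a broken generator, not noise.
* **State ordering.** Breadth-first level order (number of positive sites),
  lexicographic within a level, all-negative state first. Any published
  diagram numbering of states is a presentation convention; all marginal
  sums here are computed by membership in the state space, never by
  hard-coded indices.
* **Optimiser tolerances.** `reltol = 1e-9`, `maxit = 5000`. Bootstrap
  refits start from the original estimate, which is both faster and the
  standard warm-start for parametric resampling.

## The synthetic-cohort generator

`sample_cohort()` draws cohorts with the model's exact statistical
structure: patient states are sampled from the categorical distribution
$P(\cdot;\tau_{\text{stage}},\theta)$ (sampler `"exact"`), or by simulating
the chain event-by-event with exponential clocks (sampler `"gillespie"`).
The two samplers are independent code paths realising the same process and
are required by the test suite to be statistically indistinguishable from
each other and from the master-equation solution — the model's central
self-consistency check.

Reproducibility contract: each patient draws from an RNG substream derived
from the cohort seed and the patient's position, so patient $k$ is
identical whether the cohort has 10 or 10 000 later patients. (The
bootstrap's internal resampler, which needs no per-patient stability, uses
one vectorised substream per replicate for speed.)

Optional contamination plants, with a configured probability per patient,
one extra positive site that has neither a primary edge nor a positive
feeder — precisely the skip-metastasis pathology observed at low rates in
real cohorts (a few percent of patients), which the exclusion filter
`exclude_unreachable()` must catch. Default stage composition in examples
and tests is uniform; the clinical tongue cohort's exact composition ships
only in a non-public supplementary file, so nothing here depends on it.

What a green synthetic test does establish: the estimator recovers the
generating rates at realistic sample sizes, intervals cover, and both
samplers agree with the forward solver. What it cannot establish: that the
model is well-specified for any real cohort — real data bring detection
limits (undetected micrometastases), stage-assignment noise, and routes
outside the network (e.g. transcoelomic spread in ovarian cancer, which is
deliberately not modelled because per-site peritoneal data are not
recorded in the registries this model targets).

## Worked example

```{r, eval = FALSE}
net <- tongue_network()
space <- enumerate_reachable_states(net)
stmap <- stage_to_time("linear", c("T1", "T2", "T3", "T4"))
theta <- c(lambda_I = 0.09, lambda_II = 0.19, lambda_III = 0.04,
           phi_I = 0.09, phi_II = 0.21, phi_III = 0.07)

design <- cohort_design(c(T1 = 35, T2 = 35, T3 = 35, T4 = 36),
                        theta, stmap, seed = 1)
coh <- sample_cohort(net, space, design)
filt <- exclude_unreachable(coh, space)
fit <- fit_mle(filt$cohort, net, stmap, space = space)
fit <- parametric_bootstrap(fit, filt$cohort, net, stmap, B = 100, seed = 1)
fit
predict_marginals(fit, net, space, stmap, stage = "T2")
```

## Known limitations

* Rates on the linear stage scale are relative; cross-study comparison
  needs a common time mapping.
* One rate symbol per edge; tying a symbol across edges is not supported.
* No regression of sites, no metastasis sizes, no treatment effects, no
  self-seeding back to the primary, no time-varying rates.
* Identifiability degrades exactly where the network says it should: sites
  fed by both the primary and an upstream neighbour split their inflow
  ambiguously at small $n$; terminal sites with rare events produce
  degenerate bootstrap lower quantiles.
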