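make_cohort_df <- function(net, stages, states) {
  bits <- matrix(unlist(lapply(states, function(s)
    as.integer(strsplit(s, "")[[1]]))), nrow = length(states), byrow = TRUE)
  colnames(bits) <- net$sites
  cohort(cbind(data.frame(patient_id = seq_along(stages), stage = stages),
               as.data.frame(bits)), net)
}

test_that("log-likelihood matches closed forms", {
  net <- one_site_network()
  sp <- enumerate_reachable_states(net)
  stm <- stage_to_time("linear", c("T1", "T2", "T3"))
  # one metastasis-free patient at stage time 3: log P = -lambda * 3
  coh <- make_cohort_df(net, "T3", "0")
  expect_equal(log_likelihood(coh, net, sp, c(lambda = 0.25), stm), -0.75)
  # zero rates, metastasis-free cohort: every probability is 1
  coh2 <- make_cohort_df(net, c("T1", "T2", "T3"), c("0", "0", "0"))
  expect_equal(log_likelihood(coh2, net, sp, c(lambda = 0), stm), 0)
  # a state of probability zero yields the -Inf sentinel or an error
  coh3 <- make_cohort_df(net, "T2", "1")
  expect_identical(log_likelihood(coh3, net, sp, c(lambda = 0), stm), -Inf)
  expect_error(log_likelihood(coh3, net, sp, c(lambda = 0), stm,
                              on_zero = "error"), "probability 0")
  expect_error(log_likelihood(coh2[0, ], net, sp, c(lambda = 1), stm), "empty")
})

test_that("tongue likelihood equals an independent expm product", {
  net <- tongue_network()
  sp <- enumerate_reachable_states(net)
  stm <- tongue_stmap()
  th <- tongue_truth_theta()
  stages <- c("T1", "T2", "T2", "T3", "T4")
  states <- c("0000", "1000", "0100", "1100", "1110")
  coh <- make_cohort_df(net, stages, states)
  # oracle: hand-built generator, direct matrix exponential per patient
  Q <- tongue_hand_generator(th)
  p0 <- as.numeric(rownames(Q) == "0000")
  oracle <- sum(vapply(seq_along(stages), function(j) {
    tau <- match(stages[j], c("T1", "T2", "T3", "T4"))
    P <- as.matrix(Matrix::expm(Q * tau)) %*% p0
    log(P[states[j], 1])
  }, numeric(1)))
  expect_equal(log_likelihood(coh, net, sp, th, stm), oracle,
               tolerance = 1e-10)
})

test_that("likelihood is invariant to patient order and site-order convention", {
  coh <- make_tongue_cohort(40, seed = 3)
  net <- tongue_network()
  sp <- enumerate_reachable_states(net)
  stm <- tongue_stmap()
  th <- tongue_truth_theta()
  ll <- log_likelihood(coh, net, sp, th, stm)
  shuf <- coh[rev(seq_len(nrow(coh))), ]
  attributes(shuf)[c("sites", "class")] <- attributes(coh)[c("sites", "class")]
  expect_equal(log_likelihood(shuf, net, sp, th, stm), ll)
  # permuted site ordering: same patients, same rates, same likelihood
  perm <- c("II", "IV", "I", "III")
  net2 <- site_network(perm, net$primary_edges, net$secondary_edges)
  sp2 <- enumerate_reachable_states(net2)
  coh2 <- cohort(as.data.frame(coh)[c("patient_id", "stage", perm)], net2)
  expect_equal(log_likelihood(coh2, net2, sp2, th, stm), ll)
})

test_that("likelihood refuses unreachable states until filtered", {
  net <- tongue_network()
  sp <- enumerate_reachable_states(net)
  coh <- make_cohort_df(net, c("T1", "T2"), c("0000", "0001"))
  expect_error(log_likelihood(coh, net, sp, tongue_truth_theta(), tongue_stmap()),
               "unreachable")
})

test_that("a metastasis-free cohort drives identified rates to the lower boundary", {
  stm <- stage_to_time("linear", c("T1", "T2"))
  net1 <- one_site_network()
  coh1 <- make_cohort_df(net1, c("T1", "T1", "T2", "T2"), rep("0", 4))
  fit1 <- fit_mle(coh1, net1, stm)
  expect_lt(fit1$theta_hat[["lambda"]], 1e-4)
  expect_gt(fit1$log_likelihood, -1e-3)
  # on the chain, phi never enters the likelihood while A stays negative,
  # so only lambda collapses; phi is unidentified and irrelevant
  net2 <- chain_network()
  coh2 <- make_cohort_df(net2, c("T1", "T1", "T2", "T2"), rep("00", 4))
  fit2 <- fit_mle(coh2, net2, stm)
  expect_lt(fit2$theta_hat[["lambda"]], 1e-4)
  expect_gt(fit2$log_likelihood, -1e-3)
})

test_that("the fitted point is a local maximum of the likelihood", {
  coh <- make_tongue_cohort(250, seed = 5)
  net <- tongue_network()
  sp <- enumerate_reachable_states(net)
  stm <- tongue_stmap()
  fit <- fit_mle(coh, net, stm, space = sp)
  expect_true(fit$converged)
  ll_hat <- fit$log_likelihood
  expect_equal(ll_hat, log_likelihood(coh, net, sp, fit$theta_hat, stm))
  for (k in seq_along(fit$theta_hat)) {
    for (f in c(0.9, 1.1)) {
      th <- fit$theta_hat
      th[k] <- th[k] * f
      expect_lte(log_likelihood(coh, net, sp, th, stm), ll_hat + 1e-7)
    }
  }
})

test_that("multistart is deterministic given a seed and improves nothing here", {
  coh <- make_tongue_cohort(50, seed = 9)
  net <- tongue_network()
  stm <- tongue_stmap()
  f1 <- fit_mle(coh, net, stm, multistart = 3, seed = 4)
  f2 <- fit_mle(coh, net, stm, multistart = 3, seed = 4)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_length(f1$diagnostics$value, 3)
})

test_that("bootstrap flags the weakly identified rate into station II", {
  # at the clinical sample size (n = 141) the flow from station I to II is
  # barely identified: its interval is far wider, relative to the estimate,
  # than that of the well-identified direct seeding of station II
  net <- tongue_network()
  sp <- enumerate_reachable_states(net)
  stm <- tongue_stmap()
  des <- cohort_design(c(T1 = 35, T2 = 35, T3 = 35, T4 = 36), tongue_truth_theta(),
                       stm, seed = 77)
  coh <- sample_cohort(net, sp, des)
  fit <- fit_mle(coh, net, stm, space = sp)
  fit <- parametric_bootstrap(fit, coh, net, stm, B = 100, seed = 78,
                              space = sp)
  ci <- fit$bootstrap_intervals
  expect_true(all(ci[, "lower"] <= ci[, "upper"]))
  span <- function(sym) ci[sym, "upper"] - ci[sym, "lower"]
  expect_gt(span("phi_I") / span("lambda_II"), 3)
  # collapse towards zero shows up as a near-zero lower quantile
  expect_lt(min(ci[, "lower"]), 0.02)
})

test_that("seed-soil ratios divide rates by relative flows", {
  theta <- c(phi_2 = 0.092, phi_3 = 0.015, phi_4 = 0.004)
  flows <- c(phi_2 = 0.065, phi_3 = 0.05, phi_4 = 0.012)
  r <- seed_soil_ratios(theta, flows)
  expect_equal(round(unname(r), 2), c(1.42, 0.30, 0.33))
  expect_equal(unname(seed_soil_ratios(c(x = 0.05), c(x = 0.05))), 1)
  expect_error(seed_soil_ratios(theta, c(phi_2 = 0)), "\\(0, 1\\]")
  expect_error(seed_soil_ratios(theta, c(phi_9 = 0.1)), "missing")
})
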