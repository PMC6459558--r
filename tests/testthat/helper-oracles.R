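# Shared fixtures and independent oracles for the test suite.
# Oracles here are written from first principles (explicit enumeration,
# closed forms, direct tallies) and never call the code paths they check.

# Published point estimates for the tongue network, used as the
# data-generating truth in simulation studies.
tongue_truth_theta <- function() {
  c(lambda_I = 0.09, lambda_II = 0.19, lambda_III = 0.04,
    phi_I = 0.09, phi_II = 0.21, phi_III = 0.07)
}

tongue_stmap <- function() stage_to_time("linear", c("T1", "T2", "T3", "T4"))

# Single site fed by the primary: the simplest network, with the closed-form
# solution P(positive at t) = 1 - exp(-lambda t).
one_site_network <- function() {
  site_network("A", primary_edges = c(A = "lambda"))
}

# Two-site chain primary -> A (lambda), A -> B (phi).
chain_network <- function() {
  site_network(c("A", "B"), primary_edges = c(A = "lambda"),
               secondary_edges = data.frame(from = "A", to = "B",
                                            symbol = "phi"))
}

# Brute-force reachability predicate: peel justified positive sites until a
# fixpoint. A positive site is justified if it has a primary edge or a
# justified positive feeder; the state is reachable iff every positive site
# ends up justified. Independent of the BFS enumeration under test.
brute_reachable <- function(net, bits) {
  n <- length(net$sites)
  justified <- rep(FALSE, n)
  repeat {
    changed <- FALSE
    for (v in seq_len(n)) {
      if (bits[v] != 1L || justified[v]) next
      site <- net$sites[v]
      ok <- site %in% names(net$primary_edges)
      if (!ok && nrow(net$secondary_edges)) {
        feeders <- net$secondary_edges$from[net$secondary_edges$to == site]
        ok <- any(justified[match(feeders, net$sites)])
      }
      if (ok) { justified[v] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  all(justified[bits == 1L])
}

# All reachable bit vectors of a network by exhaustive scan of 2^N states.
brute_reachable_set <- function(net) {
  n <- length(net$sites)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  keep <- apply(grid, 1L, function(b) brute_reachable(net, as.integer(b)))
  apply(grid[keep, , drop = FALSE], 1L, paste, collapse = "")
}

# Hand-enumerated transition list of the tongue model: every single-site
# activation among the 12 reachable states with its rate expression, written
# out state by state from the network diagram (primary feeds I, II, III;
# chain I->II->III->IV).
tongue_hand_generator <- function(theta) {
  lI <- theta[["lambda_I"]]; lII <- theta[["lambda_II"]]
  lIII <- theta[["lambda_III"]]
  pI <- theta[["phi_I"]]; pII <- theta[["phi_II"]]; pIII <- theta[["phi_III"]]
  edges <- list(
    list("0000", "1000", lI), list("0000", "0100", lII),
    list("0000", "0010", lIII),
    list("1000", "1100", lII + pI), list("1000", "1010", lIII),
    list("0100", "1100", lI), list("0100", "0110", lIII + pII),
    list("0010", "1010", lI), list("0010", "0110", lII),
    list("0010", "0011", pIII),
    list("1100", "1110", lIII + pII),
    list("1010", "1110", lII + pI), list("1010", "1011", pIII),
    list("0110", "1110", lI), list("0110", "0111", pIII),
    list("0011", "1011", lI), list("0011", "0111", lII),
    list("1110", "1111", pIII),
    list("1011", "1111", lII + pI),
    list("0111", "1111", lI))
  states <- c("0000", "0010", "0100", "1000", "0011", "0110", "1010", "1100",
              "0111", "1011", "1110", "1111")
  Q <- matrix(0, 12, 12, dimnames = list(states, states))
  for (e in edges) Q[e[[2]], e[[1]]] <- e[[3]]
  diag(Q) <- -colSums(Q)
  Q
}

# Random valid rate vector for a network (fixed-stream caller sets the seed).
random_theta <- function(net, max_rate = 1) {
  syms <- rate_symbols(net)
  stats::setNames(stats::runif(length(syms), 0.01, max_rate), syms)
}

# State strings of a cohort, via a direct paste over site columns.
cohort_states_for_test <- function(coh) {
  do.call(paste0, as.data.frame(coh)[attr(coh, "sites")])
}

# A synthetic tongue cohort at the published rates, uniform stages.
make_tongue_cohort <- function(n_per_stage, seed = 1, theta = tongue_truth_theta(),
                               contamination = 0, sampler = "exact") {
  net <- tongue_network()
  space <- enumerate_reachable_states(net)
  des <- cohort_design(
    stats::setNames(rep(n_per_stage, 4), c("T1", "T2", "T3", "T4")),
    theta, tongue_stmap(), seed = seed, sampler = sampler,
    contamination_rate = contamination)
  sample_cohort(net, space, des)
}
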