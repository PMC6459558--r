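# Synthetic cohorts with the model's exact statistical structure.
#
# Two samplers: "exact" draws each patient's metastatic state from the
# categorical distribution given by the master-equation solution at the
# patient's stage time; "gillespie" simulates the CTMC event by event and is
# an independent stochastic realisation of the same process, used as a
# cross-check oracle. Optional contamination plants skip metastases to
# exercise the exclusion filter.

# Per-patient RNG substream: patient k is reproducible independently of
# cohort size or sampler interleaving. Seeds stay below 2^31.
patient_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483629) + 1L
}

#' Design of a synthetic cohort
#'
#' @param stage_composition named integer vector: patients per stage label.
#' @param theta named rate vector (the data-generating rates).
#' @param stmap a \code{stage_time_map} covering the composition's labels.
#' @param seed integer RNG seed.
#' @param sampler \code{"exact"} (categorical draw from the master-equation
#'   distribution) or \code{"gillespie"} (event-by-event CTMC simulation).
#' @param contamination_rate probability, in [0, 1), that a patient gets one
#'   extra positive site with no positive upstream feeder and no primary
#'   edge -- a skip metastasis that makes the state unreachable. Default 0.
#' @return A list of class \code{cohort_design}.
#' @export
cohort_design <- function(stage_composition, theta, stmap, seed = 1,
                          sampler = c("exact", "gillespie"),
                          contamination_rate = 0) {
  sampler <- match.arg(sampler)
  if (is.null(names(stage_composition)))
    stop("stage_composition must be a named vector (stage label -> count)")
  if (any(stage_composition < 0) || sum(stage_composition) < 1)
    stop("stage counts must be >= 0 with total >= 1")
  bad <- setdiff(names(stage_composition), stmap$stage_labels)
  if (length(bad))
    stop("stage label(s) not in the stage-time map: ", paste(bad, collapse = ", "))
  if (contamination_rate < 0 || contamination_rate >= 1)
    stop("contamination_rate must lie in [0, 1)")
  structure(list(stage_composition = stage_composition, theta = theta,
                 stmap = stmap, seed = as.integer(seed), sampler = sampler,
                 contamination_rate = contamination_rate),
            class = "cohort_design")
}

#' Sample a synthetic patient cohort from the model
#'
#' Deterministic given the design's seed. With
#' \code{contamination_rate = 0} every sampled state is reachable.
#'
#' @param net the \code{site_network}.
#' @param space its \code{state_space}.
#' @param design a \code{\link{cohort_design}}.
#' @return A \code{metanet_cohort}.
#' @export
sample_cohort <- function(net, space, design) {
  stopifnot(inherits(design, "cohort_design"))
  theta <- validate_theta(net, design$theta)
  comp <- design$stage_composition
  stages <- rep(names(comp), times = comp)
  n <- length(stages)
  taus <- stage_time(design$stmap, stages)

  dist_by_stage <- NULL
  if (design$sampler == "exact") {
    u <- !duplicated(stages)
    Q <- build_generator(net, space, theta)
    ord <- order(taus[u])
    traj <- solve_master_equation(Q, taus[u][ord])
    dist_by_stage <- traj$probs[order(ord), , drop = FALSE]
    rownames(dist_by_stage) <- stages[u]
  }

  m <- length(space$states)
  bits <- matrix(0L, n, length(net$sites), dimnames = list(NULL, net$sites))
  for (k in seq_len(n)) {
    set.seed(patient_seed(design$seed, k))
    state <- if (design$sampler == "exact") {
      i <- sample.int(m, 1L, prob = dist_by_stage[stages[k], ])
      space$bits[i, ]
    } else {
      gillespie_bits(net, theta, taus[k])
    }
    if (design$contamination_rate > 0 &&
        stats::runif(1) < design$contamination_rate) {
      state <- contaminate_state(net, state)
    }
    bits[k, ] <- state
  }
  df <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                   stage = stages, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(bits))
  cohort(df, net,
         provenance = sprintf("synthetic(sampler=%s, seed=%d, contamination=%g)",
                              design$sampler, design$seed,
                              design$contamination_rate))
}

# Flip one negative site that has no primary edge and no positive feeder:
# the resulting state exhibits a skip metastasis and fails is_reachable().
# If no such site exists (e.g. everything positive) the state is returned
# unchanged.
contaminate_state <- function(net, bits) {
  cand <- character(0)
  for (v in setdiff(net$sites, names(net$primary_edges))) {
    if (bits[[match(v, net$sites)]] == 1L) next
    feeders <- net$secondary_edges$from[net$secondary_edges$to == v]
    if (!any(bits[match(feeders, net$sites)] == 1L))
      cand <- c(cand, v)
  }
  if (!length(cand)) return(bits)
  v <- if (length(cand) == 1L) cand else sample(cand, 1L)
  bits[[match(v, net$sites)]] <- 1L
  bits
}

# Core Gillespie simulation using the current RNG stream.
gillespie_bits <- function(net, theta, tau) {
  bits <- integer(length(net$sites))
  names(bits) <- net$sites
  t <- 0
  repeat {
    rates <- activation_rates(net, bits, theta)
    total <- sum(rates)
    if (total <= 0) break
    t <- t + stats::rexp(1L, total)
    if (t > tau) break
    v <- sample.int(length(rates), 1L, prob = rates)
    bits[v] <- 1L
  }
  bits
}

#' Simulate one CTMC realisation up to a given time
#'
#' Gillespie algorithm: every negative site fires at its current activation
#' rate (lambda of a primary edge plus phi of each positive feeder), waiting
#' times are exponential, and the site to activate is chosen proportionally
#' to its rate. Stops at time \code{tau} or when the all-positive absorbing
#' state is reached.
#'
#' @param net the \code{site_network}.
#' @param theta named rate vector.
#' @param tau simulation horizon, >= 0.
#' @param seed integer RNG seed.
#' @return Named integer 0/1 vector: the metastatic state at \code{tau}.
#' @export
gillespie_state_at <- function(net, theta, tau, seed = NULL) {
  if (tau < 0) stop("tau must be >= 0")
  theta <- validate_theta(net, theta)
  if (!is.null(seed)) set.seed(seed)
  gillespie_bits(net, theta, tau)
}
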