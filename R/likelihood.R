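# Maximum-likelihood inference of dissemination rates.
#
# Each patient contributes P_{s_j}(tau_j, theta): the master-equation
# probability of their observed metastatic state at the time mapped to
# their tumour stage. The cohort log-likelihood is the sum of these logs.
# Patients are aggregated into (stage, state) counts and the master equation
# is solved once per distinct stage time, so the cost of an evaluation is
# independent of cohort size.

RATE_FLOOR <- 1e-12

# counts[t, s]: number of patients of stage t observed in state s.
aggregate_counts <- function(coh, space, stmap) {
  states <- cohort_states(coh)
  idx <- match(states, space$states)
  if (anyNA(idx))
    stop("cohort contains unreachable state(s) (e.g. '",
         states[which(is.na(idx))[1]],
         "'); run exclude_unreachable() first")
  stg <- factor(coh$stage, levels = stmap$stage_labels)
  if (anyNA(stg))
    stop("unknown stage label(s): ",
         paste(unique(coh$stage[is.na(stg)]), collapse = ", "))
  tab <- table(stg, factor(idx, levels = seq_along(space$states)))
  matrix(as.integer(tab), nrow = nlevels(stg),
         dimnames = list(stmap$stage_labels, space$states))
}

#' Cohort log-likelihood under given dissemination rates
#'
#' @param coh a \code{metanet_cohort}; every state must be reachable (apply
#'   \code{\link{exclude_unreachable}} first).
#' @param net the \code{site_network}.
#' @param space its \code{state_space}.
#' @param theta named rate vector, values >= 0.
#' @param stmap a \code{stage_time_map} covering the cohort's stage labels.
#' @param on_zero what to do when a patient's state has probability zero
#'   under \code{theta}: return \code{-Inf} (default) or raise an error.
#' @return The log-likelihood (a finite number or \code{-Inf}).
#' @export
log_likelihood <- function(coh, net, space, theta, stmap,
                           on_zero = c("-Inf", "error")) {
  on_zero <- match.arg(on_zero)
  if (!nrow(coh)) stop("empty cohort")
  counts <- aggregate_counts(coh, space, stmap)
  loglik_from_counts(counts, net, space, theta, stmap, on_zero)
}

loglik_from_counts <- function(counts, net, space, theta, stmap,
                               on_zero = "-Inf", struct = NULL) {
  theta <- validate_theta(net, theta)
  Q <- if (is.null(struct)) build_generator(net, space, theta)
       else assemble_generator(struct, theta)
  taus <- stage_time(stmap, rownames(counts))
  ord <- order(taus)
  P <- solve_master_equation(Q, taus[ord])$probs[order(ord), , drop = FALSE]
  used <- counts > 0
  p_used <- P[used]
  if (any(p_used <= 0)) {
    if (on_zero == "error")
      stop("a patient's state has probability 0 under theta")
    return(-Inf)
  }
  sum(counts[used] * log(p_used))
}

#' Fit dissemination rates by maximum likelihood
#'
#' Minimises the negative log-likelihood with Nelder-Mead over log-rates, so
#' positivity is enforced by the parameterisation (rates are floored at
#' \code{1e-12} to keep the likelihood finite when an estimate collapses
#' towards zero). Deterministic given the initial point; with
#' \code{multistart > 1} additional starting points are drawn log-uniformly
#' on [1e-3, 1] under \code{seed} and the best final likelihood wins.
#'
#' @param coh filtered \code{metanet_cohort}.
#' @param net the \code{site_network}.
#' @param stmap a \code{stage_time_map}.
#' @param space optional precomputed \code{state_space}.
#' @param initial_theta named rate vector used as first start; default: every
#'   rate 0.1.
#' @param multistart number of starting points (>= 1).
#' @param seed RNG seed for the extra starts (only used if
#'   \code{multistart > 1}).
#' @param control passed to \code{\link[stats]{optim}}; defaults set
#'   \code{maxit = 2000} and \code{reltol = 1e-10}.
#' @return Object of class \code{metanet_fit}: \code{theta_hat} (named
#'   rates), \code{log_likelihood}, \code{converged}, \code{diagnostics}
#'   (per-start optim results summary), \code{n_patients},
#'   \code{bootstrap_intervals} (\code{NULL} until
#'   \code{\link{parametric_bootstrap}} is run).
#' @export
fit_mle <- function(coh, net, stmap, space = NULL, initial_theta = NULL,
                    multistart = 1, seed = NULL, control = list()) {
  if (!nrow(coh)) stop("empty cohort")
  if (is.null(space)) space <- enumerate_reachable_states(net)
  syms <- rate_symbols(net)
  counts <- aggregate_counts(coh, space, stmap)
  struct <- generator_structure(net, space)
  control <- utils::modifyList(list(maxit = 5000, reltol = 1e-9), control)

  negll <- function(x) {
    theta <- stats::setNames(pmax(exp(x), RATE_FLOOR), syms)
    ll <- loglik_from_counts(counts, net, space, theta, stmap, struct = struct)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  starts <- list(if (is.null(initial_theta)) stats::setNames(rep(0.1, length(syms)), syms)
                 else validate_theta(net, initial_theta))
  if (multistart > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(multistart - 1))
      starts[[k + 1]] <- stats::setNames(
        exp(stats::runif(length(syms), log(1e-3), log(1))), syms)
  }

  runs <- lapply(starts, function(th0) {
    # Nelder-Mead is kept even for 1-parameter networks (base R warns that
    # it is "unreliable" in 1-D, but it is deterministic and adequate here)
    withCallingHandlers(
      stats::optim(log(pmax(th0, RATE_FLOOR)), negll,
                   method = "Nelder-Mead", control = control),
      warning = function(w) {
        if (grepl("Nelder-Mead is unreliable", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  if (!is.finite(best$value) || best$value >= 1e12)
    stop("optimizer failed to find a point of positive likelihood after ",
         multistart, " start(s)")
  theta_hat <- stats::setNames(pmax(exp(best$par), RATE_FLOOR), syms)
  structure(list(theta_hat = theta_hat,
                 log_likelihood = -best$value,
                 converged = best$convergence == 0,
                 diagnostics = list(
                   convergence = vapply(runs, `[[`, numeric(1), "convergence"),
                   value = vals,
                   counts = best$counts),
                 n_patients = nrow(coh),
                 stage_labels = stmap$stage_labels,
                 bootstrap_intervals = NULL),
            class = "metanet_fit")
}

#' @export
print.metanet_fit <- function(x, ...) {
  cat("<metanet_fit> n =", x$n_patients,
      " log-likelihood =", format(x$log_likelihood, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  tab <- data.frame(estimate = signif(x$theta_hat, 3))
  if (!is.null(x$bootstrap_intervals)) {
    tab$lower <- signif(x$bootstrap_intervals[, 1], 3)
    tab$upper <- signif(x$bootstrap_intervals[, 2], 3)
  }
  print(tab)
  invisible(x)
}
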