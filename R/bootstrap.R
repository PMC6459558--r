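# Parametric bootstrap confidence intervals and seed-soil ratios.

#' Parametric bootstrap intervals for fitted dissemination rates
#'
#' For each replicate a synthetic cohort is generated from the fitted model
#' -- every patient keeps their observed stage, and their metastatic state is
#' redrawn from the model distribution at the fitted rates -- and the model
#' is refitted (starting from the original estimate). Per-rate intervals are
#' the empirical quantiles of the replicate estimates; the defaults, the 5
#' and 95 percent quantiles of 100 replicates, form a 90 percent equal-tailed
#' interval.
#'
#' @param fit a converged \code{metanet_fit}.
#' @param coh the (filtered) cohort the fit was obtained from.
#' @param net the \code{site_network}.
#' @param stmap the \code{stage_time_map} used for the fit.
#' @param B number of bootstrap replicates (>= 2), default 100.
#' @param quantiles lower/upper quantile pair, default \code{c(0.05, 0.95)}.
#' @param seed integer seed driving all replicate cohorts.
#' @param space optional precomputed \code{state_space}.
#' @param control optim control for the refits.
#' @return The \code{fit}, with \code{bootstrap_intervals} set to a matrix
#'   (rate symbols x c(lower, upper)) and \code{bootstrap} holding the
#'   replicate estimates, the number of failed/dropped replicates and the
#'   quantile pair.
#' @export
parametric_bootstrap <- function(fit, coh, net, stmap, B = 100,
                                 quantiles = c(0.05, 0.95), seed = 1,
                                 space = NULL, control = list()) {
  stopifnot(inherits(fit, "metanet_fit"))
  if (!fit$converged) stop("bootstrap requires a converged fit")
  if (B < 2) stop("B must be >= 2")
  if (length(quantiles) != 2 || quantiles[1] >= quantiles[2])
    stop("quantiles must be an increasing (lower, upper) pair")
  if (is.null(space)) space <- enumerate_reachable_states(net)
  comp <- table(coh$stage)
  comp <- stats::setNames(as.integer(comp), names(comp))
  stages <- rep(names(comp), times = comp)
  syms <- rate_symbols(net)
  # model distribution over states at each observed stage, under theta_hat
  taus <- stage_time(stmap, names(comp))
  ord <- order(taus)
  Q <- build_generator(net, space, fit$theta_hat)
  dist_by_stage <- solve_master_equation(Q, taus[ord])$probs[order(ord), ,
                                                             drop = FALSE]
  rownames(dist_by_stage) <- names(comp)
  est <- matrix(NA_real_, B, length(syms), dimnames = list(NULL, syms))
  n_failed <- 0L
  for (b in seq_len(B)) {
    # one RNG substream per replicate; states drawn in a single vectorized
    # pass per stage (the per-patient substreams of sample_cohort() are not
    # needed here and would dominate the run time)
    set.seed(patient_seed(seed, b))
    idx <- integer(length(stages))
    for (st in names(comp))
      idx[stages == st] <- sample.int(length(space$states), comp[[st]],
                                      replace = TRUE,
                                      prob = dist_by_stage[st, ])
    df <- data.frame(patient_id = sprintf("B%05d", seq_along(stages)),
                     stage = stages, stringsAsFactors = FALSE)
    boot_coh <- cohort(cbind(df, as.data.frame(space$bits[idx, , drop = FALSE],
                                               row.names = FALSE)),
                       net, provenance = sprintf("bootstrap replicate %d", b))
    refit <- tryCatch(
      fit_mle(boot_coh, net, stmap, space = space,
              initial_theta = fit$theta_hat, control = control),
      error = function(e) NULL)
    if (is.null(refit) || !refit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    est[b, ] <- refit$theta_hat
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  if (!nrow(est)) stop("every bootstrap replicate failed to refit")
  ints <- t(apply(est, 2L, stats::quantile, probs = quantiles, names = FALSE))
  colnames(ints) <- c("lower", "upper")
  fit$bootstrap_intervals <- ints
  fit$bootstrap <- list(estimates = est, B = B, n_failed = n_failed,
                        quantiles = quantiles, seed = seed)
  fit
}

#' Seed-soil ratios: dissemination rate per unit of physical flow
#'
#' A fitted rate into an organ aggregates the physical flow of CTCs towards
#' it with the cells' ability to survive transit and colonise it. Dividing
#' the rate by the organ's relative blood flow isolates the "soil" term --
#' how receptive the organ is per arriving cell.
#'
#' @param theta named rate vector (or a \code{metanet_fit}).
#' @param relative_flows named numeric vector: for each rate symbol of
#'   interest, the relative blood flow (a fraction in (0, 1]) to the organ
#'   that edge feeds.
#' @return Named numeric vector of ratios \code{theta[s] / relative_flows[s]}
#'   (full precision; round to 2 decimals for display).
#' @examples
#' # ovarian fitted rates over relative blood flows to liver, bone, brain
#' seed_soil_ratios(c(phi_2 = 0.092, phi_3 = 0.015, phi_4 = 0.004),
#'                  c(phi_2 = 0.065, phi_3 = 0.05, phi_4 = 0.012))
#' @export
seed_soil_ratios <- function(theta, relative_flows) {
  if (inherits(theta, "metanet_fit")) theta <- theta$theta_hat
  if (any(relative_flows <= 0) || any(relative_flows > 1))
    stop("relative flows must lie in (0, 1]")
  missing <- setdiff(names(relative_flows), names(theta))
  if (length(missing))
    stop("theta is missing symbol(s): ", paste(missing, collapse = ", "))
  theta[names(relative_flows)] / relative_flows
}
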