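# End-to-end pipeline: read -> exclude -> fit -> bootstrap -> summaries.

#' Run the full inference pipeline from a configuration
#'
#' Reads a cohort, removes patients with topologically unreachable states,
#' fits the dissemination rates by maximum likelihood, optionally computes
#' parametric-bootstrap intervals, and writes the numeric artifacts: the fit
#' (JSON), the exclusion report, observed stage fractions and
#' model-predicted marginals (CSV). Outputs carry no timestamps, so a rerun
#' with the same configuration and seed is byte-identical.
#'
#' @param config a named list, or path to a JSON file, with fields:
#'   \describe{
#'     \item{network}{\code{"tongue"}, \code{"ovarian"} or path to a network
#'       JSON document.}
#'     \item{cohort}{path to the cohort CSV.}
#'     \item{stage_map}{\code{"linear"} (default) or
#'       \code{"exponential_growth"}.}
#'     \item{stage_labels}{ordered stage labels; default: sorted unique
#'       stages found in the cohort.}
#'     \item{growth}{optional list with \code{R0}, \code{alpha},
#'       \code{stage_radii} for the exponential map.}
#'     \item{bootstrap}{number of bootstrap replicates B; 0 (default) skips
#'       the bootstrap.}
#'     \item{seed}{integer seed, default 1.}
#'     \item{multistart}{number of optimizer starts, default 1.}
#'     \item{out_dir}{output directory (created if needed); if \code{NULL},
#'       nothing is written.}
#'   }
#' @return Invisibly, a list with \code{fit}, \code{exclusion},
#'   \code{fractions}, \code{marginals}, \code{config}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(stage_map = "linear", bootstrap = 0, seed = 1,
                   multistart = 1, out_dir = NULL, stage_labels = NULL,
                   growth = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$network) || is.null(config$cohort))
    stop("config must name 'network' and 'cohort'")

  net <- load_network(config$network)
  space <- enumerate_reachable_states(net)
  coh <- read_cohort(config$cohort, net, stage_labels = config$stage_labels)
  labels <- config$stage_labels %||% sort(unique(coh$stage))
  growth <- if (!is.null(config$growth))
    do.call(growth_params, config$growth)
  else if (config$stage_map == "exponential_growth") growth_params()
  stmap <- stage_to_time(config$stage_map, labels, growth = growth)

  filt <- exclude_unreachable(coh, space)
  fit <- fit_mle(filt$cohort, net, stmap, space = space,
                 multistart = config$multistart, seed = config$seed)
  if (config$bootstrap > 0)
    fit <- parametric_bootstrap(fit, filt$cohort, net, stmap,
                                B = config$bootstrap, seed = config$seed,
                                space = space)
  fractions <- stage_fractions(filt$cohort, stage_labels = labels)
  marginals <- predict_marginals(fit, net, space, stmap)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fit_json <- list(
      theta_hat = as.list(fit$theta_hat),
      log_likelihood = fit$log_likelihood,
      converged = fit$converged,
      n_patients = fit$n_patients,
      bootstrap_intervals = if (!is.null(fit$bootstrap_intervals))
        apply(fit$bootstrap_intervals, 1L, as.list, simplify = FALSE),
      exclusion = list(n_input = filt$report$n_input,
                       n_excluded = filt$report$n_excluded),
      config = config[c("network", "cohort", "stage_map", "bootstrap",
                        "seed", "multistart")])
    jsonlite::write_json(fit_json, file.path(config$out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    utils::write.csv(filt$report$excluded,
                     file.path(config$out_dir, "excluded.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(fractions),
                     file.path(config$out_dir, "fractions.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(marginals, file.path(config$out_dir, "marginals.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(fit = fit, exclusion = filt$report, fractions = fractions,
                 marginals = marginals, config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
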