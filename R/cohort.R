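# Cohort container and I/O, the skip-metastasis exclusion filter,
# stage-fraction summaries and model-predicted marginals.

#' Construct a patient cohort
#'
#' @param data data frame with columns \code{patient_id}, \code{stage} and
#'   one 0/1 column per network site (matched by name, any order).
#' @param net the \code{site_network} the cohort refers to.
#' @param provenance optional character note (file of origin, generator
#'   settings, ...).
#' @return A data frame of class \code{metanet_cohort} with columns ordered
#'   \code{patient_id}, \code{stage}, then the sites in network order.
#' @export
cohort <- function(data, net, provenance = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("patient_id", "stage", net$sites)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  data <- data[need]
  data$patient_id <- as.character(data$patient_id)
  data$stage <- as.character(data$stage)
  for (s in net$sites) {
    v <- data[[s]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary status in column '%s' at row %d (value '%s')",
                   s, bad[1], as.character(v[bad[1]])))
    data[[s]] <- as.integer(v)
  }
  structure(data, sites = net$sites, provenance = provenance,
            class = c("metanet_cohort", "data.frame"))
}

#' @export
print.metanet_cohort <- function(x, ...) {
  cat("<metanet_cohort> ", nrow(x), " patients, sites: ",
      paste(attr(x, "sites"), collapse = ", "), "\n", sep = "")
  if (!is.null(attr(x, "provenance")))
    cat("  provenance: ", attr(x, "provenance"), "\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# State strings of all patients, in network site order.
cohort_states <- function(coh) {
  sites <- attr(coh, "sites")
  do.call(paste0, coh[sites])
}

#' Read a cohort from a CSV file
#'
#' Expected header: \code{patient_id}, \code{stage}, then one 0/1 column per
#' network site, matched by name in any order. Stage labels are validated
#' against \code{stage_labels} when given.
#'
#' @param path CSV file path.
#' @param net a \code{site_network}.
#' @param stage_labels optional character vector of admissible stage labels.
#' @return A \code{metanet_cohort}.
#' @export
read_cohort <- function(path, net, stage_labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(c("patient_id", "stage", net$sites), names(df))
  if (length(missing))
    stop("cohort file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  for (s in net$sites) {
    v <- df[[s]]
    bad <- which(!(v %in% c("0", "1")))
    if (length(bad))
      stop(sprintf("non-binary status '%s' in column '%s' at data row %d of %s",
                   v[bad[1]], s, bad[1], path))
    df[[s]] <- as.integer(v)
  }
  if (!is.null(stage_labels)) {
    bad <- which(!(df$stage %in% stage_labels))
    if (length(bad))
      stop(sprintf("unknown stage label '%s' at data row %d of %s",
                   df$stage[bad[1]], bad[1], path))
  }
  cohort(df, net, provenance = path)
}

#' Write a cohort to CSV
#'
#' @param coh a \code{metanet_cohort}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(coh, path) {
  utils::write.csv(as.data.frame(coh), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude patients whose metastatic state is topologically unreachable
#'
#' Under the secondary-seeding model a site without a primary edge can only
#' be colonised from a positive upstream site, so e.g. a tongue patient
#' positive at station IV but negative at III (a skip metastasis) has an
#' unreachable state. Such patients cannot contribute a positive likelihood
#' and are removed before fitting.
#'
#' @param coh a \code{metanet_cohort}.
#' @param space the network's \code{state_space}.
#' @return List with \code{cohort} (filtered) and \code{report}, a list of
#'   class \code{exclusion_report} with \code{n_input}, \code{n_excluded},
#'   \code{excluded} (data frame of patient_id, stage, state).
#' @export
exclude_unreachable <- function(coh, space) {
  states <- cohort_states(coh)
  ok <- !is.na(match(states, space$states))
  excl <- data.frame(patient_id = coh$patient_id[!ok],
                     stage = coh$stage[!ok],
                     state = states[!ok],
                     stringsAsFactors = FALSE)
  report <- structure(list(n_input = nrow(coh),
                           n_excluded = sum(!ok),
                           excluded = excl),
                      class = "exclusion_report")
  filtered <- coh[ok, , drop = FALSE]
  attr(filtered, "sites") <- attr(coh, "sites")
  attr(filtered, "provenance") <- attr(coh, "provenance")
  class(filtered) <- class(coh)
  list(cohort = filtered, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d of %d patients excluded (%.1f%%)\n",
              x$n_excluded, x$n_input, 100 * x$n_excluded / max(1, x$n_input)))
  if (x$n_excluded) print(x$excluded)
  invisible(x)
}

#' Observed fraction of positive patients per stage and site
#'
#' For stage t and site i the fraction is n (patients of stage t positive at
#' site i) over N (patients of stage t). This is the empirical overlay that
#' the model-predicted marginals are compared with.
#'
#' @param coh a \code{metanet_cohort}.
#' @param stage_labels optional ordering of stages for the output (defaults
#'   to sorted unique stages present).
#' @return Data frame of class \code{stage_fraction_table} with columns
#'   \code{stage}, \code{site}, \code{n_pos}, \code{N}, \code{fraction};
#'   stages with zero patients get \code{NA} fraction.
#' @export
stage_fractions <- function(coh, stage_labels = NULL) {
  if (!nrow(coh)) stop("empty cohort")
  sites <- attr(coh, "sites")
  if (is.null(stage_labels)) stage_labels <- sort(unique(coh$stage))
  out <- expand.grid(stage = stage_labels, site = sites,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$stage, stage_labels), match(out$site, sites)), ]
  out$n_pos <- mapply(function(st, si) sum(coh[[si]][coh$stage == st]),
                      out$stage, out$site)
  out$N <- vapply(out$stage, function(st) sum(coh$stage == st), integer(1))
  out$fraction <- ifelse(out$N > 0, out$n_pos / out$N, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("stage_fraction_table", "data.frame")
  out
}

#' Model-predicted per-site marginals at one or all stages
#'
#' Solves the master equation under the (fitted) rates at the time mapped to
#' each requested stage and returns the per-site marginal probabilities of
#' metastatic involvement -- the model curves overlaid on the observed stage
#' fractions.
#'
#' @param fit a \code{metanet_fit} from \code{\link{fit_mle}}, or a named
#'   rate vector.
#' @param net the \code{site_network}.
#' @param space its \code{state_space}.
#' @param stmap a \code{stage_time_map}.
#' @param stage a stage label, or \code{NULL} for all stages in the map.
#' @return Named numeric vector (single stage) or a data frame with columns
#'   \code{stage}, \code{site}, \code{probability}.
#' @export
predict_marginals <- function(fit, net, space, stmap, stage = NULL) {
  theta <- if (inherits(fit, "metanet_fit")) fit$theta_hat else fit
  single <- !is.null(stage)
  stages <- if (single) as.character(stage) else stmap$stage_labels
  taus <- stage_time(stmap, stages)
  ord <- order(taus)
  Q <- build_generator(net, space, theta)
  traj <- solve_master_equation(Q, taus[ord])
  marg <- site_marginals(space, traj)[order(ord), , drop = FALSE]
  if (single) return(stats::setNames(marg[1, ], space$sites))
  data.frame(stage = rep(stages, each = length(space$sites)),
             site = rep(space$sites, length(stages)),
             probability = as.vector(t(marg)),
             stringsAsFactors = FALSE)
}
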