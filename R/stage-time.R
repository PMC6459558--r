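# Tumour stage as a proxy for time since initiation.
#
# Only the primary tumour stage is observed at diagnosis, so rates are
# inferred on a stage-derived time scale. Two mappings are supported:
# "linear" assigns consecutive integers 1..K to the ordered stages
# (arbitrary time units; rates are then relative), and
# "exponential_growth" converts a per-stage tumour radius into years since
# initiation assuming exponential volume growth.

#' Growth parameters for the exponential stage-to-time mapping
#'
#' The tumour volume is assumed to grow as V(t) = V0 exp(alpha t); for a
#' spherical tumour the radius then grows as R(t) = R0 exp(alpha t / 3), so
#' the time at which a stage with radius R_i is reached is
#' t_i = 3 log(R_i / R0) / alpha.
#'
#' @param R0 initial radius in cm; default \code{25e-4} (25 micrometres, a
#'   single cell).
#' @param alpha volumetric growth rate per year; default
#'   \code{365 * log(2) / 40} (a 40-day volume doubling time), about 6.33.
#' @param stage_radii increasing numeric vector, radius in cm of a tumour at
#'   each stage; default \code{c(2, 4, 6, 8)} for tongue stages T1-T4.
#' @return A list of class \code{growth_params}.
#' @export
growth_params <- function(R0 = 25e-4, alpha = 365 * log(2) / 40,
                          stage_radii = c(2, 4, 6, 8)) {
  if (R0 <= 0 || alpha <= 0 || any(stage_radii <= 0))
    stop("growth parameters must be positive")
  if (is.unsorted(stage_radii, strictly = TRUE))
    stop("stage radii must be strictly increasing")
  if (any(stage_radii <= R0))
    stop("every stage radius must exceed the initial radius R0")
  structure(list(R0 = R0, alpha = alpha, stage_radii = stage_radii),
            class = "growth_params")
}

#' Map tumour stages to times since initiation
#'
#' @param kind \code{"linear"} (stage k maps to time k, arbitrary units) or
#'   \code{"exponential_growth"} (times in years from \code{growth}).
#' @param stage_labels ordered character vector of stage labels (e.g.
#'   \code{c("T1","T2","T3","T4")}).
#' @param growth a \code{\link{growth_params}} object, required for the
#'   exponential kind; must supply one radius per stage.
#' @return Object of class \code{stage_time_map}: list with \code{kind},
#'   \code{stage_labels} and \code{times} (named numeric, strictly
#'   increasing).
#' @examples
#' stage_to_time("linear", c("T1", "T2", "T3", "T4"))
#' stage_to_time("exponential_growth", c("T1", "T2", "T3", "T4"),
#'               growth = growth_params())
#' @export
stage_to_time <- function(kind = c("linear", "exponential_growth"),
                          stage_labels, growth = NULL) {
  kind <- match.arg(kind)
  stage_labels <- as.character(stage_labels)
  if (anyDuplicated(stage_labels)) stop("stage labels must be unique")
  if (kind == "linear") {
    times <- seq_along(stage_labels)
  } else {
    if (is.null(growth)) growth <- growth_params()
    if (length(growth$stage_radii) != length(stage_labels))
      stop("growth must supply one stage radius per stage label")
    times <- 3 * log(growth$stage_radii / growth$R0) / growth$alpha
  }
  names(times) <- stage_labels
  structure(list(kind = kind, stage_labels = stage_labels,
                 times = times, growth = growth),
            class = "stage_time_map")
}

#' @export
print.stage_time_map <- function(x, ...) {
  cat("<stage_time_map> kind:", x$kind, "\n")
  print(round(x$times, 4))
  invisible(x)
}

#' Look up the time of a stage label
#'
#' @param stmap a \code{stage_time_map}.
#' @param stage character vector of stage labels.
#' @return Numeric times.
#' @export
stage_time <- function(stmap, stage) {
  idx <- match(as.character(stage), stmap$stage_labels)
  if (anyNA(idx))
    stop("unknown stage label(s): ",
         paste(unique(stage[is.na(idx)]), collapse = ", "))
  unname(stmap$times[idx])
}
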