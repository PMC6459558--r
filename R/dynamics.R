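# Master-equation dynamics: dP/dt = Q P with P(0) a point mass on the
# all-negative state.

#' Solve the master equation of the dissemination CTMC
#'
#' Propagates the probability distribution over metastatic states from the
#' initial point mass on the all-negative state to each requested time.
#'
#' The default method \code{"expm"} uses the matrix exponential
#' P(t) = exp(Qt) P(0), exact for this linear system, and advances
#' incrementally between successive requested times (the exponential of each
#' distinct time gap is computed once). Method \code{"euler"} is the
#' first-order Euler forward scheme P <- P + h Q P; between requested output
#' times the iterate (I + hQ)^k P is evaluated by binary matrix powers, which
#' is algebraically the Euler recursion, so even very small steps are cheap.
#' The step is adjusted per interval so that an integer number of steps lands
#' exactly on each output time.
#'
#' @param Q generator matrix from \code{\link{build_generator}}.
#' @param times numeric vector of evaluation times, nonnegative and
#'   nondecreasing.
#' @param method \code{"expm"} (default, accuracy oracle) or \code{"euler"}.
#' @param h Euler step size (same time units as \code{times}); default
#'   \code{1e-6}, small enough that the Euler solution agrees with the matrix
#'   exponential to well under 1e-6 for rates of order one.
#' @param check_conservation if \code{TRUE} (default), verify each
#'   distribution sums to 1 within \code{1e-9}; small negative round-off is
#'   clamped to zero and renormalised, larger deviations are an error (a
#'   deviation beyond round-off indicates a broken generator).
#' @return Object of class \code{prob_trajectory}: list with \code{times} and
#'   \code{probs}, a \code{length(times)} x M matrix (columns named by state
#'   string); row t is the distribution at \code{times[t]}.
#' @export
solve_master_equation <- function(Q, times, method = c("expm", "euler"),
                                  h = 1e-6, check_conservation = TRUE) {
  method <- match.arg(method)
  times <- as.numeric(times)
  if (any(times < 0)) stop("negative evaluation time")
  if (is.unsorted(times)) stop("times must be nondecreasing")
  if (method == "euler" && (!is.finite(h) || h <= 0))
    stop("euler step size must be > 0")
  m <- nrow(Q)
  p <- numeric(m)
  p[1] <- 1  # all-negative state is index 1 by construction
  out <- matrix(0, length(times), m,
                dimnames = list(NULL, colnames(Q)))
  cache <- list()  # propagator per distinct time gap
  t_cur <- 0
  for (k in seq_along(times)) {
    dt <- times[k] - t_cur
    if (dt > 0) {
      key <- sprintf("%.17g", dt)
      if (is.null(cache[[key]])) {
        cache[[key]] <- if (method == "expm") {
          as.matrix(Matrix::expm(Q * dt))
        } else {
          euler_propagator(Q, dt, h)
        }
      }
      p <- as.vector(cache[[key]] %*% p)
      t_cur <- times[k]
    }
    out[k, ] <- p
  }
  if (check_conservation) {
    for (k in seq_along(times)) {
      pk <- out[k, ]
      dev <- max(abs(sum(pk) - 1), -min(pk, 0))
      if (dev > 1e-9)
        stop(sprintf("probability conservation violated at t=%g (deviation %.3g)",
                     times[k], dev))
      pk[pk < 0] <- 0
      out[k, ] <- pk / sum(pk)
    }
  }
  structure(list(times = times, probs = out, method = method),
            class = "prob_trajectory")
}

# (I + h_eff Q)^n for n = round(dt / h) steps, via binary powering.
euler_propagator <- function(Q, dt, h) {
  n <- max(1, round(dt / h))
  h_eff <- dt / n
  A <- diag(nrow(Q)) + h_eff * Q
  P <- diag(nrow(Q))
  while (n > 0) {
    if (n %% 2 == 1) P <- A %*% P
    A <- A %*% A
    n <- n %/% 2
  }
  P
}

#' @export
print.prob_trajectory <- function(x, ...) {
  cat("<prob_trajectory> ", length(x$times), " time points, ",
      ncol(x$probs), " states (method ", x$method, ")\n", sep = "")
  print(utils::head(cbind(time = x$times, x$probs)), ...)
  invisible(x)
}

#' Per-site marginal probabilities of metastatic involvement
#'
#' The probability that site v is positive is the sum of the probabilities of
#' all states whose binary string has a 1 at position v. Membership is
#' evaluated against the state space, never against hard-coded indices.
#'
#' @param space a \code{state_space}.
#' @param distribution probability vector over the state space (length M), or
#'   a \code{prob_trajectory} (marginals are then computed for every row).
#' @return Named numeric vector of length N (or a matrix, times x sites).
#' @export
site_marginals <- function(space, distribution) {
  if (inherits(distribution, "prob_trajectory")) {
    out <- distribution$probs %*% space$bits
    rownames(out) <- NULL
    return(out)
  }
  if (length(distribution) != length(space$states))
    stop("distribution length ", length(distribution),
         " does not match state space size ", length(space$states))
  stats::setNames(as.vector(distribution %*% space$bits), space$sites)
}
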