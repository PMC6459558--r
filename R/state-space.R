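# Reachable metastatic states and the CTMC generator.
#
# A metastatic state is a binary vector over the network's sites (0 = site
# free of metastases, 1 = colonised). Progression is monotone: sites turn
# positive one at a time and never revert. A negative site v can activate
# only if it is fed by the primary tumour (a lambda edge) or by some
# currently positive upstream site (a phi edge), so not all 2^N bit vectors
# are attainable ("skip metastases" are excluded by topology).

state_to_string <- function(bits) paste(bits, collapse = "")

#' Activation rate of each negative site in a given state
#'
#' The rate at which site v turns positive equals the sum of flow rates over
#' all its positive upstream feeders, the primary tumour counting as always
#' positive for lambda edges. Sites already positive get rate 0.
#'
#' @param net a \code{site_network}.
#' @param bits integer 0/1 vector over \code{net$sites}.
#' @param theta named numeric vector of rates (one per rate symbol); if
#'   \code{NULL}, every rate is taken as 1 (useful for reachability, where
#'   only positivity matters).
#' @return Numeric vector, one activation rate per site.
#' @export
activation_rates <- function(net, bits, theta = NULL) {
  val <- function(sym) if (is.null(theta)) 1 else theta[[sym]]
  r <- numeric(length(net$sites))
  names(r) <- net$sites
  for (v in net$sites) {
    if (bits[[match(v, net$sites)]] == 1L) next
    rate <- 0
    if (v %in% names(net$primary_edges))
      rate <- rate + val(net$primary_edges[[v]])
    se <- net$secondary_edges
    if (nrow(se)) {
      feeders <- se[se$to == v, , drop = FALSE]
      for (k in seq_len(nrow(feeders)))
        if (bits[[match(feeders$from[k], net$sites)]] == 1L)
          rate <- rate + val(feeders$symbol[k])
    }
    r[[v]] <- rate
  }
  r
}

#' Enumerate the reachable metastatic states of a network
#'
#' Breadth-first search from the all-negative state under single-site
#' activations. States are ordered by number of positive sites (level) and
#' lexicographically by binary string within a level, so indices are
#' deterministic; the all-negative state always has index 1.
#'
#' @param net a \code{site_network}.
#' @return An object of class \code{state_space}: list with \code{states}
#'   (character vector of binary strings), \code{bits} (M x N 0/1 integer
#'   matrix, rows in state order), \code{sites}.
#' @export
enumerate_reachable_states <- function(net) {
  n <- length(net$sites)
  start <- integer(n)
  seen <- new.env(parent = emptyenv())
  assign(state_to_string(start), TRUE, envir = seen)
  frontier <- list(start)
  all_bits <- list(start)
  while (length(frontier)) {
    nxt <- list()
    for (bits in frontier) {
      rates <- activation_rates(net, bits)
      for (v in which(rates > 0)) {
        child <- bits
        child[v] <- 1L
        key <- state_to_string(child)
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- child
          all_bits[[length(all_bits) + 1L]] <- child
        }
      }
    }
    frontier <- nxt
  }
  bits <- do.call(rbind, all_bits)
  strings <- apply(bits, 1L, state_to_string)
  ord <- order(rowSums(bits), strings)
  bits <- bits[ord, , drop = FALSE]
  strings <- strings[ord]
  dimnames(bits) <- list(strings, net$sites)
  structure(list(states = strings, bits = bits, sites = net$sites),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", length(x$states), " reachable states over sites ",
      paste(x$sites, collapse = ","), "\n", sep = "")
  cat(" ", paste(sprintf("%d:%s", seq_along(x$states), x$states),
                 collapse = "  "), "\n")
  invisible(x)
}

#' Index of a state string in a state space
#'
#' @param space a \code{state_space}.
#' @param state binary string or 0/1 vector.
#' @return Integer index, or \code{NA} if the state is not reachable.
#' @export
state_index <- function(space, state) {
  if (!is.character(state)) state <- state_to_string(as.integer(state))
  match(state, space$states)
}

#' Is a metastatic state topologically reachable?
#'
#' A state fails this test exactly when it exhibits a skip metastasis: some
#' positive site has neither a primary edge nor a positive upstream feeder
#' chain (e.g. tongue station IV positive with station III negative).
#'
#' @param space a \code{state_space}.
#' @param state binary string or 0/1 vector of length N.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_reachable <- function(space, state) {
  if (!is.character(state)) state <- state_to_string(as.integer(state))
  if (nchar(state) != length(space$sites))
    stop("state length ", nchar(state), " does not match network size ",
         length(space$sites))
  !is.na(match(state, space$states))
}

#' Build the CTMC generator matrix
#'
#' Column-generator convention: \code{Q[i, j]} is the rate of moving from
#' state j to state i, so the master equation reads dP/dt = Q P and every
#' column sums to zero. An off-diagonal entry is nonzero only between states
#' at Hamming distance one, the successor having one more positive site; its
#' value is the activation rate of the flipped site in the source state
#' (lambda of the primary edge, if any, plus the phi of every positive
#' feeder). The all-positive state is absorbing.
#'
#' @param net a \code{site_network}.
#' @param space the \code{state_space} from \code{enumerate_reachable_states}.
#' @param theta named numeric vector covering all of \code{rate_symbols(net)},
#'   values >= 0.
#' @return M x M numeric matrix with state strings as dimnames.
#' @export
build_generator <- function(net, space, theta) {
  theta <- validate_theta(net, theta)
  assemble_generator(generator_structure(net, space), theta)
}

# Symbolic transition structure of the CTMC: for every single-site
# activation j -> i, a 0/1 row over rate symbols saying which lambda/phi
# terms add up to that transition's rate. Computed once per (net, space);
# assembling Q for a concrete theta is then a vectorized fill, which keeps
# repeated likelihood evaluations cheap.
generator_structure <- function(net, space) {
  syms <- rate_symbols(net)
  m <- length(space$states)
  ii <- integer(0); jj <- integer(0)
  coef <- list()
  for (j in seq_len(m)) {
    bits <- space$bits[j, ]
    for (v in seq_along(net$sites)) {
      if (bits[v] == 1L) next
      site <- net$sites[v]
      terms <- character(0)
      if (site %in% names(net$primary_edges))
        terms <- net$primary_edges[[site]]
      se <- net$secondary_edges
      if (nrow(se)) {
        feeders <- se[se$to == site & bits[match(se$from, net$sites)] == 1L, ]
        terms <- c(terms, feeders$symbol)
      }
      if (!length(terms)) next
      child <- bits
      child[v] <- 1L
      ii <- c(ii, state_index(space, child)); jj <- c(jj, j)
      coef[[length(coef) + 1L]] <- as.numeric(syms %in% terms)
    }
  }
  list(i = ii, j = jj, coef = do.call(rbind, coef), syms = syms,
       m = m, states = space$states)
}

assemble_generator <- function(struct, theta) {
  rates <- as.vector(struct$coef %*% theta[struct$syms])
  Q <- matrix(0, struct$m, struct$m,
              dimnames = list(struct$states, struct$states))
  Q[cbind(struct$i, struct$j)] <- rates
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Validate a rate-parameter vector against a network
#'
#' @param net a \code{site_network}.
#' @param theta named numeric vector.
#' @return \code{theta}, reordered to \code{rate_symbols(net)}.
#' @export
validate_theta <- function(net, theta) {
  syms <- rate_symbols(net)
  missing <- setdiff(syms, names(theta))
  if (length(missing))
    stop("theta is missing rate symbol(s): ", paste(missing, collapse = ", "))
  theta <- theta[syms]
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("all rates must be finite and >= 0")
  theta
}
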