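#' Construct an anatomical dissemination network
#'
#' A dissemination network describes how circulating tumour cells (CTCs) can
#' travel from the primary tumour and between metastatic sites. Sites are
#' lymph node stations or organs; each directed edge carries a named rate
#' symbol. Edges from the (implicit) primary tumour are the \eqn{\lambda}
#' rates, edges between sites (secondary seeding) are the \eqn{\phi} rates.
#'
#' @param sites character vector of unique site identifiers, in the order
#'   used for binary state strings.
#' @param primary_edges named character vector mapping a site to the rate
#'   symbol of its edge from the primary tumour.
#' @param secondary_edges data frame with columns \code{from}, \code{to},
#'   \code{symbol}: directed site-to-site edges and their rate symbols. May
#'   be \code{NULL} or empty.
#' @return An object of class \code{site_network}.
#' @examples
#' net <- site_network(c("A", "B"),
#'                     primary_edges = c(A = "lambda_A"),
#'                     secondary_edges = data.frame(from = "A", to = "B",
#'                                                  symbol = "phi_AB"))
#' @export
site_network <- function(sites, primary_edges, secondary_edges = NULL) {
  sites <- as.character(sites)
  if (anyDuplicated(sites))
    stop("site identifiers must be unique")
  if (length(primary_edges) == 0L)
    stop("at least one primary edge is required (no site is ever seeded otherwise)")
  primary_edges <- vapply(primary_edges, as.character, character(1))
  bad <- setdiff(names(primary_edges), sites)
  if (length(bad))
    stop("primary edge names unknown site(s): ", paste(bad, collapse = ", "))
  if (is.null(secondary_edges) || NROW(secondary_edges) == 0L) {
    secondary_edges <- data.frame(from = character(), to = character(),
                                  symbol = character(), stringsAsFactors = FALSE)
  } else {
    secondary_edges <- as.data.frame(secondary_edges, stringsAsFactors = FALSE)
    need <- c("from", "to", "symbol")
    if (!all(need %in% names(secondary_edges)))
      stop("secondary_edges must have columns from, to, symbol")
    secondary_edges <- secondary_edges[need]
    secondary_edges[] <- lapply(secondary_edges, as.character)
    bad <- setdiff(c(secondary_edges$from, secondary_edges$to), sites)
    if (length(bad))
      stop("secondary edge references unknown site(s): ",
           paste(unique(bad), collapse = ", "))
    if (any(secondary_edges$from == secondary_edges$to))
      stop("self-edges are not allowed")
    if (anyDuplicated(paste(secondary_edges$from, secondary_edges$to)))
      stop("duplicate secondary edge")
  }
  syms <- c(unname(primary_edges), secondary_edges$symbol)
  if (anyDuplicated(syms))
    stop("rate symbols must be unique per edge (tying is not supported): ",
         paste(syms[duplicated(syms)], collapse = ", "))
  structure(list(sites = sites,
                 primary_edges = primary_edges,
                 secondary_edges = secondary_edges),
            class = "site_network")
}

#' @export
print.site_network <- function(x, ...) {
  cat("<site_network> ", length(x$sites), " sites: ",
      paste(x$sites, collapse = ", "), "\n", sep = "")
  cat("  primary edges:   ",
      paste(sprintf("primary->%s [%s]", names(x$primary_edges), x$primary_edges),
            collapse = ", "), "\n", sep = "")
  if (nrow(x$secondary_edges))
    cat("  secondary edges: ",
        paste(sprintf("%s->%s [%s]", x$secondary_edges$from,
                      x$secondary_edges$to, x$secondary_edges$symbol),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rate symbols used by a network
#'
#' @param net a \code{site_network}.
#' @return Character vector of all rate symbols (primary first, then
#'   secondary, in edge order).
#' @export
rate_symbols <- function(net) {
  stopifnot(inherits(net, "site_network"))
  c(unname(net$primary_edges), net$secondary_edges$symbol)
}

#' Load a dissemination network from a JSON document or built-in fixture
#'
#' The document has keys \code{sites} (ordered list), \code{primary_edges}
#' (map site -> rate symbol) and \code{secondary_edges} (list of objects with
#' \code{from}, \code{to}, \code{symbol}). The names \code{"tongue"} and
#' \code{"ovarian"} resolve to the built-in fixtures: the lymphatic network of
#' oral tongue cancer (stations I-IV) and the lymphatic/haematogenous network
#' of ovarian cancer (regional LN, lung, liver, bone, brain).
#'
#' @param spec path to a JSON file, or \code{"tongue"} / \code{"ovarian"}.
#' @return A validated \code{site_network}.
#' @export
load_network <- function(spec) {
  if (spec == "tongue") return(tongue_network())
  if (spec == "ovarian") return(ovarian_network())
  if (!file.exists(spec))
    stop("network spec not found (not a file nor a built-in fixture): ", spec)
  doc <- jsonlite::read_json(spec, simplifyVector = TRUE)
  if (is.null(doc$sites) || is.null(doc$primary_edges))
    stop("network document must contain 'sites' and 'primary_edges'")
  pe <- unlist(doc$primary_edges)
  se <- doc$secondary_edges
  if (!is.null(se) && !is.data.frame(se)) se <- as.data.frame(se)
  site_network(doc$sites, pe, se)
}

#' Tongue cancer lymphatic network (built-in fixture)
#'
#' Four cervical lymph node stations I-IV. The primary tumour of the oral
#' tongue drains into stations I, II and III (rates \code{lambda_I},
#' \code{lambda_II}, \code{lambda_III}); lymph then flows down the chain
#' I -> II -> III -> IV (rates \code{phi_I}, \code{phi_II}, \code{phi_III}),
#' so station IV can only be seeded by secondary seeding from station III.
#'
#' @return A \code{site_network} with sites \code{c("I","II","III","IV")}.
#' @export
tongue_network <- function() {
  site_network(
    sites = c("I", "II", "III", "IV"),
    primary_edges = c(I = "lambda_I", II = "lambda_II", III = "lambda_III"),
    secondary_edges = data.frame(
      from = c("I", "II", "III"),
      to = c("II", "III", "IV"),
      symbol = c("phi_I", "phi_II", "phi_III"),
      stringsAsFactors = FALSE))
}

#' Ovarian cancer dissemination network (built-in fixture)
#'
#' Five sites: regional lymph nodes (LN), lung, liver, bone and brain. The
#' primary tumour seeds the regional LNs (\code{lambda_1}) and, via the venous
#' circulation, the lung (\code{lambda_2}). LN metastases can seed the lung
#' (\code{phi_1}); lung metastases shed CTCs into the arterial circulation and
#' can seed liver, bone and brain (\code{phi_2}, \code{phi_3}, \code{phi_4}).
#' Transcoelomic (peritoneal) dissemination is not represented.
#'
#' @return A \code{site_network} with sites
#'   \code{c("LN","lung","liver","bone","brain")}.
#' @export
ovarian_network <- function() {
  site_network(
    sites = c("LN", "lung", "liver", "bone", "brain"),
    primary_edges = c(LN = "lambda_1", lung = "lambda_2"),
    secondary_edges = data.frame(
      from = c("LN", "lung", "lung", "lung"),
      to = c("lung", "liver", "bone", "brain"),
      symbol = c("phi_1", "phi_2", "phi_3", "phi_4"),
      stringsAsFactors = FALSE))
}
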