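test_that("built-in fixtures match their JSON documents and validate", {
  for (name in c("tongue", "ovarian")) {
    built <- load_network(name)
    from_json <- load_network(system.file(
      "extdata", paste0(name, "_network.json"), package = "metanet"))
    expect_identical(built$sites, from_json$sites)
    expect_identical(built$primary_edges, from_json$primary_edges)
    expect_identical(built$secondary_edges, from_json$secondary_edges)
  }
  tongue <- load_network("tongue")
  expect_identical(tongue$sites, c("I", "II", "III", "IV"))
  expect_identical(unname(tongue$primary_edges[c("I", "II", "III")]),
                   c("lambda_I", "lambda_II", "lambda_III"))
  ovarian <- load_network("ovarian")
  expect_identical(names(ovarian$primary_edges), c("LN", "lung"))
  expect_identical(ovarian$secondary_edges$from, c("LN", "lung", "lung", "lung"))
})

test_that("network validation rejects malformed specifications", {
  expect_error(site_network(c("A", "A"), c(A = "l")), "unique")
  expect_error(site_network(c("A", "B"), character(0)), "primary edge")
  expect_error(site_network("A", c(B = "l")), "unknown site")
  expect_error(site_network(c("A", "B"), c(A = "l"),
                            data.frame(from = "A", to = "C", symbol = "p")),
               "unknown site")
  expect_error(site_network(c("A", "B"), c(A = "l"),
                            data.frame(from = "A", to = "A", symbol = "p")),
               "self-edge")
  expect_error(site_network(c("A", "B"), c(A = "l", B = "l")), "unique")
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(sites = c("A", "B"),
                            primary_edges = list(A = "l"),
                            secondary_edges = data.frame(
                              from = "A", to = "Z", symbol = "p")),
                       bad, auto_unbox = TRUE)
  expect_error(load_network(bad), "unknown site")
})

test_that("reachable-state enumeration matches counts and brute force", {
  tongue <- tongue_network()
  ovarian <- ovarian_network()
  sp_t <- enumerate_reachable_states(tongue)
  sp_o <- enumerate_reachable_states(ovarian)
  expect_length(sp_t$states, 12)
  expect_length(sp_o$states, 18)
  expect_length(enumerate_reachable_states(one_site_network())$states, 2)
  # station IV without III is a skip metastasis, pruned by topology
  expect_false("0001" %in% sp_t$states)
  # exhaustive 2^N scan with the independent peeling predicate
  expect_setequal(sp_t$states, brute_reachable_set(tongue))
  expect_setequal(sp_o$states, brute_reachable_set(ovarian))
  # a deeper random-ish topology: 6 sites, branching secondary chains
  net6 <- site_network(
    letters[1:6], primary_edges = c(a = "l1", b = "l2"),
    secondary_edges = data.frame(
      from = c("a", "b", "c", "c", "e"),
      to = c("c", "c", "d", "e", "f"),
      symbol = paste0("p", 1:5)))
  expect_setequal(enumerate_reachable_states(net6)$states,
                  brute_reachable_set(net6))
  # ordering contract: all-negative first, then by level, lexicographic
  lv <- rowSums(sp_t$bits)
  expect_identical(sp_t$states[1], "0000")
  expect_true(all(diff(lv) >= 0))
  expect_false(is.unsorted(sp_t$states[lv == 2]))
})

test_that("is_reachable answers the membership question", {
  sp_t <- enumerate_reachable_states(tongue_network())
  sp_o <- enumerate_reachable_states(ovarian_network())
  expect_true(is_reachable(sp_t, "1110"))
  expect_false(is_reachable(sp_t, "0001"))
  expect_false(is_reachable(sp_o, "00100"))  # liver without lung
  expect_true(is_reachable(sp_o, "01100"))
  expect_error(is_reachable(sp_t, "11100"), "length")
  expect_true(is_reachable(sp_t, c(1L, 1L, 1L, 0L)))
})

test_that("generator matches hand enumeration on the two-site chain", {
  net <- chain_network()
  sp <- enumerate_reachable_states(net)
  # only 00 -> 10 -> 11 are attainable: B has no primary edge
  expect_identical(sp$states, c("00", "10", "11"))
  Q <- build_generator(net, sp, c(lambda = 0.3, phi = 0.8))
  Q_hand <- matrix(c(-0.3, 0, 0,
                     0.3, -0.8, 0,
                     0, 0.8, 0),
                   3, 3, byrow = TRUE,
                   dimnames = list(sp$states, sp$states))
  expect_equal(Q, Q_hand)
})

test_that("tongue generator reproduces the transition-diagram rates", {
  net <- tongue_network()
  sp <- enumerate_reachable_states(net)
  th <- tongue_truth_theta()
  Q <- build_generator(net, sp, th)
  # seeding from the all-negative state comes only from the primary
  expect_equal(Q["1000", "0000"], th[["lambda_I"]])
  expect_equal(Q["0100", "0000"], th[["lambda_II"]])
  # station II activates from the primary plus positive station I
  expect_equal(Q["1100", "1000"], th[["lambda_II"]] + th[["phi_I"]])
  # full hand-built matrix agreement
  expect_equal(Q, tongue_hand_generator(th)[sp$states, sp$states])
})

test_that("generator columns conserve probability and steps are monotone", {
  nets <- list(tongue_network(), ovarian_network(), chain_network())
  set.seed(7)
  for (net in nets) {
    sp <- enumerate_reachable_states(net)
    for (rep in 1:5) {
      Q <- build_generator(net, sp, random_theta(net))
      expect_lt(max(abs(colSums(Q))), 1e-12)
      off <- Q - diag(diag(Q))
      expect_true(all(off >= 0))
      hit <- which(off > 0, arr.ind = TRUE)
      ham <- abs(sp$bits[hit[, 1], , drop = FALSE] -
                 sp$bits[hit[, 2], , drop = FALSE])
      expect_true(all(rowSums(ham) == 1))
      expect_true(all(rowSums(sp$bits[hit[, 1], , drop = FALSE]) ==
                      rowSums(sp$bits[hit[, 2], , drop = FALSE]) + 1))
    }
  }
})

test_that("permuting site order yields an isomorphic state space and generator", {
  th <- tongue_truth_theta()
  net1 <- tongue_network()
  perm <- c("III", "I", "IV", "II")
  net2 <- site_network(perm,
                       primary_edges = net1$primary_edges,
                       secondary_edges = net1$secondary_edges)
  sp1 <- enumerate_reachable_states(net1)
  sp2 <- enumerate_reachable_states(net2)
  expect_length(sp2$states, length(sp1$states))
  # map each state of net1 into net2's site order, then compare entries
  remap <- vapply(sp1$states, function(s) {
    bits <- as.integer(strsplit(s, "")[[1]])
    paste(bits[match(perm, net1$sites)], collapse = "")
  }, character(1))
  expect_setequal(remap, sp2$states)
  Q1 <- build_generator(net1, sp1, th)
  Q2 <- build_generator(net2, sp2, th)
  expect_equal(unname(Q2[remap, remap]), unname(Q1))
})

test_that("theta validation catches missing symbols and bad values", {
  net <- tongue_network()
  sp <- enumerate_reachable_states(net)
  th <- tongue_truth_theta()
  expect_error(build_generator(net, sp, th[-2]), "lambda_II")
  th_bad <- th; th_bad[1] <- -0.1
  expect_error(build_generator(net, sp, th_bad), ">= 0")
})
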