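test_that("fragments extract contiguous windows with renumbering", {
  snap <- mk_snapshot(rep(200, 29))
  fr <- extract_fragment(snap, 11, 9)
  rt <- residue_table(fr)
  expect_equal(rt$resno, 1:9)
  expect_equal(rt$resno_author, 11:19)
  whole <- extract_fragment(snap, 1, 29)
  expect_equal(nrow(residue_table(whole)), 29L)
  expect_error(extract_fragment(snap, 25, 9), "out of range")
  expect_error(extract_fragment(snap, 0, 5), "out of range")
})

test_that("backbone connectivity is verified bond by bond", {
  fr <- extract_fragment(mk_snapshot(rep(200, 6)), 2, 4)
  expect_true(check_connectivity(fr))
  # introduce a chain break by translating the second half
  broken <- fr
  half <- broken$atoms$resno > 2
  broken$xyz[half, 1] <- broken$xyz[half, 1] + 10
  expect_false(check_connectivity(broken))
  # per-bond oracle on randomized fragments
  set.seed(71)
  for (rep in 1:5) {
    f2 <- extract_fragment(mk_snapshot(random_chis(6), noise = 0.4), 1, 6)
    res <- residue_table(f2)$resno
    d <- vapply(seq_len(5), function(k)
      proton_distance(f2, res[k], "O3'", res[k + 1], "P"), 0)
    expect_identical(check_connectivity(f2, bond_max = 2.0), all(d <= 2.0))
  }
})

test_that("the prefilter threshold is the ensemble radius plus the cutoff", {
  set.seed(72)
  frags <- lapply(1:4, function(i)
    extract_fragment(mk_snapshot(random_chis(7), noise = 0.1), 2, 5))
  cen <- frags[[1]]
  expect_equal(prefilter_threshold(cen, list(cen)), 1.0)
  thr <- prefilter_threshold(cen, frags, base_cutoff = 1.0)
  brute <- max(vapply(frags, function(f) ermsd(cen, f), 0))
  expect_equal(thr, 1.0 + brute)
})

test_that("a planted library is searched exactly", {
  set.seed(73)
  # query: a 5-residue syn-pattern fragment
  q_chis <- c(200, 70, 200, 200, 200)
  query <- mk_snapshot(q_chis, sequence = rep(c("G", "U"), length.out = 5))
  # library entry 1: the query embedded at positions 3..7 of a 10-mer
  lib_chis <- c(300, 250, q_chis, 160, 250, 300)
  hit_snap <- mk_snapshot(lib_chis, sequence = rep(c("G", "U"),
                                                   length.out = 10))
  # library entry 2: pure decoy, different chi everywhere
  decoy <- mk_snapshot(rep(300, 10), sequence = rep(c("G", "U"),
                                                    length.out = 10))
  library <- list(planted = mk_ensemble(list(hit_snap)),
                  decoy = mk_ensemble(list(decoy)))
  cand <- search_library(query, library, threshold = 1.0)
  expect_true(nrow(cand$meta) >= 1L)
  top <- cand$meta[which.min(cand$meta$ermsd_centroid), ]
  expect_equal(top$structure, "planted")
  expect_equal(top$start, 3L)
  # an identical copy scores (near) zero
  self_lib <- list(self = mk_ensemble(list(query)))
  self_hit <- search_library(query, self_lib, threshold = 1.0)
  expect_equal(self_hit$meta$ermsd_centroid, 0, tolerance = 1e-12)
  # empty library
  empty <- search_library(query, list(), threshold = 1.0)
  expect_equal(nrow(empty$meta), 0L)
})

test_that("prefilter plus refinement equals the exhaustive all-pairs scan", {
  set.seed(74)
  n_res <- 8; L <- 5
  toy <- generate_toy_ensemble(n_res, list(
    state_spec("A", c(200, 200, 70, 200, 200, 200, 200, 200), 0.6),
    state_spec("B", c(200, 200, 200, 70, 200, 200, 200, 200), 0.4)),
    12, seed = 74)
  frags <- fragment_ensemble(toy$ensemble, 2, L)
  cache <- ermsd_matrix(frags)
  cen <- frags[[centroid_index(cache)]]
  # library with near-copies of both states plus decoys
  mk_entry <- function(chis) mk_ensemble(list(
    mk_snapshot(chis, sequence = rep(c("G", "U"), length.out = length(chis)),
                noise = 0.1)))
  library <- list(
    e1 = mk_entry(c(250, 200, 200, 70, 200, 200, 250, 300)),
    e2 = mk_entry(c(300, 200, 70, 200, 200, 200, 300, 160)),
    e3 = mk_entry(rep(300, 8)))
  thr <- prefilter_threshold(cen, frags, base_cutoff = 1.0)
  hits <- refine_matches(search_library(cen, library, thr), frags,
                         cutoff = 1.0)
  # oracle: scan every window of every entry against every fragment
  oracle <- list()
  for (nm in names(library)) {
    snap <- get_snapshot(library[[nm]], 1)
    for (s in 1:(8 - L + 1)) {
      fr <- extract_fragment(snap, s, L)
      if (!check_connectivity(fr)) next
      e <- vapply(frags, function(f) ermsd(fr, f), 0)
      if (any(e < 1.0))
        oracle[[paste(nm, s)]] <- c(n = sum(e < 1.0), min = min(e))
    }
  }
  got_keys <- paste(hits$structure, hits$start)
  expect_setequal(got_keys, names(oracle))
  for (k in seq_len(nrow(hits))) {
    o <- oracle[[got_keys[k]]]
    expect_equal(hits$n_matching_snapshots[k], as.integer(o["n"]))
    expect_equal(hits$min_ermsd[k], unname(o["min"]))
  }
})

test_that("refinement drops candidates at or beyond the cutoff", {
  set.seed(75)
  fragA <- extract_fragment(mk_snapshot(random_chis(6), noise = 0.1), 1, 5)
  fragB <- extract_fragment(mk_snapshot(random_chis(6), noise = 0.1), 1, 5)
  d <- ermsd(fragA, fragB)
  cand <- structure(list(meta = data.frame(structure = "x", model = 1L,
                                           chain = "A", start = 1L,
                                           start_author = 1L,
                                           ermsd_centroid = d,
                                           stringsAsFactors = FALSE),
                         fragments = list(fragA)),
                    class = "motif_candidates")
  # strict inequality: cutoff exactly at the distance drops the pair
  expect_equal(nrow(refine_matches(cand, list(fragB), cutoff = d)), 0L)
  kept <- refine_matches(cand, list(fragB), cutoff = d + 1e-9)
  expect_equal(nrow(kept), 1L)
  # identical candidate retained at distance zero
  self <- refine_matches(cand, list(fragA), cutoff = 1.0)
  expect_equal(self$min_ermsd, 0)
})

test_that("the chi filter keeps exact bitstring matches only", {
  snapA <- mk_snapshot(c(200, 70, 200, 200))
  snapB <- mk_snapshot(c(200, 70, 200, 70))
  mk_match <- function(snap, id) {
    fr <- extract_fragment(snap, 1, 4)
    structure(list(meta = data.frame(structure = id, model = 1L, chain = "A",
                                     start = 1L, start_author = 1L,
                                     ermsd_centroid = 0,
                                     stringsAsFactors = FALSE),
                   fragments = list(fr)), class = "motif_candidates")
  }
  frags <- list(extract_fragment(snapA, 1, 4))
  m <- rbind(refine_matches(mk_match(snapA, "same"), frags, cutoff = 10),
             refine_matches(mk_match(snapB, "diff"), frags, cutoff = 10))
  attr(m, "pairs") <- data.frame()
  attr(m, "fragments") <- list(extract_fragment(snapA, 1, 4),
                               extract_fragment(snapB, 1, 4))
  class(m) <- c("motif_matches", class(m))
  kept <- filter_chi(m, chi_conformation(snapA))
  expect_equal(kept$structure, "same")
  # componentwise equality oracle
  expect_identical(m$chi == chi_conformation(snapA), c(TRUE, FALSE))
})
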