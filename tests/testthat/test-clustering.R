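test_that("pre-clusters partition by exact bitstring with ordered fractions", {
  pc <- precluster(c("00", "00", "00"))
  expect_length(pc, 1L)
  expect_equal(pc[[1]]$fraction, 1.0)
  pc2 <- precluster(c("00", "01", "00"))
  expect_length(pc2, 2L)
  expect_equal(pc2[[1]]$bits, "00")
  expect_equal(pc2[[1]]$fraction, 2 / 3)
  expect_equal(pc2[[2]]$fraction, 1 / 3)
  set.seed(51)
  bits <- sample(c("000", "010", "110"), 30, replace = TRUE)
  w <- runif(30)
  pc3 <- precluster(bits, w)
  # grouping oracle
  oracle <- split(seq_along(bits), bits)
  expect_setequal(vapply(pc3, `[[`, "", "bits"), names(oracle))
  for (g in pc3) expect_setequal(g$members, oracle[[g$bits]])
  expect_equal(sum(vapply(pc3, `[[`, 0, "fraction")), 1.0)
})

test_that("the neighbor matrix thresholds strictly at the cutoff", {
  snap <- mk_snapshot(rep(200, 4))
  cache <- ermsd_matrix(mk_ensemble(list(snap, snap, snap)))
  expect_equal(neighbor_matrix(cache), matrix(1L, 3, 3))
  # exact boundary: a fabricated cache with a pair at exactly 0.7
  fake <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  class(fake) <- c("ermsd_cache", class(fake))
  M <- neighbor_matrix(fake)
  expect_equal(M, matrix(c(1L, 0L, 0L, 1L), 2, 2))
  set.seed(52)
  vals <- matrix(runif(25, 0, 1.5), 5, 5)
  vals <- (vals + t(vals)) / 2; diag(vals) <- 0
  class(vals) <- c("ermsd_cache", class(vals))
  M2 <- neighbor_matrix(vals, cutoff = 0.7)
  for (i in 1:5) for (j in 1:5)
    expect_identical(M2[i, j], if (i == j) 1L else as.integer(vals[i, j] < 0.7))
})

test_that("max-weight cliques match exhaustive enumeration on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    adj <- matrix(rbinom(n * n, 1, 0.5), n, n)
    adj <- (adj + t(adj)) > 0; diag(adj) <- TRUE
    w <- runif(n)
    got <- max_weight_clique(adj, w)
    oracle <- oracle_max_weight_cliques(adj * 1L, w)
    expect_equal(sum(w[got]), oracle$weight, tolerance = 1e-9)
    expect_identical(got, lex_min_set(oracle$sets))
  }
})

test_that("clique clustering handles complete and disconnected graphs", {
  n <- 5
  complete <- matrix(1L, n, n)
  cl <- max_clique_clustering(complete, rep(1, n))
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$members, 1:5)
  two <- matrix(0L, 4, 4); two[1:2, 1:2] <- 1L; two[3:4, 3:4] <- 1L
  cl2 <- max_clique_clustering(two, c(1, 1, 2, 2))
  expect_length(cl2, 2L)
  expect_identical(cl2[[1]]$members, 3:4)  # heavier clique extracted first
  expect_identical(cl2[[2]]$members, 1:2)
})

test_that("equal-weight ties resolve to the lexicographically smallest set", {
  # two disjoint maximal cliques of equal weight
  adj <- matrix(0L, 4, 4); adj[1, 3] <- adj[3, 1] <- 1L
  adj[2, 4] <- adj[4, 2] <- 1L; diag(adj) <- 1L
  expect_identical(max_weight_clique(adj, rep(1, 4)), c(1L, 3L))
})

test_that("zero-weight members become zero-population singletons", {
  adj <- matrix(1L, 3, 3)
  cl <- max_clique_clustering(adj, rep(0, 3))
  expect_length(cl, 3L)
  expect_equal(vapply(cl, `[[`, 0, "weight"), rep(0, 3))
})

test_that("greedy and exact clique search agree on easy graphs", {
  adj <- matrix(1L, 6, 6)
  w <- c(5, 1, 1, 1, 1, 1)
  expect_identical(max_clique_clustering(adj, w, method = "greedy")[[1]]$members,
                   max_clique_clustering(adj, w, method = "exact")[[1]]$members)
})

test_that("the weighted median follows the sub-half cumulative rule", {
  expect_equal(weighted_median_signal(c(1, 2, 3), rep(1, 3)), 1)
  expect_equal(weighted_median_signal(5, 1), 5)
  # first value already holds half the mass -> smallest value
  expect_equal(weighted_median_signal(c(1, 2, 3), c(0.6, 0.2, 0.2)), 1)
  # sorted weights (.2, .4, .3, .1): already 0.6 mass at value 2 -> median 1
  expect_equal(weighted_median_signal(c(4, 1, 3, 2), c(.1, .2, .3, .4)), 1)
  set.seed(54)
  for (rep in 1:10) {
    x <- sample(1:6, 8, replace = TRUE)
    w <- runif(8)
    got <- weighted_median_signal(x, w)
    # direct application of the definition
    cand <- sort(unique(x))
    ok <- cand[vapply(cand, function(v) sum(w[x <= v]) / sum(w) < 0.5, TRUE)]
    expect_equal(got, if (length(ok)) max(ok) else min(x))
  }
})

test_that("cluster statistics match weighted-mean oracles and bounds", {
  set.seed(55)
  S <- matrix(runif(40, 1, 9), 4, 10)
  w <- runif(10)
  members <- c(2, 5, 7, 9)
  st <- cluster_statistics(members, S, w)
  for (i in 1:4) {
    manual <- sum(w[members] * S[i, members]) / sum(w[members])
    expect_equal(st$average[i], manual)
    expect_gte(st$average[i], min(S[i, members]))
    expect_lte(st$average[i], max(S[i, members]))
  }
  one <- cluster_statistics(3L, S, w)
  expect_equal(one$average, S[, 3])
  expect_equal(one$median, S[, 3])
})

test_that("two-stage clustering recovers planted states as a partition", {
  toy <- generate_toy_ensemble(6, two_state_specs(), 40, seed = 56)
  cl <- cluster_ensemble(toy$ensemble)
  expect_true(all(cl$assignments > 0))
  expect_equal(sum(vapply(cl$clusters, `[[`, 0, "population")), 1,
               tolerance = 1e-12)
  # clusters coincide with the planted states
  expect_length(cl$clusters, 2L)
  for (c_ in cl$clusters)
    expect_length(unique(toy$labels[c_$members]), 1L)
  # post-hoc: within-cluster pairwise eRMSD below the cutoff, identical bits
  cache <- ermsd_matrix(toy$ensemble)
  for (c_ in cl$clusters) {
    m <- c_$members
    if (length(m) > 1)
      expect_lt(max(cache[m, m]), 0.7)
    bits <- vapply(m, function(t)
      chi_conformation(get_snapshot(toy$ensemble, t)), "")
    expect_identical(unique(bits), c_$bits)
  }
})

test_that("the cluster signal table applies the population floor", {
  toy <- generate_toy_ensemble(6, two_state_specs(c(0.9, 0.1)), 30,
                               seed = 57)
  mat <- build_signal_matrix(toy$ensemble,
                             generate_mixture_restraints(toy$ensemble,
                                                         toy$labels,
                                                         c(0.9, 0.1)))
  cl <- cluster_ensemble(toy$ensemble)
  tab <- cluster_signal_table(cl, mat, toy$ensemble$prior, floor = 0.002)
  expect_true(all(tab$populations > 0.002))
  big <- cluster_signal_table(cl, mat, toy$ensemble$prior, floor = 0.2)
  expect_lte(length(big$populations), length(tab$populations))
  expect_error(cluster_signal_table(cl, mat, toy$ensemble$prior, floor = 2),
               "floor")
})
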