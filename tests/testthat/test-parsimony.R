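test_that("composition enumeration is complete, unique and on-grid", {
  expect_equal(enumerate_compositions(1), matrix(1, 1, 1))
  c2 <- enumerate_compositions(2)
  expect_equal(nrow(c2), 99L)              # compositions of 100 into 2 parts
  expect_true(all(abs(rowSums(c2) - 1) < 1e-12))
  expect_true(all(c2 >= 0.01 - 1e-12))
  expect_false(any(duplicated(c2)))
  # closed form: C(1/step - 1, Y - 1)
  c3 <- enumerate_compositions(3, step = 0.05)
  expect_equal(nrow(c3), choose(19, 2))
  # the published example composition appears on the Y = 4 grid
  c4 <- enumerate_compositions(4)
  expect_equal(nrow(c4), choose(99, 3))
  target <- c(0.01, 0.45, 0.32, 0.22)
  expect_true(any(apply(c4, 1, function(r) all(abs(r - target) < 1e-12))))
})

make_table <- function(averages, populations) {
  ids <- as.character(seq_len(nrow(averages)))
  rownames(averages) <- ids
  structure(list(populations = setNames(populations, ids),
                 averages = averages, medians = averages, floor = 0.002),
            class = "cluster_signal_table")
}

test_that("set averages are convex combinations of cluster averages", {
  set.seed(61)
  A <- matrix(runif(15, 1, 5), 3, 5)
  tab <- make_table(A, c(0.5, 0.3, 0.2))
  expect_equal(set_average(tab, 2, 1), A[2, ])
  # identical clusters: any weights give the same averages
  tab2 <- make_table(rbind(A[1, ], A[1, ]), c(0.6, 0.4))
  expect_equal(set_average(tab2, c(1, 2), c(0.3, 0.7)), A[1, ])
  w <- c(0.2, 0.5, 0.3)
  manual <- w[1] * A[1, ] + w[2] * A[2, ] + w[3] * A[3, ]
  expect_equal(set_average(tab, c(1, 2, 3), w), manual)
  expect_error(set_average(tab, 9, 1), "unknown cluster")
})

test_that("the KL divergence uses raw populations as printed", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.25)), log(2))
  # renormalized variant recovers zero when proportions match
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.25),
                             renormalize = TRUE), 0)
  expect_error(kl_divergence(c(0.5, 0.5), c(0.5, 0)), "positive")
  set.seed(62)
  for (rep in 1:10) {
    w <- runif(3); w <- w / sum(w)
    P <- runif(3, 0.05, 1)
    # log-sum inequality lower bound
    expect_gte(kl_divergence(w, P), sum(w) * log(sum(w) / sum(P)) - 1e-12)
  }
})

test_that("a single sufficient cluster gives Y = 1", {
  A <- rbind(c(2, 2, 2), c(0.5, 3, 3))
  f_exp <- c(1, 1, 1)
  tab <- make_table(A, c(0.7, 0.3))
  ms <- find_minimal_sets(tab, f_exp)
  expect_true(ms$feasible)
  expect_equal(ms$Y, 1L)
  expect_equal(ms$sets$clusters[1], "1")
})

test_that("a planted complementary pair is found at Y = 2, matching brute force", {
  # cluster 1 fails restraint 2, cluster 2 fails restraint 1; only their
  # mixture can satisfy both; cluster 3 fails restraint 3 entirely
  A <- rbind(c(2.4, 0.4, 1.2),
             c(0.4, 2.4, 1.2),
             c(2.4, 2.4, 0.1))
  f_exp <- c(1, 1, 1)
  tab <- make_table(A, c(0.5, 0.3, 0.2))
  ms <- find_minimal_sets(tab, f_exp)
  expect_true(ms$feasible)
  expect_equal(ms$Y, 2L)
  expect_true(all(vapply(ms$details, function(d)
    identical(d$clusters, c("1", "2")), TRUE)))
  # every returned composition re-verifies against the thresholds
  for (d in ms$details)
    expect_true(all(set_average(tab, d$clusters, d$weights) >=
                      f_exp * (1 - 1e-9)))
  # brute force over the full grid at Y = 1 confirms minimality
  c1 <- enumerate_compositions(1)
  for (k in 1:3)
    expect_false(all(A[k, ] >= f_exp))
  # and the top-ranked composition is the closest to 50/50 that satisfies
  best <- ms$details[[1]]
  expect_true(all(diff(vapply(ms$details, `[[`, 0, "d_kl")) >= -1e-12))
})

test_that("LP-prefilter and exact-grid modes agree on random instances", {
  set.seed(63)
  for (rep in 1:10) {
    K <- sample(3:6, 1)
    n <- 5
    A <- matrix(runif(K * n, 0.3, 3), K, n)
    # thresholds feasible for some mixture but rarely for singletons
    mix <- runif(K); mix <- mix / sum(mix)
    f_exp <- as.numeric(crossprod(A, mix)) * runif(n, 0.8, 1.05)
    P <- runif(K, 0.05, 1); P <- P / sum(P)
    tab <- make_table(A, P)
    m1 <- find_minimal_sets(tab, f_exp, step = 0.05, mode = "lp-prefilter")
    m2 <- find_minimal_sets(tab, f_exp, step = 0.05, mode = "exact-grid")
    expect_equal(m1$feasible, m2$feasible)
    expect_equal(m1$Y, m2$Y)
    if (m1$feasible) {
      expect_equal(m1$sets$clusters, m2$sets$clusters)
      expect_equal(m1$sets$weights, m2$sets$weights)
      expect_equal(m1$sets$d_kl, m2$sets$d_kl)
    }
  }
})

test_that("infeasible tables report the most violated restraint", {
  A <- rbind(c(0.2, 2), c(0.3, 2))
  tab <- make_table(A, c(0.5, 0.5))
  ms <- find_minimal_sets(tab, c(1, 1))
  expect_false(ms$feasible)
  expect_equal(ms$most_violated, 1L)
})

test_that("sets rank by ascending divergence with lexicographic ties", {
  sets <- data.frame(clusters = c("2 3", "1 2", "1 3"),
                     weights = c("a", "b", "c"),
                     d_kl = c(2.0, 1.0, 1.0), stringsAsFactors = FALSE)
  r <- rank_sets(sets)
  expect_equal(r$d_kl, c(1.0, 1.0, 2.0))
  expect_equal(r$clusters, c("1 2", "1 3", "2 3"))
  one <- sets[1, , drop = FALSE]
  expect_equal(rank_sets(one), one)
})
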