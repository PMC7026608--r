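# Test helpers: toy structure builders and independently coded oracles.
# The oracle implementations deliberately share no code with the package:
# plain scalar loops and textbook formulas only.

# -- toy snapshot construction (wraps the synthetic template) ---------------

mk_snapshot <- function(chis, sequence = NULL, bend = 0, noise = 0) {
  if (is.null(sequence))
    sequence <- rep(c("G", "U"), length.out = length(chis))
  s <- noetools:::.build_toy_snapshot(chis, sequence, bend = bend,
                                      noise = noise)
  structure(list(atoms = s$atoms, xyz = s$xyz, model_id = 1L),
            class = "noe_snapshot")
}

mk_ensemble <- function(snapshots, prior = NULL) {
  noe_ensemble(snapshots[[1L]]$atoms, lapply(snapshots, `[[`, "xyz"),
               prior_weights = prior)
}

random_chis <- function(n) {
  sample(c(40, 70, 100, 160, 200, 250, 300), n, replace = TRUE)
}

rigid_transform <- function(xyz) {
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3)
  sweep(xyz %*% (Rx %*% Ry %*% Rz), 2, runif(3, -20, 20), "+")
}

# -- independent dihedral (textbook atan2 formula) --------------------------

ref_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b0 <- p1 - p2
  b1 <- p3 - p2
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  deg <- atan2(sum(cr(b1, v) * w), sum(v * w)) * 180 / pi
  ((deg %% 360) + 360) %% 360
}

# -- independent eRMSD implementation ---------------------------------------
# Same published definition, coded from scratch with scalar loops: base
# frame from the six-ring atoms (purines ordered C2,C6,C4; pyrimidines
# C2,C4,C6), positions scaled by (5,5,3) A, smooth 4-vector G with cutoff
# 2.4 in scaled units, RMS over all ordered pairs divided by residue count.

ref_gvec <- function(snap) {
  at <- snap$atoms
  res <- unique(at$resno)
  n <- length(res)
  origin <- matrix(0, n, 3)
  axes <- vector("list", n)
  for (k in seq_len(n)) {
    base <- at$base[match(res[k], at$resno)]
    nms <- if (base == "purine") c("C2", "C6", "C4") else c("C2", "C4", "C6")
    p <- matrix(0, 3, 3)
    for (q in 1:3)
      p[q, ] <- snap$xyz[which(at$resno == res[k] & at$elety == nms[q]), ]
    o <- c(mean(p[, 1]), mean(p[, 2]), mean(p[, 3]))
    v1 <- p[1, ] - o
    v2 <- p[2, ] - o
    x <- v1 / sqrt(sum(v1^2))
    zr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    z <- zr / sqrt(sum(zr^2))
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    origin[k, ] <- o
    axes[[k]] <- list(x = x, y = y, z = z)
  }
  gamma <- pi / 2.4
  G <- array(0, c(n, n, 4))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    d <- origin[k, ] - origin[j, ]
    r <- c(sum(d * axes[[j]]$x) / 5, sum(d * axes[[j]]$y) / 5,
           sum(d * axes[[j]]$z) / 3)
    e <- sqrt(sum(r^2))
    if (e < 2.4)
      G[j, k, ] <- c(sin(gamma * e) * r / e, 1 + cos(gamma * e)) / gamma
  }
  G
}

ref_ermsd <- function(a, b) {
  ga <- ref_gvec(a)
  gb <- ref_gvec(b)
  sqrt(sum((ga - gb)^2) / dim(ga)[1])
}

# -- exhaustive max-weight clique via igraph maximal-clique enumeration -----

oracle_max_weight_cliques <- function(adj, w) {
  g <- igraph::graph_from_adjacency_matrix(adj != 0 & !diag(nrow(adj)),
                                           mode = "undirected")
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(x) sort(as.integer(x)))
  ws <- vapply(cl, function(x) sum(w[x]), 0)
  best <- max(ws)
  list(weight = best, sets = cl[abs(ws - best) <= 1e-9 * max(1, best)])
}

lex_min_set <- function(sets) {
  keys <- vapply(sets, function(s) paste(sprintf("%06d", s), collapse = ","),
                 "")
  sets[[order(keys)[1L]]]
}

# standard planted fixtures ------------------------------------------------

two_state_specs <- function(p = c(0.65, 0.35)) {
  list(state_spec("A", c(200, 200, 70, 200, 200, 200), p[1]),
       state_spec("B", c(200, 200, 200, 70, 200, 200), p[2]))
}

three_state_specs <- function(p = c(0.55, 0.3, 0.15)) {
  list(state_spec("A", c(200, 200, 70, 200, 200, 200), p[1]),
       state_spec("B", c(200, 200, 200, 70, 200, 200), p[2]),
       state_spec("C", rep(200, 6), p[3], bend = 60))
}
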