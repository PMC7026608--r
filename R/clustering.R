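# Two-stage conformational clustering.
#
# Stage 1 partitions snapshots by their exact syn/anti chi bitstring, so that
# conformations with different glycosidic patterns can never share a cluster
# (a single syn outlier would otherwise dominate a cluster's d^-6 averages).
# Stage 2 clusters each pre-cluster by iteratively extracting the
# maximum-total-weight clique of the graph whose edges connect snapshots with
# eRMSD below the cutoff (0.7 by default). Every emitted cluster therefore
# has pairwise eRMSD < 0.7 and an identical chi conformation.

#' Pre-cluster snapshots by chi bitstring
#'
#' Partitions snapshots by exact equality of their syn/anti bitstrings and
#' orders pre-clusters by descending weighted fraction of the ensemble
#' (ties broken by bitstring).
#'
#' @param conformations Character vector of per-snapshot bitstrings
#'   (see [chi_conformation()]).
#' @param weights Snapshot weights (default uniform; renormalized).
#' @return Object of class `noe_preclusters`: list of lists with elements
#'   `bits`, `members` (snapshot indices) and `fraction`.
#' @export
precluster <- function(conformations, weights = NULL) {
  w <- .check_weights(weights, length(conformations), "weights")
  groups <- split(seq_along(conformations), conformations)
  frac <- vapply(groups, function(m) sum(w[m]), 0)
  ord <- order(-frac, names(groups))
  structure(lapply(ord, function(k)
    list(bits = names(groups)[k], members = unname(groups[[k]]),
         fraction = unname(frac[k]))),
    class = "noe_preclusters")
}

#' Neighbor matrix of a set of snapshots
#'
#' Binary symmetric matrix with unit diagonal; entry (t, t') is 1 iff the
#' eRMSD between the two snapshots is strictly below the cutoff.
#'
#' @param cache Pairwise `ermsd_cache` matrix over the full ensemble.
#' @param members Snapshot indices (rows/columns of the submatrix); default
#'   all.
#' @param cutoff eRMSD cutoff (default 0.7; strict inequality).
#' @return Integer 0/1 matrix of dimension `length(members)` squared.
#' @export
neighbor_matrix <- function(cache, members = NULL, cutoff = 0.7) {
  m <- unclass(cache)
  if (!is.null(members)) m <- m[members, members, drop = FALSE]
  out <- (m < cutoff) * 1L
  diag(out) <- 1L
  out
}

# lexicographic comparison of two sorted index sets; a strict prefix is
# smaller than its extension
.lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Exact maximum-weight clique of a neighbor graph
#'
#' Branch-and-bound search for the clique with the largest total vertex
#' weight; among equal-weight cliques the lexicographically smallest sorted
#' member set is returned, making the result deterministic.
#'
#' @param adjacency Symmetric 0/1 (or logical) adjacency matrix; the diagonal
#'   is ignored.
#' @param weights Nonnegative vertex weights.
#' @return Sorted integer vector of clique member indices.
#' @export
max_weight_clique <- function(adjacency, weights) {
  n <- nrow(adjacency)
  stopifnot(ncol(adjacency) == n, length(weights) == n, all(weights >= 0))
  if (n == 0L) return(integer(0))
  adjl <- lapply(seq_len(n), function(i)
    which(adjacency[i, ] != 0 & seq_len(n) != i))
  eps <- 1e-9 * max(1, sum(weights))
  best <- integer(0)
  best_w <- -Inf
  expand <- function(cur, cur_w, cand) {
    if (!length(cand)) {
      if (cur_w > best_w + eps ||
          (abs(cur_w - best_w) <= eps && .lex_less(cur, best))) {
        best <<- cur
        best_w <<- max(cur_w, best_w)
      }
      return(invisible(NULL))
    }
    if (cur_w + sum(weights[cand]) < best_w - eps) return(invisible(NULL))
    v <- cand[1L]
    expand(c(cur, v), cur_w + weights[v], intersect(cand[-1L], adjl[[v]]))
    expand(cur, cur_w, cand[-1L])
  }
  expand(integer(0), 0, seq_len(n))
  sort(best)
}

# greedy fallback for very large graphs: grow from the heaviest vertex,
# always adding the heaviest compatible candidate (ties: lowest index)
.greedy_clique <- function(adjacency, weights) {
  n <- nrow(adjacency)
  seed <- order(-weights, seq_len(n))[1L]
  mem <- seed
  cand <- which(adjacency[seed, ] != 0 & seq_len(n) != seed)
  while (length(cand)) {
    v <- cand[order(-weights[cand], cand)[1L]]
    mem <- c(mem, v)
    cand <- cand[cand != v & adjacency[v, cand] != 0]
  }
  sort(mem)
}

#' Iterative maximum-clique clustering of one neighbor graph
#'
#' Repeatedly extracts the maximum-total-weight clique of the remaining
#' graph, removes its members, and continues until every snapshot is
#' assigned; singleton cliques are allowed. If the remaining members carry
#' zero total weight (possible after reweighting), they are emitted as
#' singletons with zero population.
#'
#' @param adjacency Neighbor matrix from [neighbor_matrix()].
#' @param weights Nonnegative member weights (same order as the matrix; not
#'   renormalized -- populations are reported on the given scale).
#' @param method `"exact"` (branch-and-bound, default) or `"greedy"` for very
#'   large graphs; the method used is recorded as an attribute.
#' @return List of clusters in extraction order; each a list with `members`
#'   (indices into the matrix) and `weight` (sum of member weights).
#' @export
max_clique_clustering <- function(adjacency, weights,
                                  method = c("exact", "greedy")) {
  method <- match.arg(method)
  n <- nrow(adjacency)
  stopifnot(length(weights) == n)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining)) {
    if (sum(weights[remaining]) <= 0) {
      clusters <- c(clusters, lapply(remaining, function(i)
        list(members = i, weight = 0)))
      break
    }
    sub <- adjacency[remaining, remaining, drop = FALSE]
    sel <- if (method == "exact") max_weight_clique(sub, weights[remaining])
           else .greedy_clique(sub, weights[remaining])
    mem <- remaining[sel]
    clusters <- c(clusters, list(list(members = mem,
                                      weight = sum(weights[mem]))))
    remaining <- setdiff(remaining, mem)
  }
  attr(clusters, "method") <- method
  clusters
}

#' Full two-stage clustering of an ensemble
#'
#' Computes the chi bitstring of every snapshot, pre-clusters by bitstring,
#' clusters each pre-cluster by weighted maximum-clique extraction under the
#' eRMSD cutoff, and numbers the resulting clusters 1, 2, ... by descending
#' population (sum of member weights).
#'
#' @param ensemble A `noe_ensemble`.
#' @param weights Snapshot weights, e.g. from [maxent_reweight()] (default:
#'   the ensemble's prior weights).
#' @param cache Optional precomputed [ermsd_matrix()].
#' @param cutoff eRMSD clustering cutoff (default 0.7).
#' @param method Clique search method, see [max_clique_clustering()].
#' @return Object of class `noe_clusters`: list with `clusters` (list of
#'   `id`, `members`, `population`, `bits`, `n`), `assignments` (integer
#'   vector, snapshot -> cluster id), `preclusters`, `cutoff`, `method`.
#' @export
cluster_ensemble <- function(ensemble, weights = NULL, cache = NULL,
                             cutoff = 0.7, method = c("exact", "greedy")) {
  method <- match.arg(method)
  T_ <- n_snapshots(ensemble)
  w <- if (is.null(weights)) ensemble$prior
       else .check_weights(weights, T_, "weights")
  bits <- vapply(seq_len(T_), function(t)
    chi_conformation(get_snapshot(ensemble, t)), "")
  if (is.null(cache)) cache <- ermsd_matrix(ensemble)
  pcs <- precluster(bits, w)
  raw <- list()
  for (pc in pcs) {
    adj <- neighbor_matrix(cache, pc$members, cutoff)
    cl <- max_clique_clustering(adj, w[pc$members], method = method)
    for (c_ in cl)
      raw <- c(raw, list(list(members = pc$members[c_$members],
                              population = c_$weight, bits = pc$bits)))
  }
  ord <- order(-vapply(raw, `[[`, 0, "population"),
               vapply(raw, `[[`, "", "bits"),
               vapply(raw, function(c_) min(c_$members), 0))
  clusters <- lapply(seq_along(ord), function(k) {
    c_ <- raw[[ord[k]]]
    list(id = k, members = sort(c_$members), population = c_$population,
         bits = c_$bits, n = length(c_$members))
  })
  assignments <- integer(T_)
  for (c_ in clusters) assignments[c_$members] <- c_$id
  structure(list(clusters = clusters, assignments = assignments,
                 preclusters = pcs, cutoff = cutoff, method = method),
            class = "noe_clusters")
}

#' Summary table of a clustering
#'
#' @param object A `noe_clusters` object.
#' @param ... Unused.
#' @return Data frame with columns `cluster_id`, `population`, `chi`,
#'   `n_members`.
#' @export
summary.noe_clusters <- function(object, ...) {
  data.frame(cluster_id = vapply(object$clusters, `[[`, 0L, "id"),
             population = vapply(object$clusters, `[[`, 0, "population"),
             chi = vapply(object$clusters, `[[`, "", "bits"),
             n_members = vapply(object$clusters, `[[`, 0L, "n"),
             stringsAsFactors = FALSE)
}

#' @export
print.noe_clusters <- function(x, ...) {
  s <- summary(x)
  cat("noe_clusters:", nrow(s), "clusters over", length(x$assignments),
      "snapshots (eRMSD cutoff ", x$cutoff, ", ", x$method, " clique search)\n",
      sep = "")
  print(head(s, 10L))
  if (nrow(s) > 10L) cat("  ...", nrow(s) - 10L, "more\n")
  invisible(x)
}

#' Weighted median signal of a cluster
#'
#' The maximum signal value v in the cluster such that the summed relative
#' weight of that value and all lower signals stays strictly below 0.5; when
#' already the smallest value carries half the mass or more, the smallest
#' signal is returned.
#'
#' @param x Signal values.
#' @param w Nonnegative weights (same length, not all zero).
#' @return Scalar.
#' @export
weighted_median_signal <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w)
  last <- !duplicated(x, fromLast = TRUE)
  ux <- x[last]
  cw <- cum[last]
  eligible <- ux[cw < 0.5]
  if (!length(eligible)) ux[1L] else max(eligible)
}

#' Per-cluster signal statistics
#'
#' Weighted average `sum_{t in c} w_t f_it / sum_{t in c} w_t` and weighted
#' median (see [weighted_median_signal()]) of every restraint's signal over a
#' cluster's members.
#'
#' @param members Snapshot indices of the cluster.
#' @param signals Signal matrix (restraints x snapshots).
#' @param weights Full-ensemble snapshot weights.
#' @return List with numeric vectors `average` and `median`.
#' @export
cluster_statistics <- function(members, signals, weights) {
  stopifnot(length(members) >= 1L)
  wm <- weights[members]
  if (sum(wm) <= 0) wm <- rep(1, length(members))  # zero-population cluster
  S <- signals[, members, drop = FALSE]
  avg <- as.numeric(S %*% wm) / sum(wm)
  med <- apply(S, 1L, weighted_median_signal, w = wm)
  list(average = avg, median = med)
}

#' Cluster signal table feeding the parsimony search
#'
#' Collects, for every cluster whose population exceeds the admission floor,
#' its population and per-restraint weighted average (and median) signals.
#'
#' @param clustering A `noe_clusters` object.
#' @param signals Signal matrix (restraints x snapshots).
#' @param weights Snapshot weights used for the clustering.
#' @param floor Population floor for admission (default 0.002; strictly
#'   greater-than).
#' @return Object of class `cluster_signal_table`: list with `populations`
#'   (named by cluster id), `averages` and `medians` (cluster x restraint
#'   matrices), `floor`.
#' @export
cluster_signal_table <- function(clustering, signals, weights,
                                 floor = 0.002) {
  keep <- Filter(function(c_) c_$population > floor, clustering$clusters)
  if (!length(keep))
    stop("no cluster has population above the floor ", floor, call. = FALSE)
  ids <- vapply(keep, `[[`, 0L, "id")
  stats <- lapply(keep, function(c_)
    cluster_statistics(c_$members, signals, weights))
  avg <- do.call(rbind, lapply(stats, `[[`, "average"))
  med <- do.call(rbind, lapply(stats, `[[`, "median"))
  rownames(avg) <- rownames(med) <- ids
  structure(list(populations = setNames(vapply(keep, `[[`, 0, "population"),
                                        ids),
                 averages = avg, medians = med, floor = floor),
            class = "cluster_signal_table")
}

#' Export clusters as multi-model PDB files
#'
#' Writes one multi-model PDB per cluster (members as models), mirroring the
#' per-cluster all-atom coordinate sets that accompany published ensemble
#' analyses.
#'
#' @param ensemble The clustered `noe_ensemble`.
#' @param clustering A `noe_clusters` object.
#' @param dir Output directory (created if needed).
#' @param ids Cluster ids to export (default: all).
#' @return Character vector of files written, invisibly.
#' @export
export_cluster_pdbs <- function(ensemble, clustering, dir, ids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(ids)) ids <- vapply(clustering$clusters, `[[`, 0L, "id")
  files <- character(0)
  for (c_ in clustering$clusters) {
    if (!(c_$id %in% ids)) next
    sub <- noe_ensemble(ensemble$atoms, ensemble$xyz[c_$members])
    f <- file.path(dir, sprintf("cluster_%03d.pdb", c_$id))
    write_ensemble_pdb(sub, f)
    files <- c(files, f)
  }
  invisible(files)
}
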