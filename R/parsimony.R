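# Maximum-parsimony selection of a minimal cluster set.
#
# Given per-cluster average signals and the NOE thresholds, find the smallest
# number Y of clusters that can be reweighted -- over a discrete weight grid
# with step 0.01 -- so that every restraint's set average meets its
# threshold. Feasible sets are ranked by the Kullback-Leibler divergence of
# the new weights from the clusters' original populations, so that the most
# "conservative" reinterpretations of the simulated ensemble come first.

#' Enumerate discrete weight compositions
#'
#' All vectors of Y weights, each a positive multiple of `step` and at least
#' `step`, summing to 1 -- i.e. each weight lies in
#' `[step, (N - Y + 1) * step]` with `N = 1/step` (100 by default). Emitted
#' exactly once, in deterministic lexicographic order.
#'
#' @param Y Number of weights.
#' @param step Grid step (default 0.01).
#' @return Matrix with Y columns; one composition per row.
#' @export
enumerate_compositions <- function(Y, step = 0.01) {
  M <- round(1 / step)
  stopifnot(Y >= 1L, Y <= M)
  comp_int <- function(m, y) {
    if (y == 1L) return(matrix(m, 1L, 1L))
    do.call(rbind, lapply(seq_len(m - y + 1L), function(k)
      cbind(k, comp_int(m - k, y - 1L))))
  }
  out <- comp_int(M, as.integer(Y)) * step
  dimnames(out) <- NULL
  out
}

#' Convex combination of cluster average signals
#'
#' `<f_i>_set = sum_y w'_y <f_i>_wy` over the clusters of the set.
#'
#' @param table A `cluster_signal_table`.
#' @param clusters Cluster ids in the set.
#' @param composition Weights `w'_y` (same order as `clusters`; must sum
#'   to 1).
#' @return Per-restraint signal vector.
#' @export
set_average <- function(table, clusters, composition) {
  ids <- as.character(clusters)
  if (!all(ids %in% rownames(table$averages)))
    stop("unknown cluster id(s): ",
         paste(setdiff(ids, rownames(table$averages)), collapse = ", "),
         call. = FALSE)
  stopifnot(length(composition) == length(ids),
            abs(sum(composition) - 1) < 1e-9)
  as.numeric(crossprod(table$averages[ids, , drop = FALSE], composition))
}

#' Kullback-Leibler divergence of set weights from cluster populations
#'
#' `D_KL(w'||P) = sum_y w'_y ln(w'_y / P_y)` over the clusters of the set,
#' using the raw populations exactly as reported (the populations restricted
#' to the set are deliberately not renormalized; pass
#' `renormalize = TRUE` for the sensitivity-analysis variant).
#'
#' @param composition Set weights `w'_y` (positive, sum 1).
#' @param populations Original cluster populations `P_y` for the same
#'   clusters (must be > 0).
#' @param renormalize Renormalize `populations` to sum 1 over the set first
#'   (default `FALSE`).
#' @return Scalar divergence.
#' @export
kl_divergence <- function(composition, populations, renormalize = FALSE) {
  stopifnot(length(composition) == length(populations))
  if (any(populations <= 0))
    stop("populations must be strictly positive within the set",
         call. = FALSE)
  if (any(composition <= 0))
    stop("composition weights must be strictly positive", call. = FALSE)
  if (renormalize) populations <- populations / sum(populations)
  sum(composition * log(composition / populations))
}

# LP feasibility of one cluster subset: does any continuous weight vector
# with w_y >= step, sum w = 1 satisfy all thresholds? Sound prefilter: if the
# continuous relaxation is infeasible, so is every grid point.
.lp_feasible <- function(averages, f_exp, step) {
  Y <- nrow(averages)
  if (Y == 1L) return(all(averages[1L, ] >= f_exp * (1 - 1e-12)))
  b3 <- 1 - Y * step
  if (b3 < -1e-12) return(FALSE)
  rhs <- f_exp - step * colSums(averages)   # thresholds for v = w - step
  keep <- rhs > 0
  if (!any(keep)) return(TRUE)              # met already at the lower bounds
  if (b3 <= 1e-15) return(FALSE)            # v forced to 0 but demands remain
  s <- tryCatch(
    suppressWarnings(
    boot::simplex(a = rep(0, Y),
                  A2 = t(averages)[keep, , drop = FALSE], b2 = rhs[keep],
                  A3 = matrix(1, 1L, Y), b3 = b3, maxi = TRUE)),
    error = function(e) NULL)
  # a solver hiccup admits the subset; the grid enumeration decides
  if (is.null(s)) return(TRUE)
  isTRUE(s$solved == 1)
}

#' Find minimal cluster sets satisfying all NOE thresholds
#'
#' Starting from Y = 1 and increasing, searches every subset of Y admitted
#' clusters and every discrete weight composition (see
#' [enumerate_compositions()]) for combinations whose set averages meet every
#' threshold; stops at the smallest Y with at least one feasible set and
#' returns all feasible sets at that Y, ranked by [kl_divergence()].
#'
#' Two search modes give identical results: `"exact-grid"` enumerates the
#' full grid over every subset; `"lp-prefilter"` (default) first tests each
#' subset for feasibility of the continuous relaxation by linear programming
#' over the simplex with lower bound `step`, and enumerates the grid only
#' inside feasible subsets -- the relaxation can only over-admit, never
#' discard a grid-feasible subset.
#'
#' @param table A `cluster_signal_table` (already floored by population).
#' @param restraints A `noe_restraints` table or numeric `f_exp` vector.
#' @param step Weight grid step (default 0.01).
#' @param mode `"lp-prefilter"` or `"exact-grid"`.
#' @param max_Y Optional cap on the set size searched.
#' @param tol Relative feasibility tolerance at the threshold boundary
#'   (default 1e-12).
#' @return List with `feasible` flag; when feasible: `Y`, `step`, `mode` and
#'   `sets`, a data frame (columns `clusters`, `weights` --
#'   space-separated -- and `d_kl`) sorted by divergence, plus `details`, a
#'   list of `(clusters, weights, d_kl)` in the same order. When no set of
#'   any allowed size is feasible: `most_violated`, the index of the
#'   restraint whose threshold exceeds the best cluster average by the
#'   largest margin.
#' @export
find_minimal_sets <- function(table, restraints, step = 0.01,
                              mode = c("lp-prefilter", "exact-grid"),
                              max_Y = NULL, tol = 1e-12) {
  mode <- match.arg(mode)
  f_exp <- if (is.numeric(restraints)) restraints else restraints$f_exp
  A <- table$averages
  stopifnot(ncol(A) == length(f_exp))
  K <- nrow(A)
  ids <- rownames(A)
  M <- round(1 / step)
  y_max <- min(K, M, if (is.null(max_Y)) Inf else max_Y)
  lim <- f_exp * (1 - tol)
  for (Y in seq_len(y_max)) {
    comps <- enumerate_compositions(Y, step)
    subsets <- combn(K, Y)
    details <- list()
    for (s in seq_len(ncol(subsets))) {
      sel <- subsets[, s]
      As <- A[sel, , drop = FALSE]
      if (mode == "lp-prefilter" && !.lp_feasible(As, f_exp, step)) next
      vals <- comps %*% As                      # compositions x restraints
      ok <- which(rowSums(vals >= rep(lim, each = nrow(vals))) == length(f_exp))
      for (r in ok) {
        w <- comps[r, ]
        details <- c(details, list(list(
          clusters = ids[sel], weights = w,
          d_kl = kl_divergence(w, table$populations[ids[sel]]))))
      }
    }
    if (length(details)) {
      sets <- data.frame(
        clusters = vapply(details, function(d) paste(d$clusters,
                                                     collapse = " "), ""),
        weights = vapply(details, function(d)
          paste(format(d$weights, trim = TRUE), collapse = " "), ""),
        d_kl = vapply(details, `[[`, 0, "d_kl"),
        stringsAsFactors = FALSE)
      ord <- rank_sets(sets, index = TRUE)
      return(list(feasible = TRUE, Y = Y, step = step, mode = mode,
                  sets = sets[ord, , drop = FALSE],
                  details = details[ord]))
    }
  }
  shortfall <- f_exp - apply(A, 2L, max)
  list(feasible = FALSE, Y = NA_integer_, step = step, mode = mode,
       most_violated = which.max(shortfall))
}

#' Rank feasible sets by Kullback-Leibler divergence
#'
#' Ascending divergence; ties broken by the lexicographic cluster-id string.
#'
#' @param sets Data frame with columns `clusters` and `d_kl` (as produced by
#'   [find_minimal_sets()]).
#' @param index Return the ordering permutation instead of the sorted frame.
#' @return Sorted data frame (or an integer permutation).
#' @export
rank_sets <- function(sets, index = FALSE) {
  ord <- order(sets$d_kl, sets$clusters)
  if (index) ord else sets[ord, , drop = FALSE]
}
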