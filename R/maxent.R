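# A-posteriori maximum-entropy reweighting with inequality restraints.
#
# Given per-snapshot signals f_{i,t} and thresholds f_exp_i, the reweighted
# ensemble w_t  propto  prior_t * exp(-sum_i lambda_i f_{i,t}) is the
# minimal-information perturbation of the prior whose averages satisfy
# <f_i>_w >= f_exp_i. The multipliers minimize the convex dual
#
#   Gamma(lambda) = ln sum_t prior_t exp(-sum_i lambda_i f_{i,t})
#                   + sum_i lambda_i f_exp_i + sigma^2/2 sum_i lambda_i^2
#
# subject to lambda_i <= 0 (inequality restraints act only downward: a
# correcting potential is applied only where the prior average falls short).
# The sigma^2 term is a Gaussian prior on the experimental/model error which
# relaxes active constraints to <f_i>_w = f_exp_i + sigma^2 lambda_i.
# The dual gradient is f_exp_i - <f_i>_lambda + sigma^2 lambda_i and the
# Hessian Cov_w(f_i, f_j) + sigma^2 I is positive definite, so a projected
# Newton iteration with backtracking converges reliably; weights are
# evaluated with log-sum-exp stabilization.

#' Maximum-entropy reweighting under NOE inequality restraints
#'
#' Solves for snapshot weights `w_t` proportional to
#' `prior_t * exp(-sum_i lambda_i f_it)` with sign-constrained multipliers
#' `lambda_i <= 0` minimizing the dual objective described in the package
#' documentation. At the solution, each restraint either is inactive
#' (`lambda_i = 0` and the weighted average already meets the threshold) or
#' active (`lambda_i < 0` and the average equals
#' `f_exp_i + sigma^2 * lambda_i`; exactly the threshold when `sigma = 0`).
#'
#' With `sigma = 0` and a restraint set infeasible on the given snapshots the
#' multipliers diverge; this is reported via `converged = FALSE` and a
#' warning naming the worst restraint, never silently.
#'
#' @param signals Signal matrix (restraints x snapshots) in nm^-6, from
#'   [build_signal_matrix()].
#' @param restraints A `noe_restraints` table or numeric vector of threshold
#'   signals `f_exp` (nm^-6).
#' @param sigma Gaussian error scale in nm^-6 (default 0.5; 0 gives hard
#'   inequality restraints).
#' @param prior_weights Prior snapshot weights (default uniform).
#' @param tolerance Convergence tolerance: the iteration stops when the
#'   Karush-Kuhn-Tucker residual of the dual gradient, relative to
#'   `max(1, max(f_exp))`, drops below it. Default `1e-8`.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `maxent_result`: list with `weights` (sum 1),
#'   `lambda` (all <= 0), `sigma`, `kish` ([kish_size()] of the weights),
#'   `converged`, `iterations`, `objective_trace` and `averages` (weighted
#'   per-restraint signals).
#' @export
maxent_reweight <- function(signals, restraints, sigma = 0.5,
                            prior_weights = NULL, tolerance = 1e-8,
                            max_iter = 200L) {
  f_exp <- if (is.numeric(restraints)) restraints else restraints$f_exp
  F <- as.matrix(signals)
  stopifnot(length(f_exp) == nrow(F), all(is.finite(F)), sigma >= 0)
  n <- nrow(F)
  T_ <- ncol(F)
  prior <- .check_weights(prior_weights, T_, "prior_weights")
  log_prior <- log(prior)
  scale <- max(1, max(abs(f_exp)))

  state <- function(lambda) {
    a <- log_prior - as.numeric(crossprod(F, lambda))
    m <- max(a)
    lz <- m + log(sum(exp(a - m)))
    w <- exp(a - lz)
    avg <- as.numeric(F %*% w)
    list(w = w, avg = avg,
         g = f_exp - avg + sigma^2 * lambda,
         obj = lz + sum(lambda * f_exp) + sigma^2 / 2 * sum(lambda^2))
  }

  lambda <- rep(0, n)
  st <- state(lambda)
  trace <- st$obj
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    kkt <- ifelse(lambda < 0, abs(st$g), pmax(0, st$g))
    if (max(kkt) <= tolerance * scale) { converged <- TRUE; break }
    free <- which(lambda < 0 | st$g > 0)
    Ff <- F[free, , drop = FALSE]
    M2 <- Ff %*% (t(Ff) * st$w)
    H <- M2 - tcrossprod(st$avg[free]) + diag(sigma^2 + 1e-12 * scale^2,
                                              length(free))
    dir <- tryCatch(-solve(H, st$g[free]),
                    error = function(e) -st$g[free] / scale^2)
    step <- 1
    improved <- FALSE
    for (ls in 1:60) {
      cand <- lambda
      cand[free] <- pmin(0, lambda[free] + step * dir)
      st_new <- state(cand)
      if (st_new$obj <= st$obj + 1e-12 * abs(st$obj)) {
        lambda <- cand
        st <- st_new
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, st$obj)
    if (!improved) break  # numerically stationary
  }
  kkt <- ifelse(lambda < 0, abs(st$g), pmax(0, st$g))
  if (max(kkt) <= tolerance * scale) converged <- TRUE
  if (!converged) {
    worst <- which.min(lambda)
    warning("maximum-entropy reweighting did not converge (KKT residual ",
            format(max(kkt) / scale, digits = 3),
            "); most negative multiplier: restraint ", worst, " at ",
            format(lambda[worst], digits = 3),
            if (sigma == 0) " -- the restraint set may be infeasible on these snapshots",
            call. = FALSE)
  }
  structure(list(weights = st$w, lambda = lambda, sigma = sigma,
                 kish = kish_size(st$w), converged = converged,
                 iterations = it, objective_trace = trace,
                 averages = st$avg, tolerance = tolerance),
            class = "maxent_result")
}

#' Normalized Kish effective sample size
#'
#' `s = <w>^2 / <w^2>`, between 0 and 1; equal to 1 iff all weights are equal
#' and `1/T` for a one-hot weight vector. It measures the fraction of
#' statistically effective snapshots left after reweighting.
#'
#' @param weights Nonnegative weights, not all zero (any normalization).
#' @return Scalar in `(0, 1]`.
#' @export
kish_size <- function(weights) {
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0)
    stop("'weights' must be nonnegative, finite and not all zero",
         call. = FALSE)
  mean(weights)^2 / mean(weights^2)
}

#' Kish size as a function of snapshot-prefix length
#'
#' Re-solves the reweighting on the first k snapshots for a grid of prefix
#' lengths -- the statistical-efficiency trace used to judge whether a
#' simulation has run long enough.
#'
#' @inheritParams maxent_reweight
#' @param lengths Prefix lengths (default: 10 evenly spaced values up to T).
#' @return Data frame with columns `prefix` and `kish`.
#' @export
kish_trace <- function(signals, restraints, sigma = 0.5, prior_weights = NULL,
                       lengths = NULL) {
  T_ <- ncol(signals)
  if (is.null(lengths))
    lengths <- unique(pmax(2L, round(seq(T_ / 10, T_, length.out = 10L))))
  prior <- .check_weights(prior_weights, T_, "prior_weights")
  ks <- vapply(lengths, function(k) {
    r <- suppressWarnings(
      maxent_reweight(signals[, seq_len(k), drop = FALSE], restraints,
                      sigma = sigma, prior_weights = prior[seq_len(k)]))
    r$kish
  }, 0)
  data.frame(prefix = as.integer(lengths), kish = ks)
}

#' @export
print.maxent_result <- function(x, ...) {
  cat("maxent_result:", length(x$weights), "snapshots,",
      length(x$lambda), "restraints\n")
  cat("  sigma:", x$sigma, "nm^-6 | active multipliers:",
      sum(x$lambda < 0), "| Kish size:", format(x$kish, digits = 4),
      "| converged:", x$converged, "(", x$iterations, "iterations )\n")
  invisible(x)
}
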