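# NOE forward model, ensemble averages, relative signals and violation
# accounting.
#
# Under the assumption that conformational exchange is much slower than
# molecular tumbling, the NOE back-calculation for a proton pair at distance
# d reduces to f(d) = 1/d^6. Signals are carried in nm^-6 throughout so that
# the Gaussian error scale sigma = 0.5 nm^-6 of the reweighting step applies
# without conversion; restraint files give distances in Angstrom and are
# converted on load.

.class_dmax <- c(strong = 3.6, s = 3.6,
                 medium = 5.0, m = 5.0,
                 weak = 6.5, w = 6.5, l = 6.5, long = 6.5)

#' NOE forward signal of an interproton distance
#'
#' `f(d) = 1/d^6` with `d` expressed in nm; the returned signal is in nm^-6.
#'
#' @param d Distance(s), strictly positive.
#' @param unit Unit of `d`: `"angstrom"` (default, matching structure
#'   coordinates) or `"nm"`.
#' @return Signal(s) in nm^-6.
#' @export
forward_signal <- function(d, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("'d' must be finite and > 0", call. = FALSE)
  if (unit == "angstrom") d <- d / 10
  d^(-6)
}

#' Build a restraint set from proton pairs and signal classes
#'
#' A restraint is a proton pair with a maximum (upper-bound) distance `d_exp`
#' given either directly or through its signal class: strong = 3.6 A,
#' medium = 5.0 A, weak (long) = 6.5 A. The threshold signal is
#' `f_exp = (d_exp in nm)^-6`; an ensemble satisfies restraint i when its
#' average signal is at least `f_exp[i]`.
#'
#' @param res_i,atom_i,res_j,atom_j Residue sequence positions and atom names
#'   of the proton pairs.
#' @param class Signal class per pair (`s`/`m`/`w`/`l` or full words), or `NA`
#'   where `d_exp` is given directly.
#' @param d_exp Explicit maximum distances in Angstrom (overrides `class`
#'   where not `NA`).
#' @return Data frame of class `noe_restraints` with columns `res_i`,
#'   `atom_i`, `res_j`, `atom_j`, `class`, `d_exp` (Angstrom), `f_exp`
#'   (nm^-6).
#' @export
noe_restraints <- function(res_i, atom_i, res_j, atom_j, class = NA,
                           d_exp = NA_real_) {
  n <- length(res_i)
  class <- rep_len(as.character(class), n)
  d_exp <- rep_len(as.numeric(d_exp), n)
  from_class <- is.na(d_exp)
  if (any(from_class)) {
    cl <- tolower(trimws(class[from_class]))
    bad <- !(cl %in% names(.class_dmax))
    if (any(bad))
      stop("unknown NOE signal class: ",
           paste(unique(cl[bad]), collapse = ", "), call. = FALSE)
    d_exp[from_class] <- .class_dmax[cl]
  }
  if (any(d_exp <= 0)) stop("'d_exp' must be > 0", call. = FALSE)
  out <- data.frame(res_i = as.integer(res_i),
                    atom_i = .normalize_elety(atom_i),
                    res_j = as.integer(res_j),
                    atom_j = .normalize_elety(atom_j),
                    class = class, d_exp = d_exp,
                    f_exp = forward_signal(d_exp),
                    stringsAsFactors = FALSE)
  class(out) <- c("noe_restraints", "data.frame")
  out
}

#' Read an NOE restraint table from CSV/TSV
#'
#' Expected columns: `res_i`, `atom_i`, `res_j`, `atom_j`, and either `class`
#' (strong/medium/weak or s/m/w/l) or `d_max` (Angstrom; also accepted as
#' `dmax` or `d_exp`). A `d_min`/`dmin` column, if present, is parsed and
#' discarded with a message: only the maximum distances act as restraints.
#'
#' @param path File path; the separator (comma or tab) is sniffed from the
#'   header line.
#' @return A `noe_restraints` data frame.
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("restraint file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE, quote = "", comment.char = "")
  names(df) <- tolower(names(df))
  need <- c("res_i", "atom_i", "res_j", "atom_j")
  if (!all(need %in% names(df)))
    stop("restraint table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  dmax_col <- intersect(c("d_max", "dmax", "d_exp"), names(df))
  if (any(c("d_min", "dmin") %in% names(df)))
    message("minimum NOE distances present in ", basename(path),
            " were parsed and ignored (only maxima act as restraints)")
  noe_restraints(df$res_i, df$atom_i, df$res_j, df$atom_j,
                 class = if ("class" %in% names(df)) df$class else NA,
                 d_exp = if (length(dmax_col)) df[[dmax_col[1L]]] else NA_real_)
}

#' Per-restraint, per-snapshot forward signals
#'
#' Entry (i, t) is `forward_signal` of the distance of restraint i's proton
#' pair in snapshot t, in nm^-6.
#'
#' @param ensemble A `noe_ensemble`.
#' @param restraints A `noe_restraints` table.
#' @return Matrix with `nrow(restraints)` rows and T columns.
#' @export
build_signal_matrix <- function(ensemble, restraints) {
  n <- nrow(restraints)
  T_ <- n_snapshots(ensemble)
  a <- ensemble$atoms
  mat <- matrix(NA_real_, n, T_)
  for (i in seq_len(n)) {
    ii <- tryCatch(.atom_index(a, restraints$res_i[i], restraints$atom_i[i]),
                   error = function(e)
                     stop("restraint ", i, ": ", conditionMessage(e),
                          call. = FALSE))
    jj <- tryCatch(.atom_index(a, restraints$res_j[i], restraints$atom_j[i]),
                   error = function(e)
                     stop("restraint ", i, ": ", conditionMessage(e),
                          call. = FALSE))
    d <- vapply(ensemble$xyz,
                function(m) sqrt(sum((m[ii, ] - m[jj, ])^2)), 0)
    mat[i, ] <- forward_signal(d)
  }
  mat
}

#' Relative average signals of an ensemble
#'
#' `ratio_i = sum_t w_t f(d_{i,t}) / f_exp_i`. A ratio below 1 means the
#' weighted ensemble average falls short of the threshold signal, i.e. the
#' upper-distance bound is violated.
#'
#' @param signals Signal matrix from [build_signal_matrix()].
#' @param restraints A `noe_restraints` table (or numeric `f_exp` vector).
#' @param weights Snapshot weights (nonnegative, renormalized; default
#'   uniform).
#' @return Numeric vector of per-restraint ratios.
#' @export
relative_signals <- function(signals, restraints, weights = NULL) {
  f_exp <- if (is.numeric(restraints)) restraints else restraints$f_exp
  stopifnot(length(f_exp) == nrow(signals))
  w <- .check_weights(weights, ncol(signals), "weights")
  as.numeric(signals %*% w) / f_exp
}

#' Count violated restraints
#'
#' @param ratios Relative signals from [relative_signals()].
#' @return Number of restraints with ratio strictly below 1.
#' @export
count_violations <- function(ratios) {
  if (any(!is.finite(ratios))) stop("'ratios' must be finite", call. = FALSE)
  sum(ratios < 1)
}

#' Aggregate violation score of an ensemble
#'
#' The default (and currently only) mode sums the shortfalls,
#' `sum_i max(0, 1 - ratio_i)`; satisfied restraints contribute zero, so
#' adding a satisfied restraint never increases the score. The mode is
#' recorded in pipeline output metadata.
#'
#' @param ratios Relative signals.
#' @param mode Scoring mode identifier; `"shortfall"`.
#' @return Nonnegative scalar.
#' @export
violation_score <- function(ratios, mode = "shortfall") {
  if (any(!is.finite(ratios))) stop("'ratios' must be finite", call. = FALSE)
  if (!identical(mode, "shortfall"))
    stop("unknown violation score mode: ", mode, call. = FALSE)
  sum(pmax(0, 1 - ratios))
}

#' Tabular violation report for one ensemble
#'
#' One row per restraint with its pair label, class, threshold distance,
#' relative signal and violation flag; optionally filtered to "critical"
#' restraints whose ratio is below a cutoff (e.g. 1.2).
#'
#' @param restraints A `noe_restraints` table.
#' @param ratios Relative signals for the same restraints.
#' @param critical Optional ratio cutoff; rows at or above it are dropped.
#' @return Data frame with columns `pair`, `class`, `d_exp`, `ratio`,
#'   `violated`.
#' @export
violation_report <- function(restraints, ratios, critical = NULL) {
  stopifnot(length(ratios) == nrow(restraints))
  out <- data.frame(
    pair = paste0(restraints$res_i, "_", restraints$atom_i, "-",
                  restraints$res_j, "_", restraints$atom_j),
    class = restraints$class,
    d_exp = restraints$d_exp,
    ratio = ratios,
    violated = ratios < 1,
    stringsAsFactors = FALSE)
  if (!is.null(critical)) out <- out[out$ratio < critical, , drop = FALSE]
  rownames(out) <- NULL
  out
}
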