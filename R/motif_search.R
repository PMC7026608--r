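# Sequence-independent structural motif search.
#
# A query fragment (by default a hairpin loop window) is searched against a
# library of PDB structures by sliding a window of the same length over every
# chain of every model and comparing with the eRMSD. Scanning the whole
# ensemble against the whole library is avoided using the metric's triangle
# inequality: searching only the ensemble centroid with the threshold
# "base cutoff + max distance centroid-to-ensemble" is guaranteed to retain
# every library window within the base cutoff of ANY ensemble member; the
# exact per-snapshot matches are then recovered by a refinement pass over the
# candidates only.

#' Extract a contiguous residue window as a fragment
#'
#' Returns the sub-structure of `length` consecutive residues starting at
#' `start`, with residues renumbered 1..length (author numbering preserved).
#'
#' @param snapshot A `noe_snapshot`.
#' @param start First residue (1-based sequence position).
#' @param length Number of residues.
#' @param chain Optional chain identifier (default: the snapshot's first
#'   chain).
#' @return A `noe_snapshot` restricted to the window, with attributes
#'   `source_start` and `source_chain`.
#' @export
extract_fragment <- function(snapshot, start, length, chain = NULL) {
  a <- snapshot$atoms
  if (is.null(chain)) chain <- a$chain[1L]
  res <- sort(unique(a$resno[a$chain == chain]))
  window <- seq(start, start + length - 1L)
  if (start < 1L || !all(window %in% res))
    stop("fragment window [", start, ", ", start + length - 1L,
         "] out of range for chain ", chain, " (residues ", min(res), "-",
         max(res), ")", call. = FALSE)
  keep <- which(a$chain == chain & a$resno %in% window)
  atoms <- a[keep, , drop = FALSE]
  atoms$resno <- atoms$resno - start + 1L
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 xyz = snapshot$xyz[keep, , drop = FALSE],
                 model_id = snapshot$model_id),
            class = "noe_snapshot",
            source_start = start, source_chain = chain)
}

#' Extract the same fragment window from every snapshot of an ensemble
#'
#' @param ensemble A `noe_ensemble`.
#' @inheritParams extract_fragment
#' @return List of fragment `noe_snapshot`s.
#' @export
fragment_ensemble <- function(ensemble, start, length, chain = NULL) {
  lapply(seq_len(n_snapshots(ensemble)), function(t)
    extract_fragment(get_snapshot(ensemble, t), start, length, chain))
}

#' Backbone connectivity check of a fragment
#'
#' TRUE iff, for every consecutive residue pair (i, i+1), the O3'(i)-P(i+1)
#' distance is at most `bond_max` -- i.e. the residues lie covalently linked
#' on one strand. Fragments missing O3' or P atoms fail the check.
#'
#' @param fragment A `noe_snapshot` (typically from [extract_fragment()]).
#' @param bond_max Maximum O3'-P distance in Angstrom (default 2.0; the
#'   covalent bond is about 1.6).
#' @return Logical scalar.
#' @export
check_connectivity <- function(fragment, bond_max = 2.0) {
  res <- sort(unique(fragment$atoms$resno))
  if (length(res) < 2L) return(TRUE)
  for (k in seq_len(length(res) - 1L)) {
    d <- tryCatch(proton_distance(fragment, res[k], "O3'", res[k + 1L], "P"),
                  error = function(e) Inf)
    if (!(d <= bond_max)) return(FALSE)
  }
  TRUE
}

#' Triangle-inequality prefilter threshold
#'
#' `base_cutoff + max_t eRMSD(centroid, fragment_t)`: any library window
#' within `base_cutoff` of some ensemble fragment must lie within this
#' threshold of the centroid.
#'
#' @param centroid The centroid fragment.
#' @param ensemble_fragments List of ensemble fragments (same window).
#' @param base_cutoff Final match cutoff (default 1.0).
#' @return Scalar threshold.
#' @export
prefilter_threshold <- function(centroid, ensemble_fragments,
                                base_cutoff = 1.0) {
  stopifnot(length(ensemble_fragments) >= 1L)
  base_cutoff + max(vapply(ensemble_fragments,
                           function(f) ermsd(centroid, f), 0))
}

#' Scan a structure library for windows similar to a query fragment
#'
#' Slides a window of the query's length over every chain of every model of
#' every library structure; windows that are backbone-connected and lie
#' within `threshold` eRMSD of the query are returned as candidates. Entries
#' that cannot be parsed (or contain unsupported residues) are skipped with a
#' warning. Results are sorted canonically (structure, model, chain, start),
#' so they do not depend on file ordering.
#'
#' @param centroid Query fragment (a `noe_snapshot`).
#' @param library A directory of PDB files, a character vector of file paths,
#'   or a named list of `noe_ensemble` objects.
#' @param threshold eRMSD acceptance threshold for the scan (strict `<`);
#'   typically from [prefilter_threshold()].
#' @param bond_max Connectivity cutoff passed to [check_connectivity()].
#' @return Object of class `motif_candidates`: list with `meta` (data frame:
#'   `structure`, `model`, `chain`, `start`, `start_author`,
#'   `ermsd_centroid`) and `fragments` (list of fragment snapshots, same
#'   order).
#' @export
search_library <- function(centroid, library, threshold, bond_max = 2.0) {
  L <- nrow(residue_table(centroid))
  entries <- .load_library(library)
  meta <- list()
  frags <- list()
  for (nm in names(entries)) {
    ens <- entries[[nm]]
    for (t in seq_len(n_snapshots(ens))) {
      snap <- get_snapshot(ens, t)
      for (ch in unique(snap$atoms$chain)) {
        res <- sort(unique(snap$atoms$resno[snap$atoms$chain == ch]))
        if (length(res) < L) next
        for (s in res[seq_len(length(res) - L + 1L)]) {
          fr <- tryCatch(extract_fragment(snap, s, L, ch),
                         error = function(e) NULL)
          if (is.null(fr) || !check_connectivity(fr, bond_max)) next
          e <- tryCatch(ermsd(centroid, fr), error = function(e) NA_real_)
          if (is.na(e) || e >= threshold) next
          meta <- c(meta, list(data.frame(
            structure = nm, model = t, chain = ch, start = s,
            start_author = fr$atoms$resno_author[1L],
            ermsd_centroid = e, stringsAsFactors = FALSE)))
          frags <- c(frags, list(fr))
        }
      }
    }
  }
  if (!length(meta))
    return(structure(list(meta = data.frame(), fragments = list()),
                     class = "motif_candidates"))
  meta <- do.call(rbind, meta)
  ord <- order(meta$structure, meta$model, meta$chain, meta$start)
  structure(list(meta = meta[ord, , drop = FALSE], fragments = frags[ord]),
            class = "motif_candidates")
}

.load_library <- function(library) {
  if (is.list(library) && all(vapply(library, inherits, TRUE, "noe_ensemble"))) {
    if (is.null(names(library)))
      names(library) <- sprintf("entry%03d", seq_along(library))
    return(library)
  }
  files <- if (length(library) == 1L && dir.exists(library))
    sort(list.files(library, pattern = "\\.pdb$", full.names = TRUE))
  else library
  out <- list()
  for (f in files) {
    ens <- tryCatch(read_ensemble(f), error = function(e) {
      warning("skipping unparsable library entry ", basename(f), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(ens)) out[[sub("\\.pdb$", "", basename(f))]] <- ens
  }
  out
}

#' Refine prefilter candidates against the full ensemble
#'
#' Computes the eRMSD between every candidate window and every ensemble
#' fragment and keeps candidate/snapshot pairs strictly below the cutoff. By
#' the triangle inequality, no window outside the prefiltered candidates can
#' form such a pair, so the result equals an exhaustive all-pairs scan.
#'
#' @param candidates A `motif_candidates` object from [search_library()].
#' @param ensemble_fragments List of ensemble fragments (same window as the
#'   query).
#' @param cutoff Final match cutoff (default 1.0, strict `<`).
#' @return Object of class `motif_matches`: data frame with one row per
#'   retained candidate (`structure`, `model`, `chain`, `start`,
#'   `start_author`, `min_ermsd`, `n_matching_snapshots`, `chi`), with the
#'   per-pair table in `attr(, "pairs")` and the fragments in
#'   `attr(, "fragments")`.
#' @export
refine_matches <- function(candidates, ensemble_fragments, cutoff = 1.0) {
  meta <- candidates$meta
  empty <- data.frame(structure = character(0), model = integer(0),
                      chain = character(0), start = integer(0),
                      start_author = integer(0), min_ermsd = numeric(0),
                      n_matching_snapshots = integer(0), chi = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(meta)) {
    attr(empty, "pairs") <- data.frame()
    attr(empty, "fragments") <- list()
    class(empty) <- c("motif_matches", class(empty))
    return(empty)
  }
  pairs <- list()
  rows <- list()
  frags <- list()
  for (k in seq_len(nrow(meta))) {
    fr <- candidates$fragments[[k]]
    e <- vapply(ensemble_fragments, function(f) ermsd(fr, f), 0)
    hit <- which(e < cutoff)
    if (!length(hit)) next
    pairs <- c(pairs, list(data.frame(candidate = length(rows) + 1L,
                                      snapshot = hit, ermsd = e[hit])))
    row <- meta[k, , drop = FALSE]
    row$min_ermsd <- min(e[hit])
    row$n_matching_snapshots <- length(hit)
    row$chi <- chi_conformation(fr)
    row$ermsd_centroid <- NULL
    rows <- c(rows, list(row))
    frags <- c(frags, list(fr))
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "pairs") <- if (length(pairs)) do.call(rbind, pairs)
                        else data.frame()
  attr(out, "fragments") <- frags
  class(out) <- c("motif_matches", class(out))
  out
}

#' Keep only matches with the query's chi conformation
#'
#' Exact bitstring equality over the fragment window.
#'
#' @param matches A `motif_matches` object.
#' @param query_conformation Bitstring of the query fragment
#'   (see [chi_conformation()]).
#' @return The filtered `motif_matches`.
#' @export
filter_chi <- function(matches, query_conformation) {
  keep <- matches$chi == query_conformation
  out <- matches[keep, , drop = FALSE]
  pairs <- attr(matches, "pairs")
  if (nrow(out) && nrow(pairs)) {
    idx <- which(keep)
    pairs <- pairs[pairs$candidate %in% idx, , drop = FALSE]
    pairs$candidate <- match(pairs$candidate, idx)
  } else pairs <- data.frame()
  rownames(out) <- NULL
  attr(out, "pairs") <- pairs
  attr(out, "fragments") <- attr(matches, "fragments")[keep]
  class(out) <- unique(c("motif_matches", class(out)))
  out
}
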