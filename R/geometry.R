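# Glycosidic torsions, syn/anti bitstrings, the eRMSD metric and centroids.
#
# The eRMSD compares two nucleic-acid structures through the relative
# arrangement of their bases rather than through superposition. Each base
# carries a local orthonormal frame centred in its six-membered ring; the
# position of every other base in that frame is scaled anisotropically
# (x/5, y/5, z/3 Angstrom, flattening the stacking direction), mapped through
# a smooth vector function G with a cutoff at scaled distance 2.4, and the
# metric is the root-mean-square difference of all pairwise G vectors. Two
# structures below eRMSD 0.7 have an essentially identical base-base contact
# map, which is what makes 0.7 a natural clustering cutoff and 1.0 a motif
# similarity cutoff.

.ermsd_scale <- c(5, 5, 3)   # Angstrom; anisotropic ellipsoid axes
.ermsd_cutoff <- 2.4         # cutoff in scaled-distance units

# ring atoms defining the base frame; the order differs between families so
# that the frame handedness is consistent across purines and pyrimidines
.ring_atoms <- function(base) {
  if (base == "purine") c("C2", "C6", "C4") else c("C2", "C4", "C6")
}

# atoms defining the glycosidic torsion chi
.chi_atoms <- function(base) {
  if (base == "purine") c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
}

.torsion <- function(p1, p2, p3, p4) {
  as.numeric(bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4L))
}

#' Glycosidic torsion angle of one residue
#'
#' The standard chi dihedral: O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for
#' pyrimidines, reported in degrees wrapped to `[0, 360)`. This range makes
#' the syn window `0 < chi < 115` directly applicable, with high-anti
#' conformations (~270-300 degrees) falling in the anti class.
#'
#' @param snapshot A `noe_snapshot`.
#' @param residue Residue sequence position (1-based).
#' @param chain Optional chain identifier.
#' @return Angle in degrees in `[0, 360)`.
#' @export
chi_angle <- function(snapshot, residue, chain = NULL) {
  rt <- residue_table(snapshot)
  row <- rt[rt$resno == residue &
              (if (is.null(chain)) TRUE else rt$chain == chain), , drop = FALSE]
  if (nrow(row) != 1L)
    stop("residue ", residue, " does not resolve uniquely", call. = FALSE)
  nm <- .chi_atoms(row$base)
  idx <- tryCatch(vapply(nm, function(a)
    .atom_index(snapshot$atoms, residue, a, chain), 1L),
    error = function(e) stop("chi atoms missing for residue ", residue, ": ",
                             conditionMessage(e), call. = FALSE))
  .wrap360(.torsion(snapshot$xyz[idx[1L], ], snapshot$xyz[idx[2L], ],
                    snapshot$xyz[idx[3L], ], snapshot$xyz[idx[4L], ]))
}

#' Classify a glycosidic angle as syn (1) or anti/high-anti (0)
#'
#' The syn window is the open interval `0 < chi < 115` degrees; the boundary
#' values themselves classify as anti.
#'
#' @param chi Angle(s) in degrees, in `[0, 360)`.
#' @return Integer 0/1 vector.
#' @export
syn_bit <- function(chi) {
  if (any(!is.finite(chi)) || any(chi < 0) || any(chi >= 360))
    stop("'chi' must be finite and in [0, 360)", call. = FALSE)
  as.integer(chi > 0 & chi < 115)
}

#' Per-residue syn/anti bitstring of a snapshot
#'
#' Concatenates [syn_bit()] of every residue's [chi_angle()] in residue order;
#' position r of the string is 1 iff residue r is syn. Snapshots with
#' different bitstrings belong to different conformational pre-clusters.
#'
#' @param snapshot A `noe_snapshot`.
#' @param residues Optional subset of residue positions (default: all, in
#'   order).
#' @param chain Optional chain identifier.
#' @return Character scalar over `{0,1}`.
#' @export
chi_conformation <- function(snapshot, residues = NULL, chain = NULL) {
  rt <- residue_table(snapshot)
  if (!is.null(chain)) rt <- rt[rt$chain == chain, , drop = FALSE]
  res <- if (is.null(residues)) rt$resno else residues
  paste(vapply(res, function(r) syn_bit(chi_angle(snapshot, r, chain)), 1L),
        collapse = "")
}

# local base frames of one snapshot: list(origins = n x 3, rot = list of 3x3
# matrices with rows x,y,z)
.base_frames <- function(snapshot, chain = NULL) {
  rt <- residue_table(snapshot)
  if (!is.null(chain)) rt <- rt[rt$chain == chain, , drop = FALSE]
  n <- nrow(rt)
  origins <- matrix(NA_real_, n, 3L)
  rot <- vector("list", n)
  for (k in seq_len(n)) {
    nm <- .ring_atoms(rt$base[k])
    idx <- tryCatch(vapply(nm, function(a)
      .atom_index(snapshot$atoms, rt$resno[k], a, rt$chain[k]), 1L),
      error = function(e) stop("base ring atoms missing for residue ",
                               rt$resno[k], ": ", conditionMessage(e),
                               call. = FALSE))
    p <- snapshot$xyz[idx, , drop = FALSE]
    o <- colMeans(p)
    x <- .unit(p[1L, ] - o)
    z <- .unit(.cross(p[1L, ] - o, p[2L, ] - o))
    y <- .cross(z, x)
    origins[k, ] <- o
    rot[[k]] <- rbind(x, y, z)
  }
  list(origins = origins, rot = rot)
}

# flattened G-vector representation (length 4*n*n) of one snapshot
.gvectors <- function(snapshot, chain = NULL) {
  fr <- .base_frames(snapshot, chain)
  n <- nrow(fr$origins)
  gamma <- pi / .ermsd_cutoff
  G <- array(0, c(n, n, 4L))
  for (j in seq_len(n)) {
    rel <- sweep(fr$origins, 2L, fr$origins[j, ])
    loc <- rel %*% t(fr$rot[[j]])
    loc <- sweep(loc, 2L, .ermsd_scale, "/")
    eps <- sqrt(rowSums(loc * loc))
    for (k in seq_len(n)) {
      if (k == j) next
      e <- eps[k]
      if (e < .ermsd_cutoff)
        G[j, k, ] <- c(sin(gamma * e) * loc[k, ] / e, 1 + cos(gamma * e)) / gamma
    }
  }
  as.numeric(G)
}

#' eRMSD between two snapshots
#'
#' Base-arrangement metric between two structures with the same number of
#' nucleotides: the root-mean-square (over residues) difference of the
#' pairwise G vectors described in the package geometry documentation. It is
#' zero for identical coordinates, symmetric, invariant under rigid motions,
#' and satisfies the triangle inequality -- the property the motif-search
#' prefilter relies on.
#'
#' @param a,b `noe_snapshot` objects with equal nucleotide counts.
#' @return Nonnegative scalar.
#' @export
ermsd <- function(a, b) {
  na <- nrow(residue_table(a))
  nb <- nrow(residue_table(b))
  if (na != nb)
    stop("snapshots are not comparable: ", na, " vs ", nb, " residues",
         call. = FALSE)
  sqrt(sum((.gvectors(a) - .gvectors(b))^2) / na)
}

#' Pairwise eRMSD matrix of an ensemble
#'
#' Computes the G-vector representation of every snapshot once and derives all
#' pairwise eRMSD values from Euclidean distances between the flattened
#' representations, which keeps the cost linear in T for the representation
#' and quadratic only in a cheap vector norm.
#'
#' @param x A `noe_ensemble`, or a list of `noe_snapshot` objects (e.g.
#'   fragments).
#' @return A symmetric T-by-T matrix of class `ermsd_cache` with zero
#'   diagonal.
#' @export
ermsd_matrix <- function(x) {
  snaps <- if (inherits(x, "noe_ensemble"))
    lapply(seq_len(n_snapshots(x)), function(t) get_snapshot(x, t))
  else x
  n_res <- nrow(residue_table(snaps[[1L]]))
  G <- t(vapply(snaps, .gvectors, numeric(4L * n_res * n_res)))
  d <- as.matrix(dist(G)) / sqrt(n_res)
  dimnames(d) <- NULL
  class(d) <- c("ermsd_cache", class(d))
  d
}

#' Persist / restore a pairwise eRMSD matrix as plain text
#'
#' @param cache An `ermsd_cache` matrix.
#' @param path File path.
#' @return `path` invisibly (write), or the matrix (read).
#' @export
write_ermsd_cache <- function(cache, path) {
  write.table(format(unclass(cache), digits = 10), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ermsd_cache
#' @export
read_ermsd_cache <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  class(m) <- c("ermsd_cache", class(m))
  m
}

#' Centroid snapshot of an ensemble
#'
#' Index of the snapshot with the minimum mean square eRMSD to all other
#' snapshots; ties are broken by the lowest index.
#'
#' @param cache Pairwise `ermsd_cache` matrix (see [ermsd_matrix()]).
#' @return Snapshot index (1-based).
#' @export
centroid_index <- function(cache) {
  which.min(rowSums(unclass(cache)^2))
}
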