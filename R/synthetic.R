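# Synthetic fixtures with planted ground truth.
#
# The generator emulates the features of a real NMR/MD ensemble that the
# analysis stages consume -- and nothing more: a short RNA-like chain whose
# residues carry exactly the atoms the implemented metrics touch (glycosidic
# chi atoms, base six-ring atoms for the eRMSD, H1'/H6/H8 protons for NOEs,
# O3'/P for backbone connectivity), built from an idealized planar-base
# template via internal coordinates. Metastable states are planted as
# per-residue syn/anti chi targets plus an optional backbone hinge bend;
# within-state coordinate noise is kept small enough that states are
# eRMSD-separable (verified post hoc), mirroring the clusterable sub-states
# of a real loop ensemble.

#' Specify one planted conformational state
#'
#' @param id State identifier.
#' @param chi Per-residue target glycosidic angles in degrees (syn targets
#'   must stay below, anti targets above, the 115-degree boundary by more
#'   than the jitter margin).
#' @param population Planted population (the states of an ensemble must sum
#'   to 1).
#' @param bend Hinge bend in degrees applied to the second half of the chain
#'   (distinguishes states that share a chi pattern).
#' @return A list of class `state_spec`.
#' @export
state_spec <- function(id, chi, population, bend = 0) {
  stopifnot(is.numeric(chi), all(chi >= 0), all(chi < 360),
            population >= 0, population <= 1)
  structure(list(id = id, chi = chi, population = population, bend = bend),
            class = "state_spec")
}

# idealized nucleotide template: returns list(names, base, xyz) for one
# residue with glycosidic angle chi (degrees); i is the 0-based residue index
.residue_spacing <- 4.6

.build_residue <- function(i, chi, purine) {
  s <- .residue_spacing
  P <- c(s * i, 0, 0)
  O3p <- c(s * i + s - 1.6, 0, 0)
  C1p <- c(s * i + 1.8, 2.6, 0.4)
  O4p <- C1p + 1.41 * .unit(c(-0.75, 0.45, 0.45))
  N <- C1p + 1.48 * .unit(c(0.55, 0.75, -0.35))
  pos <- list("P" = P, "O3'" = O3p, "C1'" = C1p, "O4'" = O4p)
  pos[["H1'"]] <- .place_atom(N, O4p, C1p, 1.09, 109, 235)
  if (purine) {
    pos[["N9"]] <- N
    pos[["C4"]] <- .place_atom(O4p, C1p, N, 1.37, 126, chi)
    pos[["C5"]] <- .place_atom(C1p, N, pos[["C4"]], 1.40, 120, 180)
    pos[["C6"]] <- .place_atom(N, pos[["C4"]], pos[["C5"]], 1.40, 120, 0)
    pos[["N1"]] <- .place_atom(pos[["C4"]], pos[["C5"]], pos[["C6"]],
                               1.35, 120, 0)
    pos[["C2"]] <- .place_atom(pos[["C5"]], pos[["C6"]], pos[["N1"]],
                               1.35, 120, 0)
    pos[["N3"]] <- .place_atom(pos[["C6"]], pos[["N1"]], pos[["C2"]],
                               1.35, 120, 0)
    pos[["C8"]] <- .place_atom(pos[["C5"]], pos[["C4"]], N, 1.37, 106, 0)
    pos[["H8"]] <- .place_atom(pos[["C4"]], N, pos[["C8"]], 1.08, 125, 180)
  } else {
    pos[["N1"]] <- N
    pos[["C2"]] <- .place_atom(O4p, C1p, N, 1.38, 118, chi)
    pos[["N3"]] <- .place_atom(C1p, N, pos[["C2"]], 1.36, 120, 180)
    pos[["C4"]] <- .place_atom(N, pos[["C2"]], pos[["N3"]], 1.36, 120, 0)
    pos[["C5"]] <- .place_atom(pos[["C2"]], pos[["N3"]], pos[["C4"]],
                               1.36, 120, 0)
    pos[["C6"]] <- .place_atom(pos[["N3"]], pos[["C4"]], pos[["C5"]],
                               1.36, 120, 0)
    pos[["H6"]] <- .place_atom(pos[["C4"]], pos[["C5"]], pos[["C6"]],
                               1.08, 120, 180)
  }
  list(names = names(pos), xyz = do.call(rbind, pos))
}

# build a full toy snapshot; chis in degrees per residue; sequence of
# one-letter residue names; bend in degrees about a z-hinge at mid-chain
.build_toy_snapshot <- function(chis, sequence, bend = 0, noise = 0) {
  n <- length(chis)
  stopifnot(length(sequence) == n)
  purine <- .base_family(sequence) == "purine"
  names_all <- character(0)
  res_all <- integer(0)
  xyz <- NULL
  for (r in seq_len(n)) {
    res <- .build_residue(r - 1L, chis[r], purine[r])
    names_all <- c(names_all, res$names)
    res_all <- c(res_all, rep(r, length(res$names)))
    xyz <- rbind(xyz, res$xyz)
  }
  if (bend != 0) {
    h <- ceiling(n / 2)
    hinge <- c(.residue_spacing * (h - 0.5), 0, 0)
    th <- bend * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
    mov <- res_all > h
    xyz[mov, ] <- sweep(sweep(xyz[mov, , drop = FALSE], 2L, hinge) %*% t(R),
                        2L, hinge, "+")
  }
  if (noise > 0) xyz <- xyz + matrix(rnorm(length(xyz), sd = noise),
                                     ncol = 3L)
  atoms <- data.frame(chain = "A", resno = res_all, resno_author = res_all,
                      resname = sequence[res_all], elety = names_all,
                      base = ifelse(purine[res_all], "purine", "pyrimidine"),
                      stringsAsFactors = FALSE)
  rownames(xyz) <- NULL
  list(atoms = atoms, xyz = xyz)
}

# jitter a chi target without approaching the syn/anti boundary
.jitter_chi <- function(target, jitter, margin = 10) {
  x <- target + runif(length(target), -jitter, jitter)
  syn <- target < 115
  x[syn] <- pmin(pmax(x[syn], 5), 115 - margin)
  x[!syn] <- pmin(pmax(x[!syn], 115 + margin), 355)
  x
}

#' Generate a toy multi-state ensemble with known ground truth
#'
#' Draws snapshots from the planted states (multinomially, with the planted
#' populations), builds coordinates from the idealized nucleotide template
#' with per-snapshot chi jitter and coordinate noise, and verifies post hoc
#' that the states are eRMSD-separable at the clustering cutoff: all
#' within-state pairs below `cutoff`, all between-state pairs above it. If
#' separation fails, the ensemble is regenerated (fresh jitter draws) up to
#' `max_attempts` times before erroring.
#'
#' @param n_residues Chain length.
#' @param states List of [state_spec()] objects; populations must sum to 1
#'   and each `chi` must have `n_residues` entries.
#' @param n_snapshots Number of snapshots T.
#' @param seed Integer seed; the same seed reproduces the ensemble
#'   bit-identically.
#' @param sequence One-letter residue names (default: alternating G/U).
#' @param noise Coordinate noise s.d. in Angstrom (default 0.06).
#' @param chi_jitter Half-width of the uniform chi jitter in degrees
#'   (default 8; kept 10 degrees clear of the 115-degree boundary).
#' @param cutoff Separation cutoff used for the post-hoc check (default
#'   0.7).
#' @param max_attempts Regeneration attempts before giving up.
#' @return List with `ensemble` (a `noe_ensemble`, uniform prior),
#'   `labels` (integer state index per snapshot), `states` and `seed`.
#' @export
generate_toy_ensemble <- function(n_residues, states, n_snapshots, seed,
                                  sequence = NULL, noise = 0.06,
                                  chi_jitter = 8, cutoff = 0.7,
                                  max_attempts = 10L) {
  stopifnot(length(states) >= 1L)
  pops <- vapply(states, `[[`, 0, "population")
  if (abs(sum(pops) - 1) > 1e-9)
    stop("state populations must sum to 1", call. = FALSE)
  for (st in states)
    if (length(st$chi) != n_residues)
      stop("state '", st$id, "' must specify chi for all ", n_residues,
           " residues", call. = FALSE)
  if (is.null(sequence))
    sequence <- rep(c("G", "U"), length.out = n_residues)
  set.seed(seed)
  labels <- sample(seq_along(states), n_snapshots, replace = TRUE,
                   prob = pops)
  for (attempt in seq_len(max_attempts)) {
    xyz <- vector("list", n_snapshots)
    atoms <- NULL
    for (t in seq_len(n_snapshots)) {
      st <- states[[labels[t]]]
      snap <- .build_toy_snapshot(.jitter_chi(st$chi, chi_jitter), sequence,
                                  bend = st$bend, noise = noise)
      if (is.null(atoms)) atoms <- snap$atoms
      xyz[[t]] <- snap$xyz
    }
    ens <- noe_ensemble(atoms, xyz)
    if (length(states) == 1L || n_snapshots == 1L ||
        .states_separated(ens, labels, cutoff))
      return(list(ensemble = ens, labels = labels, states = states,
                  seed = seed))
  }
  stop("could not generate eRMSD-separated states in ", max_attempts,
       " attempts; reduce noise/chi_jitter or increase state contrast",
       call. = FALSE)
}

.states_separated <- function(ensemble, labels, cutoff) {
  d <- ermsd_matrix(ensemble)
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  within_ok <- all(d[which(same)] < cutoff)
  between <- d[which(!same)]
  within_ok && (!length(between) || all(between > cutoff))
}

#' Derive a feasible NOE restraint set from a planted mixture
#'
#' For a panel of chi-sensitive proton pairs (intra-residue base-H to H1'
#' and sequential base-H to previous H1'), sets each threshold signal to
#' `(1 - slack)` times the planted-mixture average signal
#' `sum_s p_s <f>_s`, so the planted ensemble is feasible by construction
#' while individual states generally are not. In class mode, the implied
#' maximum distance is snapped to the nearest signal-class distance not
#' below it (3.6 / 5.0 / 6.5 A), which preserves the feasibility guarantee;
#' pairs beyond 6.5 A are dropped with a message.
#'
#' @param ensemble A toy `noe_ensemble`.
#' @param labels Integer state labels per snapshot.
#' @param populations Planted state populations (same order as state
#'   indices).
#' @param slack Fractional slack on the thresholds (default 0.02).
#' @param classes Snap thresholds to signal-class distances (default
#'   `FALSE`: explicit `d_exp`).
#' @return A `noe_restraints` table.
#' @export
generate_mixture_restraints <- function(ensemble, labels, populations,
                                        slack = 0.02, classes = FALSE) {
  stopifnot(length(labels) == n_snapshots(ensemble),
            abs(sum(populations) - 1) < 1e-9, slack >= 0, slack < 1)
  rt <- residue_table(ensemble)
  hb <- ifelse(rt$base == "purine", "H8", "H6")
  pairs <- data.frame(res_i = rt$resno, atom_i = hb,
                      res_j = rt$resno, atom_j = "H1'",
                      stringsAsFactors = FALSE)
  if (nrow(rt) > 1L)
    pairs <- rbind(pairs, data.frame(
      res_i = rt$resno[-1L], atom_i = hb[-1L],
      res_j = rt$resno[-nrow(rt)], atom_j = "H1'",
      stringsAsFactors = FALSE))
  probe <- noe_restraints(pairs$res_i, pairs$atom_i, pairs$res_j,
                          pairs$atom_j, d_exp = 1)
  mat <- build_signal_matrix(ensemble, probe)
  state_means <- vapply(seq_along(populations), function(s) {
    idx <- which(labels == s)
    if (!length(idx)) rep(0, nrow(mat))
    else rowMeans(mat[, idx, drop = FALSE])
  }, numeric(nrow(mat)))
  f_mix <- as.numeric(state_means %*% populations)
  f_exp <- (1 - slack) * f_mix
  d_exp <- 10 * f_exp^(-1 / 6)
  if (classes) {
    cls <- c(3.6, 5.0, 6.5)
    lab <- c("s", "m", "l")
    snap_up <- vapply(d_exp, function(d) {
      ok <- which(cls >= d)
      if (length(ok)) ok[1L] else NA_integer_
    }, 1L)
    drop <- is.na(snap_up)
    if (any(drop))
      message(sum(drop), " pair(s) beyond the weak-class distance were dropped")
    noe_restraints(pairs$res_i[!drop], pairs$atom_i[!drop],
                   pairs$res_j[!drop], pairs$atom_j[!drop],
                   class = lab[snap_up[!drop]])
  } else {
    noe_restraints(pairs$res_i, pairs$atom_i, pairs$res_j, pairs$atom_j,
                   d_exp = d_exp)
  }
}

#' Write a complete synthetic fixture to disk
#'
#' Multi-model PDB + restraint CSV + ground-truth JSON (state labels,
#' populations, seed), self-contained for pipeline runs.
#'
#' @param dir Output directory.
#' @param n_residues,states,n_snapshots,seed Passed to
#'   [generate_toy_ensemble()].
#' @param slack,classes Passed to [generate_mixture_restraints()].
#' @param ... Further arguments to [generate_toy_ensemble()].
#' @return Invisibly, a list of the paths written.
#' @export
write_synthetic_fixture <- function(dir, n_residues, states, n_snapshots,
                                    seed, slack = 0.02, classes = FALSE,
                                    ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- generate_toy_ensemble(n_residues, states, n_snapshots, seed, ...)
  pops <- vapply(toy$states, `[[`, 0, "population")
  restr <- generate_mixture_restraints(toy$ensemble, toy$labels, pops,
                                       slack = slack, classes = classes)
  paths <- list(ensemble = file.path(dir, "ensemble.pdb"),
                restraints = file.path(dir, "restraints.csv"),
                truth = file.path(dir, "truth.json"))
  write_ensemble_pdb(toy$ensemble, paths$ensemble)
  write.table(restr[, c("res_i", "atom_i", "res_j", "atom_j", "class",
                        "d_exp")],
              paths$restraints, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = seed, labels = toy$labels, populations = pops,
         state_ids = vapply(toy$states, function(s) as.character(s$id), ""),
         slack = slack),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
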