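# Reading/writing multi-model structures and resolving atoms by
# (chain, residue, atom name).
#
# An ensemble is an ordered collection of T snapshots of one molecule that
# share a single topology (atom table); coordinates are stored per snapshot.
# Residues are indexed by 1-based sequence position within their chain; the
# author (PDB-file) numbering is retained in `resno_author` and reachable
# through map_residue_numbering().

#' Read a conformational ensemble from PDB input
#'
#' Reads a multi-model PDB file (MODEL/ENDMDL records, or a single implicit
#' model) or a directory of single/multi-model PDB files, taken in
#' lexicographic filename order and concatenated into one ensemble. All models
#' must share the same topology (same atoms in the same order). Alternate
#' locations other than blank/'A' are discarded; hydrogens must be present in
#' the input (NMR models carry them explicitly) -- no hydrogen building is
#' attempted.
#'
#' @param path Path to a PDB file or a directory containing `*.pdb` files.
#' @param prior_weights Optional per-snapshot prior weights (nonnegative,
#'   renormalized to sum 1). Default: uniform.
#' @return An object of class `noe_ensemble`: a list with elements `atoms`
#'   (topology data frame with columns `chain`, `resno` -- 1-based sequence
#'   position within chain -- `resno_author`, `resname`, `elety`, `base`),
#'   `xyz` (list of T numeric n_atoms-by-3 matrices, Angstrom), `prior`
#'   (numeric T) and `model_id`.
#' @seealso [get_snapshot()], [write_ensemble_pdb()], [proton_distance()]
#' @export
read_ensemble <- function(path, prior_weights = NULL) {
  if (length(path) != 1L || !is.character(path))
    stop("'path' must be a single file or directory path", call. = FALSE)
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) stop("no .pdb files in directory: ", path, call. = FALSE)
    parts <- lapply(files, .read_one_pdb)
    ens <- parts[[1L]]
    for (k in seq_along(parts)[-1L]) {
      if (!isTRUE(all.equal(parts[[k]]$atoms, ens$atoms)))
        stop("topology mismatch: file ", basename(files[k]),
             " differs from ", basename(files[1L]), call. = FALSE)
      ens$xyz <- c(ens$xyz, parts[[k]]$xyz)
    }
    ens$model_id <- seq_along(ens$xyz)
  } else {
    ens <- .read_one_pdb(path)
  }
  ens$prior <- .check_weights(prior_weights, length(ens$xyz), "prior_weights")
  class(ens) <- "noe_ensemble"
  ens
}

# name the first model whose ATOM count deviates from model 1, then stop
.topology_scan <- function(file, fallback_msg) {
  lines <- readLines(file, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    cnt <- mapply(function(s, e) sum(grepl("^ATOM  ", lines[s:e])),
                  starts, ends[seq_along(starts)])
    bad <- which(cnt != cnt[1L])
    if (length(bad))
      stop("inconsistent atom sets across models in ", basename(file),
           ": model ", bad[1L], " has ", cnt[bad[1L]],
           " ATOM records, model 1 has ", cnt[1L], call. = FALSE)
  }
  stop(fallback_msg, call. = FALSE)
}

.read_one_pdb <- function(file) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = TRUE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e)
      .topology_scan(file, paste0("failed to parse PDB file ", file, ": ",
                                  conditionMessage(e))))
  if (!is.null(dim(pdb$xyz)) && ncol(pdb$xyz) != 3L * nrow(pdb$atom))
    .topology_scan(file, paste0("coordinate/atom table mismatch in ", file))
  sel <- which(pdb$atom$type == "ATOM")
  if (!length(sel)) stop("no ATOM records in ", file, call. = FALSE)
  at <- pdb$atom[sel, , drop = FALSE]
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atoms <- data.frame(chain = chain,
                      resno_author = at$resno,
                      resname = trimws(at$resid),
                      elety = .normalize_elety(at$elety),
                      stringsAsFactors = FALSE)
  # 1-based sequence position within each chain, in order of appearance
  atoms$resno <- NA_integer_
  for (ch in unique(atoms$chain)) {
    i <- atoms$chain == ch
    atoms$resno[i] <- match(atoms$resno_author[i], unique(atoms$resno_author[i]))
  }
  atoms$base <- .base_family(atoms$resname)
  atoms <- atoms[, c("chain", "resno", "resno_author", "resname", "elety", "base")]

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- bio3d::atom2xyz(sel)
  snaps <- lapply(seq_len(nrow(xyz)), function(t) {
    m <- matrix(xyz[t, cols], ncol = 3L, byrow = TRUE)
    if (any(!is.finite(m)))
      stop("non-finite coordinates in model ", t, " of ", file, call. = FALSE)
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  list(atoms = atoms, xyz = snaps, prior = NULL,
       model_id = seq_along(snaps))
}

#' Construct an ensemble from a topology and coordinate list
#'
#' Low-level constructor used by the synthetic-fixture generator and by
#' fragment extraction; most users will call [read_ensemble()].
#'
#' @param atoms Topology data frame (see [read_ensemble()]).
#' @param xyz List of n_atoms-by-3 coordinate matrices.
#' @param prior_weights Optional prior weights.
#' @return A `noe_ensemble`.
#' @export
noe_ensemble <- function(atoms, xyz, prior_weights = NULL) {
  stopifnot(is.data.frame(atoms), is.list(xyz), length(xyz) >= 1L)
  for (m in xyz)
    stopifnot(is.matrix(m), nrow(m) == nrow(atoms), ncol(m) == 3L,
              all(is.finite(m)))
  structure(list(atoms = atoms, xyz = xyz,
                 prior = .check_weights(prior_weights, length(xyz), "prior_weights"),
                 model_id = seq_along(xyz)),
            class = "noe_ensemble")
}

#' Number of snapshots in an ensemble
#' @param ensemble A `noe_ensemble`.
#' @return Integer T.
#' @export
n_snapshots <- function(ensemble) length(ensemble$xyz)

#' Extract one snapshot from an ensemble
#'
#' @param ensemble A `noe_ensemble`.
#' @param t Snapshot index (1-based).
#' @return An object of class `noe_snapshot`: list with `atoms`, `xyz`
#'   (matrix) and `model_id`.
#' @export
get_snapshot <- function(ensemble, t) {
  if (t < 1L || t > n_snapshots(ensemble))
    stop("snapshot index out of range: ", t, call. = FALSE)
  structure(list(atoms = ensemble$atoms, xyz = ensemble$xyz[[t]],
                 model_id = ensemble$model_id[t]),
            class = "noe_snapshot")
}

#' Residue table of a snapshot or ensemble
#'
#' @param x A `noe_snapshot` or `noe_ensemble`.
#' @return Data frame with one row per residue: `chain`, `resno`,
#'   `resno_author`, `resname`, `base`.
#' @export
residue_table <- function(x) {
  a <- x$atoms
  r <- a[!duplicated(paste(a$chain, a$resno)),
         c("chain", "resno", "resno_author", "resname", "base")]
  rownames(r) <- NULL
  r
}

# resolve one atom to its row index in the atom table
.atom_index <- function(atoms, resno, elety, chain = NULL) {
  elety <- .normalize_elety(elety)
  hit <- which(atoms$resno == resno & atoms$elety == elety &
                 (if (is.null(chain)) TRUE else atoms$chain == chain))
  if (length(hit) != 1L)
    stop("cannot resolve atom '", elety, "' of residue ", resno,
         if (!is.null(chain)) paste0(" (chain ", chain, ")"),
         ": ", length(hit), " matches", call. = FALSE)
  hit
}

#' Distance between two protons (or any two atoms) in a snapshot
#'
#' Euclidean distance in Angstrom; symmetric in the argument order.
#'
#' @param snapshot A `noe_snapshot`.
#' @param res_i,atom_i Residue sequence position and atom name of the first
#'   atom. Unicode prime and apostrophe spellings are both accepted.
#' @param res_j,atom_j Likewise for the second atom.
#' @param chain Optional chain identifier (needed only for multi-chain
#'   structures).
#' @return Distance in Angstrom.
#' @export
proton_distance <- function(snapshot, res_i, atom_i, res_j, atom_j,
                            chain = NULL) {
  i <- .atom_index(snapshot$atoms, res_i, atom_i, chain)
  j <- .atom_index(snapshot$atoms, res_j, atom_j, chain)
  sqrt(sum((snapshot$xyz[i, ] - snapshot$xyz[j, ])^2))
}

#' Map between internal and author (PDB-file) residue numbering
#'
#' Internal residue indices are 1-based sequence positions within the chain.
#' Deposited structures often use an offset author numbering; for the SINEB2
#' hairpin entry 5LSN the hairpin residue 16 is PDB residue 79, i.e. offset 63.
#'
#' @param paper_index 1-based sequence position.
#' @param offset Integer offset added to the index (default 0; use 63 for the
#'   5LSN convention).
#' @param chain_length Optional chain length for range validation.
#' @return `paper_index + offset`.
#' @export
map_residue_numbering <- function(paper_index, offset = 0L,
                                  chain_length = NULL) {
  if (!is.numeric(paper_index) || any(paper_index != round(paper_index)))
    stop("'paper_index' must be integer-valued", call. = FALSE)
  if (any(paper_index < 1L))
    stop("residue index out of range: ", paste(paper_index[paper_index < 1L],
                                               collapse = ", "), call. = FALSE)
  if (!is.null(chain_length) && any(paper_index > chain_length))
    stop("residue index exceeds chain length ", chain_length, call. = FALSE)
  as.integer(paper_index + offset)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per snapshot, fixed-width PDB ATOM records,
#' coordinates to 3 decimals. The author residue numbering is written out.
#'
#' @param ensemble A `noe_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  a <- ensemble$atoms
  name4 <- ifelse(nchar(a$elety) < 4L, paste0(" ", a$elety), a$elety)
  elem <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", a$elety)),
                         1L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_snapshots(ensemble))) {
    writeLines(sprintf("MODEL     %4d", t), con)
    m <- ensemble$xyz[[t]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, a$resname, a$chain, a$resno_author,
      m[, 1L], m[, 2L], m[, 3L], 1, 0, elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.noe_ensemble <- function(x, ...) {
  r <- residue_table(x)
  cat("noe_ensemble:", n_snapshots(x), "snapshot(s),", nrow(r), "residue(s),",
      nrow(x$atoms), "atoms\n")
  cat("  chains:", paste(unique(r$chain), collapse = " "), "\n")
  cat("  prior weights:",
      if (max(x$prior) - min(x$prior) < 1e-12) "uniform" else "non-uniform",
      "\n")
  invisible(x)
}

#' @export
print.noe_snapshot <- function(x, ...) {
  cat("noe_snapshot: model", x$model_id, "with", nrow(x$atoms), "atoms\n")
  invisible(x)
}
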