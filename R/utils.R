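# internal helpers shared across modules

.unit <- function(v) v / sqrt(sum(v * v))

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Normalize atom-name dialects: unicode prime U+2032 -> ASCII apostrophe,
# strip embedded blanks (fixed-width PDB names arrive padded).
.normalize_elety <- function(x) {
  x <- gsub("′", "'", x)
  gsub("[[:space:]]", "", x)
}

# wrap an angle in degrees to [0, 360)
.wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Natural-extension placement: coordinates of atom D bonded to C, given the
# chain A-B-C, the C-D bond length, the B-C-D angle and the A-B-C-D torsion
# (degrees). Torsion follows the standard sign convention used by
# bio3d::torsion.xyz.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

# purine / pyrimidine from residue name; modified nucleotides are unsupported
.base_family <- function(resname) {
  rn <- toupper(trimws(resname))
  pur <- c("A", "G", "ADE", "GUA", "RA", "RG", "DA", "DG",
           "RA3", "RA5", "RG3", "RG5")
  pyr <- c("C", "U", "CYT", "URA", "URI", "RC", "RU", "DC", "DT", "T", "THY",
           "RC3", "RC5", "RU3", "RU5")
  out <- rep(NA_character_, length(rn))
  out[rn %in% pur] <- "purine"
  out[rn %in% pyr] <- "pyrimidine"
  if (anyNA(out)) {
    bad <- unique(rn[is.na(out)])
    stop("unsupported (modified or non-nucleotide) residue name(s): ",
         paste(bad, collapse = ", "),
         "; only standard A/C/G/U nucleotides are handled", call. = FALSE)
  }
  out
}

# md5 of a deparsed R object, used to stamp pipeline outputs
.object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(x), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

# validate/normalize a weight vector of expected length
.check_weights <- function(w, n, what = "weights") {
  if (is.null(w)) return(rep(1 / n, n))
  if (length(w) != n)
    stop(what, " must have length ", n, ", got ", length(w), call. = FALSE)
  if (any(!is.finite(w)) || any(w < 0))
    stop(what, " must be finite and nonnegative", call. = FALSE)
  s <- sum(w)
  if (s <= 0) stop(what, " must not be all zero", call. = FALSE)
  w / s
}
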