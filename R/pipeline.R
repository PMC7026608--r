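# End-to-end pipeline: violations -> reweight -> cluster -> minimal sets,
# with reproducible on-disk artifacts. The thin command-line wrapper in
# exec/noetools chains these functions; every stage is also callable on the
# previous stage's files.

#' Assemble a pipeline run configuration
#'
#' Defaults are the protocol's standard constants: error scale
#' sigma = 0.5 nm^-6, eRMSD clustering cutoff 0.7, cluster population floor
#' 0.002, parsimony grid step 0.01, and a 9-residue motif window starting at
#' residue 11.
#'
#' @param ensemble Path to a multi-model PDB file or directory of PDB files.
#' @param restraints Path to the NOE restraint table (CSV/TSV).
#' @param out Output directory.
#' @param sigma Gaussian error scale (nm^-6).
#' @param ermsd_cutoff Clustering cutoff.
#' @param pop_floor Cluster admission floor for the parsimony search.
#' @param grid_step Parsimony weight grid step.
#' @param window_start,window_length Motif fragment window.
#' @param library Optional motif-search library (directory of PDB files).
#' @param seed Integer seed recorded with the run.
#' @param violation_mode Violation score mode (see [violation_score()]).
#' @param clique_method Clique search method (see
#'   [max_clique_clustering()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(ensemble, restraints, out = "noetools_run",
                       sigma = 0.5, ermsd_cutoff = 0.7, pop_floor = 0.002,
                       grid_step = 0.01, window_start = 11L,
                       window_length = 9L, library = NULL, seed = 1L,
                       violation_mode = "shortfall",
                       clique_method = "exact") {
  structure(list(ensemble = ensemble, restraints = restraints, out = out,
                 sigma = sigma, ermsd_cutoff = ermsd_cutoff,
                 pop_floor = pop_floor, grid_step = grid_step,
                 window_start = as.integer(window_start),
                 window_length = as.integer(window_length),
                 library = library, seed = as.integer(seed),
                 violation_mode = violation_mode,
                 clique_method = clique_method),
            class = "run_config")
}

.stage <- function(out, name, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("stage ", name, " failed: ", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full reconciliation pipeline
#'
#' Executes violations -> reweighting -> clustering -> minimal-set search on
#' the configured inputs, writing all artifacts under the output directory:
#' `violations.csv`, `weights.tsv`, `multipliers.tsv`, `reweight.json`,
#' `cluster_assignments.tsv`, `cluster_report.csv`, per-cluster PDBs under
#' `clusters/`, `minimal_sets.csv` and `run.json` (configuration, hash, seed
#' and stage status). Deterministic stages are bit-identical across reruns of
#' the same configuration; on failure, partial outputs are retained next to a
#' `FAILED` marker naming the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory results (`ensemble`,
#'   `restraints`, `reweighting`, `clustering`, `minimal_sets`) and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$ensemble, config$restraints))
    if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  set.seed(config$seed)

  ens <- .stage(out, "read", read_ensemble(config$ensemble))
  restr <- .stage(out, "read", read_restraints(config$restraints))
  mat <- .stage(out, "signals", build_signal_matrix(ens, restr))

  # stage: violations of the prior ensemble
  ratios <- relative_signals(mat, restr)
  rep_df <- violation_report(restr, ratios)
  write.csv(rep_df, file.path(out, "violations.csv"), row.names = FALSE)

  # stage: maximum-entropy reweighting
  rw <- .stage(out, "reweight",
               maxent_reweight(mat, restr, sigma = config$sigma,
                               prior_weights = ens$prior))
  write.table(data.frame(snapshot_id = seq_along(rw$weights),
                         weight = rw$weights),
              file.path(out, "weights.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(restraint_id = seq_along(rw$lambda),
                         lambda = rw$lambda),
              file.path(out, "multipliers.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sigma = rw$sigma, kish = rw$kish,
                            converged = rw$converged,
                            iterations = rw$iterations,
                            violation_mode = config$violation_mode,
                            prior_violations = count_violations(ratios),
                            prior_violation_score =
                              violation_score(ratios, config$violation_mode)),
                       file.path(out, "reweight.json"), auto_unbox = TRUE,
                       digits = NA)

  # stage: two-stage clustering under the reweighted weights
  cl <- .stage(out, "cluster",
               cluster_ensemble(ens, weights = rw$weights,
                                cutoff = config$ermsd_cutoff,
                                method = config$clique_method))
  write.table(data.frame(snapshot_id = seq_along(cl$assignments),
                         cluster_id = cl$assignments),
              file.path(out, "cluster_assignments.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.csv(summary(cl), file.path(out, "cluster_report.csv"),
            row.names = FALSE)
  big <- vapply(cl$clusters, function(c_) c_$population > config$pop_floor,
                TRUE)
  export_cluster_pdbs(ens, cl, file.path(out, "clusters"),
                      ids = vapply(cl$clusters[big], `[[`, 0L, "id"))

  # stage: minimal cluster sets
  ms <- .stage(out, "minsets", {
    tab <- cluster_signal_table(cl, mat, rw$weights,
                                floor = config$pop_floor)
    find_minimal_sets(tab, restr, step = config$grid_step)
  })
  if (ms$feasible) {
    sets_out <- ms$sets
    sets_out$weights_percent <- vapply(ms$details, function(d)
      paste(round(100 * d$weights), collapse = " "), "")
    write.csv(sets_out[, c("clusters", "weights_percent", "d_kl")],
              file.path(out, "minimal_sets.csv"), row.names = FALSE)
  } else {
    write.csv(data.frame(feasible = FALSE,
                         most_violated = ms$most_violated),
              file.path(out, "minimal_sets.csv"), row.names = FALSE)
  }

  cfg <- unclass(config)
  jsonlite::write_json(
    list(config = cfg[!vapply(cfg, is.null, TRUE)],
         config_hash = .object_hash(cfg), seed = config$seed,
         package_version = as.character(utils::packageVersion("noetools")),
         stages = c("violations", "reweight", "cluster", "minsets"),
         status = "OK"),
    file.path(out, "run.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(ensemble = ens, restraints = restr, signals = mat,
                 reweighting = rw, clustering = cl, minimal_sets = ms,
                 out = out))
}

#' Violation report across one or more ensembles
#'
#' Computes per-restraint relative signals for each named ensemble and flags
#' violations; with `critical` set (e.g. 1.2), restricts the table to
#' restraints whose ratio falls below it in at least one ensemble -- a
#' superset of the violated ones.
#'
#' @param ensembles A `noe_ensemble` or named list of them.
#' @param restraints A `noe_restraints` table.
#' @param weights Optional list of weight vectors (parallel to `ensembles`).
#' @param critical Optional "critical" ratio filter.
#' @return Data frame: `pair`, `class`, `d_exp`, then one ratio column per
#'   ensemble.
#' @export
report_violations <- function(ensembles, restraints, weights = NULL,
                              critical = NULL) {
  if (inherits(ensembles, "noe_ensemble"))
    ensembles <- list(ensemble = ensembles)
  ratio_cols <- lapply(seq_along(ensembles), function(k) {
    mat <- build_signal_matrix(ensembles[[k]], restraints)
    relative_signals(mat, restraints,
                     if (is.null(weights)) NULL else weights[[k]])
  })
  names(ratio_cols) <- names(ensembles)
  out <- data.frame(
    pair = paste0(restraints$res_i, "_", restraints$atom_i, "-",
                  restraints$res_j, "_", restraints$atom_j),
    class = restraints$class, d_exp = restraints$d_exp,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ratio_cols))
  if (!is.null(critical)) {
    keep <- Reduce(`|`, lapply(ratio_cols, function(r) r < critical))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
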