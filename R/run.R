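#' Run the full CCS-focused structure-prediction workflow
#'
#' Wires the stages together for one species: descriptor extraction and
#' batch CCS prediction, semiautonomous filter-band focusing
#' ([focus_ensemble()]), greedy-leader representative clustering
#' ([cluster_representatives()]), energy ingestion, lowest-energy candidate
#' selection and Boltzmann-weighted CCS ([boltzmann_ccs()]), and percent
#' error against the experimental CCS. Writes `filtered.xyz`,
#' `representatives.xyz` and `report.json` under `output_dir`. When the band
#' captures no conformers the run returns (and writes) a report with status
#' `"no viable conformers"` rather than failing. The whole pipeline is
#' deterministic: the same inputs produce a byte-identical report.
#'
#' @param ensemble Input [conformer_ensemble()].
#' @param model A trained [train_ccs_regressor()] model.
#' @param ccs_user User reference CCS for the filter band (Angstrom^2).
#' @param output_dir Directory for output files (created if needed).
#' @param exp_ccs Experimental CCS for scoring; defaults to `ccs_user`.
#' @param stats,capacity Passed to [focus_ensemble()].
#' @param rmsd_threshold Leader-clustering radius, Angstrom.
#' @param temperature Boltzmann temperature, Kelvin.
#' @param energy_provider How representative conformers get relative
#'   energies: `NULL` uses the ensemble's `energy` metadata (e.g. read from
#'   XYZ comment lines or a table); a function is called with the
#'   representative ensemble and must return one energy (kcal/mol) per
#'   conformer. This is the pluggable stand-in for an external
#'   geometry-optimization stage.
#' @param include_hydrogens Passed to [cluster_representatives()].
#' @param probe_radius,points_per_atom Descriptor settings.
#' @return Invisibly, a list with the focused and representative ensembles
#'   and `report` (also serialized to `report.json`).
#' @export
run_ccsf_workflow <- function(ensemble, model, ccs_user, output_dir,
                              exp_ccs = NULL, stats = NULL, capacity = NULL,
                              rmsd_threshold = 1.0, temperature = 298.15,
                              energy_provider = NULL,
                              include_hydrogens = TRUE, probe_radius = 1.4,
                              points_per_atom = 960) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  if (is.null(exp_ccs)) exp_ccs <- ccs_user

  focused <- focus_ensemble(ensemble, model, ccs_user, stats = stats,
                            capacity = capacity, probe_radius = probe_radius,
                            points_per_atom = points_per_atom)
  frep <- focus_report(focused)
  report <- list(
    species = species_name(ensemble),
    n_input = frep$n_in,
    n_filtered = frep$n_out,
    band = frep$band,
    prediction_summary = frep$pred_summary,
    rmsd_threshold = rmsd_threshold,
    temperature = temperature,
    exp_ccs = exp_ccs
  )

  if (nrow(focused) == 0) {
    report$status <- "no viable conformers"
    report$n_representatives <- 0L
    write_report_json(report, file.path(output_dir, "report.json"))
    return(invisible(list(focused = focused, representatives = NULL,
                          report = report)))
  }

  write_xyz_ensemble(focused, file.path(output_dir, "filtered.xyz"))
  reps <- cluster_representatives(focused, rmsd_threshold,
                                  include_hydrogens = include_hydrogens)
  if (is.function(energy_provider)) {
    reps$energy <- as.numeric(energy_provider(reps))
  }
  if (anyNA(reps$energy)) {
    abort(paste0("representative conformers lack energies; supply them in ",
                 "the ensemble metadata or via energy_provider"))
  }
  write_xyz_ensemble(reps, file.path(output_dir, "representatives.xyz"))

  candidate <- select_candidate(reps)
  boltz <- boltzmann_ccs(reps$pred_ccs, reps$energy, temperature)
  pct <- percent_ccs_error(boltz, exp_ccs)

  report$status <- "ok"
  report$n_representatives <- nrow(reps)
  report$candidate <- list(id = candidate$id, energy = candidate$energy,
                           pred_ccs = candidate$pred_ccs)
  report$boltzmann_ccs <- boltz
  report$percent_error <- round(pct, 2)
  report$pass_3pct <- round(pct, 2) <= 3
  write_report_json(report, file.path(output_dir, "report.json"))
  invisible(list(focused = focused, representatives = reps, report = report))
}

write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
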