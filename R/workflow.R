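#' Minimum RMSD between two conformers under optimal rigid superposition
#'
#' Kabsch algorithm: both structures are centered, the optimal proper
#' rotation is obtained from the SVD of the covariance matrix (with the usual
#' determinant sign correction), and the RMSD of the superposed coordinates
#' is returned. Requires identical element sequences (same atom ordering).
#'
#' @param a,b Atom tibbles (`element`, `x`, `y`, `z`) or one-row
#'   `conformer_ensemble`s with the same formula and atom ordering.
#' @param include_hydrogens If `FALSE`, hydrogen atoms are excluded from the
#'   superposition and the RMSD.
#' @return RMSD in Angstrom; 0 (to numerical precision) iff the two are
#'   congruent under a proper rotation plus translation.
#' @export
kabsch_rmsd <- function(a, b, include_hydrogens = TRUE) {
  a <- resolve_atoms(a); b <- resolve_atoms(b)
  if (nrow(a) != nrow(b)) abort("conformers differ in atom count")
  if (!identical(a$element, b$element)) {
    abort("conformers differ in element ordering")
  }
  if (!include_hydrogens) {
    keep <- a$element != "H"
    if (!any(keep)) abort("no heavy atoms to superpose")
    a <- a[keep, ]; b <- b[keep, ]
  }
  P <- coords_matrix(a); Q <- coords_matrix(b)
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # optimal rotation P -> Q
  sqrt(mean(rowSums((P %*% t(rot) - Q)^2)))
}

#' Reduce an ensemble to representative conformers by greedy leader
#' clustering
#'
#' Conformers are scanned in input order; a conformer becomes a new
#' representative iff its Kabsch RMSD to every existing representative
#' exceeds the threshold, so every input conformer lies within the threshold
#' of at least one representative and representatives are pairwise separated
#' by more than the threshold.
#'
#' @param ensemble A non-empty [conformer_ensemble()].
#' @param rmsd_threshold Leader radius in Angstrom (default 1.0).
#' @param include_hydrogens Passed to [kabsch_rmsd()].
#' @return The representative `conformer_ensemble`, in input order.
#' @export
cluster_representatives <- function(ensemble, rmsd_threshold = 1.0,
                                    include_hydrogens = TRUE) {
  if (!inherits(ensemble, "conformer_ensemble") || nrow(ensemble) == 0) {
    abort("ensemble must be a non-empty conformer_ensemble")
  }
  stopifnot(rmsd_threshold > 0)
  reps <- integer(0)
  for (i in seq_len(nrow(ensemble))) {
    is_new <- TRUE
    for (r in reps) {
      if (kabsch_rmsd(ensemble$atoms[[i]], ensemble$atoms[[r]],
                      include_hydrogens) <= rmsd_threshold) {
        is_new <- FALSE
        break
      }
    }
    if (is_new) reps <- c(reps, i)
  }
  ensemble_slice(ensemble, reps)
}

#' Boltzmann population weights from relative energies
#'
#' `w_i = exp(-(E_i - E_min) / (R T))`, normalized to sum to 1, with
#' R = 0.0019872 kcal mol^-1 K^-1. Shifting the minimum energy to zero
#' before exponentiation makes the computation numerically safe and leaves
#' the weights invariant to any constant energy offset.
#'
#' @param energies Relative energies in kcal/mol (finite).
#' @param temperature Temperature in Kelvin (default 298.15).
#' @param units `"kcal/mol"` (default) or `"hartree"` (converted with
#'   627.5095 kcal/mol per hartree).
#' @return Numeric weights summing to 1.
#' @export
#' @examples
#' boltzmann_weights(c(0, 0.41068))  # RT ln 2 at 298.15 K -> 2/3, 1/3
boltzmann_weights <- function(energies, temperature = 298.15,
                              units = c("kcal/mol", "hartree")) {
  units <- match.arg(units)
  if (length(energies) == 0) abort("energies must be non-empty")
  if (!all(is.finite(energies))) abort("energies must be finite")
  stopifnot(temperature > 0)
  if (units == "hartree") energies <- energies * 627.5095
  w <- exp(-(energies - min(energies)) / (.R_KCAL * temperature))
  w / sum(w)
}

#' Boltzmann-weighted ensemble-average CCS
#'
#' @param ccs_values CCS per conformer (Angstrom^2).
#' @param energies Matching relative energies (kcal/mol).
#' @param temperature Temperature in Kelvin.
#' @param units Energy units, see [boltzmann_weights()].
#' @return The weighted average CCS (Angstrom^2), always within
#'   `[min(ccs_values), max(ccs_values)]`.
#' @export
boltzmann_ccs <- function(ccs_values, energies, temperature = 298.15,
                          units = c("kcal/mol", "hartree")) {
  if (length(ccs_values) != length(energies)) {
    abort("ccs_values and energies must have equal length")
  }
  sum(boltzmann_weights(energies, temperature, units) * ccs_values)
}

#' Select the candidate conformer by lowest relative energy
#'
#' @param ensemble A [conformer_ensemble()] whose conformers all carry an
#'   `energy`; ties are broken by input order.
#' @return A one-row `conformer_ensemble` holding the candidate.
#' @export
select_candidate <- function(ensemble) {
  if (!inherits(ensemble, "conformer_ensemble") || nrow(ensemble) == 0) {
    abort("ensemble must be a non-empty conformer_ensemble")
  }
  if (anyNA(ensemble$energy)) {
    abort("every conformer needs an energy to select a candidate")
  }
  ensemble_slice(ensemble, which.min(ensemble$energy))
}

#' Percent CCS error of a computed value against experiment
#'
#' `100 * |calc - exp| / exp`; the experimental CCS is always the
#' denominator. Vectorized.
#'
#' @param calc_ccs Computed CCS (Angstrom^2).
#' @param exp_ccs Experimental reference CCS (Angstrom^2, positive).
#' @return Percent error (unrounded; result tables round to 2 decimals).
#' @export
#' @examples
#' percent_ccs_error(235.72, 174.95)  # 34.74 after rounding
percent_ccs_error <- function(calc_ccs, exp_ccs) {
  if (any(!is.finite(exp_ccs)) || any(exp_ccs <= 0)) {
    abort("exp_ccs must be positive and finite")
  }
  100 * abs(calc_ccs - exp_ccs) / exp_ccs
}

#' Score candidate conformations against experimental CCS values
#'
#' Builds the standard evaluation table: per-species percent error (rounded
#' to 2 decimals, as reported), a pass flag at the 3% computed-CCS error
#' threshold, and summary statistics of the rounded errors.
#'
#' @param rows A data frame with columns `species`, `exp_ccs`, `calc_ccs`.
#' @param threshold Pass threshold in percent (default 3).
#' @return A `ccsf_evaluation` tibble with columns `species`, `exp_ccs`,
#'   `calc_ccs`, `percent_error`, `pass_3pct`. Use [summarize_evaluation()]
#'   for the mean +/- sd row.
#' @export
evaluate_candidates <- function(rows, threshold = 3) {
  need <- c("species", "exp_ccs", "calc_ccs")
  if (!all(need %in% names(rows)) || nrow(rows) == 0) {
    abort("rows must be non-empty with columns species, exp_ccs, calc_ccs")
  }
  out <- tibble::tibble(
    species = as.character(rows$species),
    exp_ccs = as.numeric(rows$exp_ccs),
    calc_ccs = as.numeric(rows$calc_ccs),
    percent_error = round(percent_ccs_error(rows$calc_ccs, rows$exp_ccs), 2)
  )
  out$pass_3pct <- out$percent_error <= threshold
  tibble::new_tibble(out, threshold = threshold, class = "ccsf_evaluation")
}

#' Summary row of an evaluation table
#'
#' Mean and sample standard deviation of the (2-decimal-rounded) percent
#' errors, with counts of species passing the threshold.
#'
#' @param evaluation A `ccsf_evaluation` from [evaluate_candidates()].
#' @return One-row tibble: `n`, `mean_pct_error`, `sd_pct_error`,
#'   `n_pass_3pct`.
#' @export
summarize_evaluation <- function(evaluation) {
  stopifnot(inherits(evaluation, "ccsf_evaluation"))
  tibble::tibble(
    n = nrow(evaluation),
    mean_pct_error = mean(evaluation$percent_error),
    sd_pct_error = if (nrow(evaluation) > 1) sd(evaluation$percent_error)
                   else 0,
    n_pass_3pct = sum(evaluation$pass_3pct)
  )
}
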