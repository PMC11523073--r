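#' Published lipid CCS benchmark tables
#'
#' Experimental versus computed CCS values for the fatty-acid \[M-H\]-
#' benchmark sets shipped with the package, for re-scoring with
#' [evaluate_candidates()]:
#' \describe{
#'   \item{standard}{20 lipids resolved with the standard (unfocused)
#'     gas-phase structure-prediction workflow.}
#'   \item{validation}{9 of those lipids rerun with CCS focusing
#'     (11000-conformer ensembles).}
#'   \item{test}{10 unseen lipids scored with the focused workflow.}
#'   \item{extrapolation}{4 larger (22-24 carbon, mostly saturated) lipids
#'     outside the training domain; `calc_ccs` is the minimum CCS the model
#'     forecast for each raw ensemble.}
#'   \item{extrapolation_standard}{the same 4 lipids resolved with the
#'     standard workflow.}
#' }
#' Each table has columns `species`, `carbon_chain`, `pi_bond_position`,
#' `exp_ccs`, `calc_ccs` and `reported_pct_error` (the percent error as
#' originally reported, reproducible as `round(100 |calc - exp| / exp, 2)`).
#'
#' @param which Benchmark name(s); default all.
#' @return A named list of tibbles (or a single tibble if one name is
#'   requested).
#' @export
#' @examples
#' b <- lipid_ccs_benchmarks("validation")
#' summarize_evaluation(evaluate_candidates(b))
lipid_ccs_benchmarks <- function(which = c("standard", "validation", "test",
                                           "extrapolation",
                                           "extrapolation_standard")) {
  files <- c(
    standard = "fa_standard_workflow.csv",
    validation = "fa_validation_ccsf.csv",
    test = "fa_test_unseen.csv",
    extrapolation = "fa_extrapolation_minimum_ccs.csv",
    extrapolation_standard = "fa_extrapolation_standard.csv"
  )
  which <- match.arg(which, several.ok = TRUE)
  out <- lapply(which, function(w) {
    path <- system.file("extdata", files[[w]], package = "ccsfocus",
                        mustWork = TRUE)
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      species = readr::col_character(),
                      carbon_chain = readr::col_integer(),
                      pi_bond_position = readr::col_character(),
                      .default = readr::col_double()
                    ))
  })
  names(out) <- which
  if (length(out) == 1) out[[1]] else out
}
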