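#' Synthetic training conditions: fatty-acid species grid
#'
#' The canonical species mix used to emulate the lipid training domain:
#' 18-22 carbon chains with 0-6 double bonds at common Delta positions
#' (e.g. 18:1 Delta-9, 20:4 Delta-5,8,11,14, 22:6 Delta-4,7,10,13,16,19).
#'
#' @return A tibble with columns `n_carbons` and `double_bonds`
#'   (list-column of Delta positions).
#' @export
synthetic_species_grid <- function() {
  tibble::tibble(
    n_carbons = c(18L, 18L, 18L, 18L, 20L, 20L, 20L, 22L, 22L, 22L),
    double_bonds = list(
      integer(0), 9L, c(9L, 12L), c(9L, 12L, 15L),
      11L, c(11L, 14L, 17L), c(5L, 8L, 11L, 14L),
      c(7L, 10L, 13L, 16L), c(7L, 10L, 13L, 16L, 19L),
      c(4L, 7L, 10L, 13L, 16L, 19L)
    )
  )
}

#' Build a labeled synthetic training table
#'
#' Generates conformers for every species in [synthetic_species_grid()]
#' (splitting `n_total` evenly), labels them with the
#' projection-approximation CCS oracle, and extracts the five descriptors.
#' This is the package's stand-in for a curated conformer/CCS training set.
#'
#' @param n_total Total number of conformers across species (default 5000).
#' @param seed Integer master seed; per-species generator seeds and the
#'   label-oracle seed derive from it deterministically.
#' @param pa_params Oracle parameters; the seed inside is replaced by one
#'   derived from `seed`.
#' @param points_per_atom Surface-area sampling density for [featurize()].
#' @return A tibble: `species`, `id`, the five descriptor columns and
#'   `label_ccs`.
#' @export
synthetic_training_set <- function(n_total = 5000, seed = 1,
                                   pa_params = pa_ccs_params(),
                                   points_per_atom = 960) {
  grid <- synthetic_species_grid()
  n_species <- nrow(grid)
  per <- rep(n_total %/% n_species, n_species)
  extra <- n_total - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  pa_params$seed <- (seed * 131 + 17) %% 2147483647L

  purrr::map_dfr(seq_len(n_species), function(k) {
    spec <- synthetic_spec(
      n_carbons = grid$n_carbons[k],
      double_bond_positions = grid$double_bonds[[k]],
      n_conformers = per[k],
      seed = (seed * 977 + k) %% 2147483647L
    )
    ens <- generate_ensemble(spec, labels = TRUE, pa_params = pa_params)
    feats <- featurize(ens, points_per_atom = points_per_atom)
    dplyr::mutate(feats, species = species_name(ens), .before = 1)
  })
}
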