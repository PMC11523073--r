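#' Mass-weighted center of mass of a conformer
#'
#' Uses monoisotopic masses from [element_table()].
#'
#' @param atoms An atom tibble (`element`, `x`, `y`, `z`) or a one-row
#'   `conformer_ensemble`.
#' @return Numeric length-3 vector (x, y, z) in Angstrom.
#' @export
#' @examples
#' center_of_mass(tibble::tibble(element = "C", x = 1, y = 2, z = 3))
center_of_mass <- function(atoms) {
  atoms <- resolve_atoms(atoms)
  m <- element_masses(atoms$element)
  c(x = sum(m * atoms$x), y = sum(m * atoms$y), z = sum(m * atoms$z)) / sum(m)
}

resolve_atoms <- function(atoms) {
  if (inherits(atoms, "conformer_ensemble")) {
    if (nrow(atoms) != 1) abort("expected a single conformer")
    atoms <- atoms$atoms[[1]]
  }
  as_atom_tbl(atoms)
}

#' Maximum distance of any (hetero)atom from the center of mass
#'
#' @inheritParams center_of_mass
#' @param heteroatoms_only If `TRUE`, only atoms other than C and H are
#'   considered; by convention the result is 0 when the conformer has no
#'   heteroatoms. The center of mass always uses all atoms.
#' @return Distance in Angstrom.
#' @export
max_distance_from_com <- function(atoms, heteroatoms_only = FALSE) {
  atoms <- resolve_atoms(atoms)
  com <- center_of_mass(atoms)
  if (heteroatoms_only) {
    keep <- element_lookup(atoms$element)$is_heteroatom
    if (!any(keep)) return(0)
    atoms <- atoms[keep, ]
  }
  max(sqrt((atoms$x - com[1])^2 + (atoms$y - com[2])^2 + (atoms$z - com[3])^2))
}

#' Number of heteroatoms (elements other than C and H)
#'
#' @inheritParams center_of_mass
#' @return Integer count.
#' @export
count_heteroatoms <- function(atoms) {
  atoms <- resolve_atoms(atoms)
  sum(element_lookup(atoms$element)$is_heteroatom)
}

#' Mass-to-charge ratio of the deprotonated anion \[M-H\]-
#'
#' m/z is the monoisotopic mass of the neutral molecule minus the proton mass
#' (1.00728 Da), for charge 1. By default the input geometry is assumed to be
#' the deprotonated species (the acidic hydrogen already removed, as in
#' negative-mode charge modeling), so one H is added back to obtain the
#' neutral formula.
#'
#' @inheritParams center_of_mass
#' @param geometry_is_neutral If `TRUE`, the atom list is the intact neutral
#'   molecule and no hydrogen is added.
#' @return m/z in Da (Thomson), charge 1.
#' @export
#' @examples
#' ch4 <- tibble::tibble(element = c("C", "H", "H", "H", "H"),
#'                       x = 0, y = 0, z = 0)
#' mz_anion(ch4, geometry_is_neutral = TRUE)  # 15.0240
mz_anion <- function(atoms, geometry_is_neutral = FALSE) {
  atoms <- resolve_atoms(atoms)
  neutral_mass <- sum(element_masses(atoms$element)) +
    if (geometry_is_neutral) 0 else element_masses("H")
  neutral_mass - .PROTON_MASS
}

#' Molecular surface area by sphere-point sampling
#'
#' Solvent-accessible surface area (Shrake-Rupley): each atom carries a
#' deterministic golden-spiral point set on a sphere of radius
#' `vdw_radius + probe_radius`; the accessible fraction (points not inside any
#' neighbor's expanded sphere) times the sphere area is summed over atoms.
#'
#' @inheritParams center_of_mass
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @param points_per_atom Sphere points per atom (default 960).
#' @return Area in Angstrom^2.
#' @export
#' @examples
#' # single carbon: 4*pi*(1.70 + 1.40)^2 = 120.76 A^2
#' molecular_surface_area(tibble::tibble(element = "C", x = 0, y = 0, z = 0))
molecular_surface_area <- function(atoms, probe_radius = 1.4,
                                   points_per_atom = 960) {
  atoms <- resolve_atoms(atoms)
  stopifnot(probe_radius >= 0, points_per_atom >= 1)
  cpp_sasa(coords_matrix(atoms), element_radii(atoms$element),
           probe_radius, as.integer(points_per_atom))
}

#' Compute the five CCS-regressor descriptors for each conformer
#'
#' The feature vector per conformer is: `mz` (\[M-H\]- mass-to-charge, Da),
#' `d_het_max` (farthest heteroatom from the center of mass, Angstrom;
#' 0 when there are no heteroatoms), `d_atom_max` (farthest atom from the
#' center of mass, Angstrom), `n_het` (heteroatom count) and `msa`
#' (molecular surface area, Angstrom^2). All five are invariant under rigid
#' translation and, within sphere-sampling tolerance, rotation.
#'
#' @param ensemble A [conformer_ensemble()] (or a single atom tibble).
#' @param probe_radius,points_per_atom Passed to [molecular_surface_area()].
#' @param geometry_is_neutral Passed to [mz_anion()].
#' @return A tibble with columns `id`, `mz`, `d_het_max`, `d_atom_max`,
#'   `n_het`, `msa`, `label_ccs` (NA where absent).
#' @export
featurize <- function(ensemble, probe_radius = 1.4, points_per_atom = 960,
                      geometry_is_neutral = FALSE) {
  if (!inherits(ensemble, "conformer_ensemble")) {
    ensemble <- conformer_ensemble(resolve_atoms(ensemble))
  }
  rows <- purrr::map(seq_len(nrow(ensemble)), function(i) {
    at <- ensemble$atoms[[i]]
    tibble::tibble(
      id = ensemble$id[i],
      mz = mz_anion(at, geometry_is_neutral = geometry_is_neutral),
      d_het_max = max_distance_from_com(at, heteroatoms_only = TRUE),
      d_atom_max = max_distance_from_com(at, heteroatoms_only = FALSE),
      n_het = count_heteroatoms(at),
      msa = molecular_surface_area(at, probe_radius, points_per_atom),
      label_ccs = ensemble$label_ccs[i]
    )
  })
  dplyr::bind_rows(rows)
}

#' Names of the five descriptor columns, in canonical order
#' @return Character vector.
#' @export
feature_names <- function() c("mz", "d_het_max", "d_atom_max", "n_het", "msa")

#' Feature-shift survey between a reference and a query feature set
#'
#' For each surveyed feature, reports the percent difference between the
#' query collection mean and the reference collection mean,
#' `100 * (mean_query - mean_reference) / mean_reference`, so that positive
#' values mean the query set is larger. Used to judge whether favorable
#' predictions on new data reflect generalization or mere data similarity.
#'
#' @param reference_features,query_features Data frames containing the
#'   surveyed feature columns (e.g. from [featurize()]).
#' @param features Character vector of feature columns to survey; defaults to
#'   the three conformation-dependent descriptors.
#' @return A tibble with columns `feature`, `reference_mean`, `query_mean`,
#'   `percent_difference`.
#' @export
feature_shift_survey <- function(reference_features, query_features,
                                 features = c("d_het_max", "d_atom_max",
                                              "msa")) {
  if (nrow(reference_features) == 0 || nrow(query_features) == 0) {
    abort("both feature collections must be non-empty")
  }
  missing <- setdiff(features, intersect(names(reference_features),
                                         names(query_features)))
  if (length(missing) > 0) {
    abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  ref_mean <- vapply(features, function(f) mean(reference_features[[f]]),
                     numeric(1))
  qry_mean <- vapply(features, function(f) mean(query_features[[f]]),
                     numeric(1))
  if (any(ref_mean == 0)) abort("reference mean is zero for a surveyed feature")
  tibble::tibble(
    feature = features,
    reference_mean = unname(ref_mean),
    query_mean = unname(qry_mean),
    percent_difference = unname(100 * (qry_mean - ref_mean) / ref_mean)
  )
}
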