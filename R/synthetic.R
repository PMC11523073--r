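#' Specification of a synthetic fatty-acid conformer ensemble
#'
#' Describes a deprotonated free fatty acid \[M-H\]- (carboxylate head, 2 O,
#' no acidic H) with an `n_carbons` chain and optional C=C double bonds at
#' the usual Delta positions (the carbon number where the double bond
#' starts). The neutral formula is C(n)H(2n-2u)O2 for u double bonds, so the
#' anion carries 2n-1-2u hydrogens. Backbone single-bond dihedrals are
#' sampled trans/gauche+/gauche- with the given probabilities (plus a small
#' uniform jitter); double-bond torsions are fixed by the cis/trans
#' geometry.
#'
#' @param n_carbons Chain length, 5 to 24.
#' @param double_bond_positions Integer Delta positions (each in
#'   `2..n_carbons-2` so the terminal methyl stays sp3, pairwise at least 2
#'   apart so bonds never share a carbon).
#' @param double_bond_geometry `"cis"` or `"trans"`, recycled over positions.
#' @param n_conformers Conformers to generate.
#' @param p_trans,p_gauche Backbone torsion probabilities: trans (180 deg)
#'   and each gauche branch (+60/-60 deg); must sum to 1 as
#'   `p_trans + 2 p_gauche`.
#' @param jitter_deg Half-width of the uniform torsion jitter in degrees
#'   (default 10; set 0 for ideal rotamers).
#' @param seed Integer seed; conformer `i` is a deterministic function of
#'   `(seed, i)`.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_carbons, double_bond_positions = integer(),
                           double_bond_geometry = "cis", n_conformers = 1,
                           p_trans = 0.6, p_gauche = 0.2, jitter_deg = 10,
                           seed = 1) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 5 || n_carbons > 24) abort("n_carbons must be in 5..24")
  db <- sort(as.integer(double_bond_positions))
  if (length(db) > 0) {
    if (any(db < 2) || any(db > n_carbons - 2)) {
      abort("double_bond_positions must lie in 2..(n_carbons - 2)")
    }
    if (any(diff(db) < 2)) {
      abort("double bonds must be at least 2 positions apart")
    }
  }
  if (abs(p_trans + 2 * p_gauche - 1) > 1e-8) {
    abort("p_trans + 2 * p_gauche must equal 1")
  }
  stopifnot(n_conformers >= 1, jitter_deg >= 0)
  geom <- rep_len(match.arg(double_bond_geometry, c("cis", "trans"),
                            several.ok = TRUE), length(db))
  structure(list(
    n_carbons = n_carbons, double_bond_positions = db,
    double_bond_geometry = geom, n_conformers = as.integer(n_conformers),
    p_trans = p_trans, p_gauche = p_gauche, jitter_deg = jitter_deg,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> FA ", x$n_carbons, ":", length(x$double_bond_positions),
      " [M-H]-, ", x$n_conformers, " conformer(s), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
unit3 <- function(v) v / sqrt(sum(v^2))

# natural extension reference frame: position of a new atom bonded to p3
# with the given bond length, angle at p3, and dihedral p1-p2-p3-new
nerf_place <- function(p1, p2, p3, bond, angle, dihedral) {
  bc <- unit3(p3 - p2)
  n <- unit3(cross3(p2 - p1, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  p3 + bc * d[1] + m * d[2] + n * d[3]
}

# one attempt at building the all-atom geometry; returns the atom tibble or
# NULL on a steric clash (any nonbonded pair closer than 1 Angstrom)
build_chain_attempt <- function(spec) {
  n <- spec$n_carbons
  db <- spec$double_bond_positions
  deg <- pi / 180
  is_double_bond <- function(j) j %in% db          # bond C_j - C_{j+1}
  sp2 <- unique(c(1L, db, db + 1L))                # C1 is the carboxylate C
  bond_len <- function(j) if (is_double_bond(j)) 1.33 else 1.54
  angle_at <- function(j) if (j %in% sp2) 120 * deg else 111.5 * deg

  # backbone carbons
  C <- matrix(NA_real_, n, 3)
  C[1, ] <- c(0, 0, 0)
  C[2, ] <- c(bond_len(1), 0, 0)
  a2 <- angle_at(2)
  C[3, ] <- C[2, ] + bond_len(2) * c(cos(pi - a2), sin(pi - a2), 0)
  for (i in seq(4, n)) {
    j <- i - 2L  # torsion about bond C_{j} - C_{j+1}
    if (is_double_bond(j)) {
      phi <- if (spec$double_bond_geometry[match(j, db)] == "cis") 0 else pi
    } else {
      u <- runif(1)
      base <- if (u < spec$p_trans) 180 else if (u < spec$p_trans +
                                                 spec$p_gauche) 60 else -60
      phi <- (base + runif(1, -spec$jitter_deg, spec$jitter_deg)) * deg
    }
    C[i, ] <- nerf_place(C[i - 3, ], C[i - 2, ], C[i - 1, ],
                         bond_len(i - 1), angle_at(i - 1), phi)
  }

  # carboxylate oxygens in the C3-C2-C1 frame, symmetric about the chain
  O1 <- nerf_place(C[3, ], C[2, ], C[1, ], 1.26, 117 * deg, 0)
  O2 <- nerf_place(C[3, ], C[2, ], C[1, ], 1.26, 117 * deg, pi)

  # hydrogens
  H <- list()
  h_parent <- integer(0)
  add_H <- function(pos, parent) {
    H[[length(H) + 1]] <<- pos
    h_parent[length(h_parent) + 1] <<- parent
  }
  half_hch <- 0.5 * 107.8 * deg
  for (i in seq(2, n - 1)) {
    b1 <- unit3(C[i - 1, ] - C[i, ])
    b2 <- unit3(C[i + 1, ] - C[i, ])
    if (i %in% sp2) {
      add_H(C[i, ] + 1.08 * unit3(-(b1 + b2)), i)
    } else {
      u <- unit3(-(b1 + b2))
      v <- unit3(cross3(b1, b2))
      add_H(C[i, ] + 1.09 * (u * cos(half_hch) + v * sin(half_hch)), i)
      add_H(C[i, ] + 1.09 * (u * cos(half_hch) - v * sin(half_hch)), i)
    }
  }
  # terminal methyl, staggered
  a <- unit3(C[n, ] - C[n - 1, ])
  w <- unit3(C[n - 2, ] - C[n - 1, ])
  p <- unit3(w - sum(w * a) * a)
  q <- cross3(a, p)
  for (phi in c(60, 180, 300) * deg) {
    dirv <- cos(70.5 * deg) * a + sin(70.5 * deg) * (cos(phi) * p +
                                                     sin(phi) * q)
    add_H(C[n, ] + 1.09 * dirv, n)
  }

  coords <- rbind(C, O1, O2, do.call(rbind, H))
  elements <- c(rep("C", n), "O", "O", rep("H", length(H)))

  # bonded pairs: backbone, C1-O, C-H
  bonds <- rbind(
    cbind(seq_len(n - 1), seq(2, n)),
    cbind(1L, n + 1L), cbind(1L, n + 2L),
    cbind(h_parent, n + 2L + seq_along(H))
  )
  d <- as.matrix(stats::dist(coords))
  d[cbind(bonds[, 1], bonds[, 2])] <- Inf
  d[cbind(bonds[, 2], bonds[, 1])] <- Inf
  diag(d) <- Inf
  if (min(d) < 1.0) return(NULL)
  tibble::tibble(element = elements, x = coords[, 1], y = coords[, 2],
                 z = coords[, 3])
}

#' Generate one synthetic fatty-acid conformer
#'
#' Builds an all-atom 3D model of the \[M-H\]- fatty acid described by the
#' spec: carboxylate head (two 1.26 Angstrom C-O bonds at 117 degrees, no
#' acidic hydrogen), zig-zag carbon backbone (C-C 1.54, C=C 1.33 Angstrom;
#' tetrahedral 111.5 or planar 120 degree angles), backbone dihedrals drawn
#' from the trans/gauche model (double-bond torsions fixed at 0/180 degrees
#' for cis/trans) and geometrically placed hydrogens. Self-clashing
#' geometries (any nonbonded pair under 1 Angstrom) are rejected and
#' resampled. Deterministic for a given `(seed, conformer_index)`.
#'
#' @param spec A [synthetic_spec()].
#' @param conformer_index 1-based conformer index within the spec's stream.
#' @return A one-row [conformer_ensemble()].
#' @export
generate_chain_conformer <- function(spec, conformer_index = 1) {
  stopifnot(inherits(spec, "synthetic_spec"), conformer_index >= 1)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  sub_seed <- (spec$seed * 100003 + conformer_index * 7919) %% 2147483647
  set.seed(sub_seed)
  atoms <- NULL
  for (attempt in seq_len(200)) {
    atoms <- build_chain_attempt(spec)
    if (!is.null(atoms)) break
  }
  if (is.null(atoms)) {
    abort("could not generate a clash-free conformer in 200 attempts")
  }
  sp <- paste0("FA_", spec$n_carbons, "_", length(spec$double_bond_positions))
  conformer_ensemble(list(atoms),
                     id = paste0(sp, "_c", conformer_index),
                     charge = -1L, species_name = sp)
}

#' Parameters for the projection-approximation CCS oracle
#'
#' @param n_orientations Number of random orientations to average over
#'   (minimum 100).
#' @param radius_augment Collision-size proxy added to every van der Waals
#'   radius, Angstrom (default 1.4).
#' @param grid_spacing Projection-grid cell size, Angstrom (default 0.2).
#' @param seed Integer seed for the orientation stream.
#' @return A `pa_ccs_params` list.
#' @export
pa_ccs_params <- function(n_orientations = 128, radius_augment = 1.4,
                          grid_spacing = 0.2, seed = 1) {
  stopifnot(n_orientations >= 100, radius_augment >= 0, grid_spacing > 0)
  structure(list(n_orientations = as.integer(n_orientations),
                 radius_augment = radius_augment,
                 grid_spacing = grid_spacing, seed = as.integer(seed)),
            class = "pa_ccs_params")
}

#' Projection-approximation CCS of a conformer
#'
#' Orientation-averaged hard-sphere projected area: for a seeded stream of
#' uniformly random rigid orientations, all atoms (van der Waals radius plus
#' `radius_augment`) are projected onto the viewing plane and the area of
#' the union of disks is measured by grid integration; the mean over
#' orientations is returned. Deterministic given the parameter seed;
#' translation-invariant exactly and rotation-invariant within the
#' integration tolerance. This is a fast geometric CCS surrogate used to
#' label synthetic training data, not a trajectory-method calculation.
#'
#' @param atoms An atom tibble or one-row `conformer_ensemble`.
#' @param params A [pa_ccs_params()].
#' @return Projected area in Angstrom^2.
#' @export
#' @examples
#' # single carbon: pi * (1.70 + 1.40)^2 = 30.19 A^2
#' pa_ccs(tibble::tibble(element = "C", x = 0, y = 0, z = 0))
pa_ccs <- function(atoms, params = pa_ccs_params()) {
  stopifnot(inherits(params, "pa_ccs_params"))
  atoms <- resolve_atoms(atoms)
  cpp_pa_area(coords_matrix(atoms),
              element_radii(atoms$element) + params$radius_augment,
              params$n_orientations, params$grid_spacing, params$seed)
}

#' Generate a labeled synthetic conformer ensemble
#'
#' Draws `spec$n_conformers` conformers from [generate_chain_conformer()]
#' and labels each with its projection-approximation CCS. Optionally assigns
#' synthetic relative energies as a documented function of compactness:
#' `energy = energy_scale * (label_ccs - min(label_ccs))` kcal/mol, so the
#' most compact (smallest-CCS) conformer is the energy minimum. These
#' energies exist to exercise the candidate-selection and Boltzmann
#' machinery, not to model a force field.
#'
#' @param spec A [synthetic_spec()].
#' @param labels If `TRUE` (default), set `label_ccs` from [pa_ccs()].
#' @param energies If `TRUE`, assign compactness-based energies (requires
#'   labels).
#' @param energy_scale kcal/mol per Angstrom^2 of CCS above the minimum
#'   (default 0.1).
#' @param pa_params A [pa_ccs_params()] for the labels.
#' @return A [conformer_ensemble()] of `spec$n_conformers` conformers.
#' @export
generate_ensemble <- function(spec, labels = TRUE, energies = FALSE,
                              energy_scale = 0.1,
                              pa_params = pa_ccs_params()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (energies && !labels) abort("energies require labels")
  ones <- lapply(seq_len(spec$n_conformers), function(i) {
    generate_chain_conformer(spec, i)
  })
  atoms <- lapply(ones, function(e) e$atoms[[1]])
  ids <- vapply(ones, function(e) e$id[1], character(1))
  lab <- if (labels) {
    vapply(atoms, function(a) pa_ccs(a, pa_params), numeric(1))
  } else NA_real_
  en <- if (energies) energy_scale * (lab - min(lab)) else NA_real_
  conformer_ensemble(atoms, id = ids, charge = -1L, energy = en,
                     label_ccs = lab, species_name = species_name(ones[[1]]))
}
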