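#' Conformer ensembles as nested tibbles
#'
#' A conformer ensemble is an ordered collection of 3D geometries (conformers)
#' of one molecular species. It is represented as a tibble with one row per
#' conformer and columns:
#' \describe{
#'   \item{id}{character, unique within the ensemble}
#'   \item{atoms}{list-column of atom tibbles (`element`, `x`, `y`, `z`,
#'     coordinates in Angstrom)}
#'   \item{charge}{integer formal charge (default -1 for \[M-H\]- anions)}
#'   \item{energy}{relative energy in kcal/mol, `NA` if unknown}
#'   \item{label_ccs}{reference/label CCS in Angstrom^2, `NA` if unknown}
#'   \item{pred_ccs}{model-predicted CCS in Angstrom^2, `NA` until predicted}
#' }
#' All conformers must share one molecular formula (identical element
#' multiset); the species name travels as the `species_name` attribute.
#'
#' @param atoms A list of atom tibbles/data frames with columns `element`,
#'   `x`, `y`, `z`, one per conformer (a single data frame is wrapped).
#' @param id Character vector of conformer ids (default `conf_1`, ...).
#' @param charge Integer formal charge(s), recycled.
#' @param energy,label_ccs,pred_ccs Optional numeric metadata, recycled.
#' @param species_name Species label carried as an attribute.
#' @return A `conformer_ensemble` tibble.
#' @export
#' @examples
#' at <- tibble::tibble(element = c("O", "H", "H"),
#'                      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0)
#' conformer_ensemble(list(at), species_name = "water")
conformer_ensemble <- function(atoms, id = NULL, charge = -1L, energy = NA_real_,
                               label_ccs = NA_real_, pred_ccs = NA_real_,
                               species_name = "") {
  if (is.data.frame(atoms)) atoms <- list(atoms)
  n <- length(atoms)
  if (n == 0) abort("a conformer ensemble needs at least one conformer")
  if (is.null(id)) id <- paste0("conf_", seq_len(n))
  out <- tibble::tibble(
    id = as.character(id),
    atoms = lapply(atoms, as_atom_tbl),
    charge = as.integer(rep_len(charge, n)),
    energy = as.numeric(rep_len(energy, n)),
    label_ccs = as.numeric(rep_len(label_ccs, n)),
    pred_ccs = as.numeric(rep_len(pred_ccs, n))
  )
  out <- tibble::new_tibble(out, species_name = as.character(species_name),
                            class = "conformer_ensemble")
  validate_conformer_ensemble(out)
}

as_atom_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(x))) {
    abort("atom tables need columns element, x, y, z")
  }
  x <- x[need]
  x$element <- as.character(x$element)
  x$x <- as.numeric(x$x); x$y <- as.numeric(x$y); x$z <- as.numeric(x$z)
  x
}

#' Validate a conformer ensemble
#'
#' Checks the container invariants: at least one conformer with at least one
#' atom each, finite coordinates, recognized element symbols, unique ids, a
#' single molecular formula across all conformers, and positive `label_ccs`
#' where present.
#'
#' @param x A `conformer_ensemble`.
#' @return `x`, invisibly classed, if valid; otherwise an error.
#' @export
validate_conformer_ensemble <- function(x) {
  if (nrow(x) == 0) abort("a conformer ensemble needs at least one conformer")
  if (anyDuplicated(x$id)) abort("conformer ids must be unique within an ensemble")
  formulas <- vapply(seq_len(nrow(x)), function(i) {
    at <- x$atoms[[i]]
    if (nrow(at) == 0) abort(paste0("conformer ", x$id[i], " has no atoms"))
    if (!all(is.finite(c(at$x, at$y, at$z)))) {
      abort(paste0("conformer ", x$id[i], " has non-finite coordinates"))
    }
    element_lookup(at$element)  # errors on unknown symbols
    formula_string(at$element)
  }, character(1))
  if (length(unique(formulas)) > 1L) {
    bad <- which(formulas != formulas[1])[1]
    abort(paste0("inconsistent molecular formula: conformer ", bad, " (",
                 x$id[bad], ") has ", formulas[bad],
                 " but conformer 1 has ", formulas[1]))
  }
  ok_label <- is.na(x$label_ccs) | (is.finite(x$label_ccs) & x$label_ccs > 0)
  if (!all(ok_label)) abort("label_ccs must be positive and finite where present")
  if (any(!is.na(x$energy) & !is.finite(x$energy))) {
    abort("energy must be finite where present")
  }
  invisible(x)
}

#' Molecular formula of an element vector, in Hill order
#' @param elements Character vector of element symbols.
#' @return A formula string such as `"C18H33O2"`.
#' @export
#' @examples
#' formula_string(c("C", "H", "H", "H", "H"))
formula_string <- function(elements) {
  cnt <- table(elements)
  syms <- names(cnt)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  paste0(vapply(ord, function(s) {
    n <- cnt[[s]]
    if (n == 1) s else paste0(s, n)
  }, character(1)), collapse = "")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  sp <- attr(x, "species_name")
  cat("<conformer_ensemble>", if (nzchar(sp)) paste0(" species: ", sp), "\n",
      sep = "")
  cat("  ", nrow(x), " conformer(s), formula ",
      formula_string(x$atoms[[1]]$element), "\n", sep = "")
  NextMethod()
}

#' Species name of an ensemble
#' @param x A `conformer_ensemble`.
#' @return The `species_name` attribute (character scalar).
#' @export
species_name <- function(x) attr(x, "species_name") %||% ""

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset rows of an ensemble keeping class + attributes
ensemble_slice <- function(x, idx) {
  df <- tibble::tibble(
    id = x$id[idx], atoms = x$atoms[idx], charge = x$charge[idx],
    energy = x$energy[idx], label_ccs = x$label_ccs[idx],
    pred_ccs = x$pred_ccs[idx]
  )
  tibble::new_tibble(df, species_name = species_name(x),
                     class = "conformer_ensemble")
}

coords_matrix <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}
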