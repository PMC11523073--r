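#' Element reference table
#'
#' A single embedded table of element properties used throughout the package:
#' monoisotopic masses (Da) from the standard isotope compilation and Bondi
#' van der Waals radii (Angstrom). Heteroatoms are all elements other than
#' carbon and hydrogen.
#'
#' @return A tibble with columns `symbol`, `mass` (monoisotopic, Da),
#'   `vdw_radius` (Angstrom) and `is_heteroatom`.
#' @export
#' @examples
#' element_table()
element_table <- function() {
  tibble::tibble(
    symbol = c("H", "C", "N", "O", "F", "P", "S", "Cl"),
    mass = c(1.007825032, 12.0, 14.003074005, 15.994914620,
             18.998403163, 30.973761998, 31.972071174, 34.968852682),
    vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75),
    is_heteroatom = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' Look up element data by symbol
#'
#' @param symbol Character vector of element symbols (case sensitive,
#'   e.g. `"C"`, `"O"`).
#' @return A tibble with one row per requested symbol, in request order, with
#'   the columns of [element_table()].
#' @export
#' @examples
#' element_lookup(c("C", "O"))
element_lookup <- function(symbol) {
  tab <- element_table()
  idx <- match(symbol, tab$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  tab[idx, ]
}

# fast vectors for internal hot paths
element_masses <- function(symbols) element_lookup(symbols)$mass
element_radii <- function(symbols) element_lookup(symbols)$vdw_radius
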