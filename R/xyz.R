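#' Read a multi-frame XYZ file as a conformer ensemble
#'
#' Each frame is standard XYZ: an atom-count line, a free-form comment line,
#' then one `element x y z` line per atom (coordinates in Angstrom).
#' Whitespace-separated `key=value` tokens on the comment line populate
#' conformer metadata: `id`, `charge` (integer), `energy` (kcal/mol) and
#' `ccs` (label CCS, Angstrom^2). Absent keys leave the fields at their
#' defaults (`charge` falls back to -1, the \[M-H\]- convention).
#'
#' @param path Path to an XYZ file.
#' @param species_name Species label; defaults to the file name without
#'   extension.
#' @return A [conformer_ensemble()].
#' @export
read_xyz_ensemble <- function(path, species_name = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(species_name)) {
    species_name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) abort(paste0("empty XYZ file: ", path))

  frames <- list()
  meta <- list()
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    count_line <- trimws(lines[pos])
    if (!grepl("^[0-9]+$", count_line)) {
      abort(paste0("frame ", frame, ": malformed atom-count line: '",
                   lines[pos], "'"))
    }
    n_at <- as.integer(count_line)
    if (n_at < 1) abort(paste0("frame ", frame, ": atom count must be >= 1"))
    if (pos + 1L + n_at > length(lines)) {
      abort(paste0("frame ", frame, ": declares ", n_at,
                   " atoms but the file ends early"))
    }
    comment <- lines[pos + 1L]
    atom_lines <- lines[(pos + 2L):(pos + 1L + n_at)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad) > 0) {
      abort(paste0("frame ", frame, ": atom line ", bad[1],
                   " does not have element + 3 coordinates"))
    }
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- vapply(toks, function(t) suppressWarnings(as.numeric(t[2:4])),
                  numeric(3))
    if (anyNA(xyz)) {
      abort(paste0("frame ", frame, ": non-numeric coordinates"))
    }
    tab <- element_table()
    if (!all(el %in% tab$symbol)) {
      abort(paste0("frame ", frame, ": unknown element symbol(s): ",
                   paste(unique(setdiff(el, tab$symbol)), collapse = ", ")))
    }
    frames[[frame]] <- tibble::tibble(element = el, x = xyz[1, ],
                                      y = xyz[2, ], z = xyz[3, ])
    meta[[frame]] <- parse_xyz_comment(comment)
    pos <- pos + 2L + n_at
  }

  get_meta <- function(key, default, as = as.numeric) {
    vapply(meta, function(m) {
      if (is.null(m[[key]])) default else as(m[[key]])
    }, as(default))
  }
  ids <- get_meta("id", NA_character_, as.character)
  if (anyNA(ids)) {
    auto <- paste0("conf_", seq_along(meta))
    ids[is.na(ids)] <- auto[is.na(ids)]
  }
  out <- try(conformer_ensemble(
    frames, id = ids,
    charge = get_meta("charge", -1L, function(v) as.integer(as.numeric(v))),
    energy = get_meta("energy", NA_real_),
    label_ccs = get_meta("ccs", NA_real_),
    species_name = species_name
  ), silent = TRUE)
  if (inherits(out, "try-error")) {
    abort(paste0("while reading ", path, ": ",
                 conditionMessage(attr(out, "condition"))))
  }
  out
}

parse_xyz_comment <- function(comment) {
  toks <- strsplit(trimws(comment), "[[:space:]]+")[[1]]
  kv <- toks[grepl("^[A-Za-z_][A-Za-z0-9_]*=", toks)]
  out <- list()
  for (t in kv) {
    eq <- regexpr("=", t, fixed = TRUE)
    out[[substr(t, 1, eq - 1)]] <- substr(t, eq + 1, nchar(t))
  }
  out
}

#' Write a conformer ensemble as a multi-frame XYZ file
#'
#' Inverse of [read_xyz_ensemble()]: coordinates are written with six decimal
#' places and metadata (`id`, `charge`, and `energy`/`ccs` where present) is
#' serialized as `key=value` tokens on each frame's comment line.
#'
#' @param ensemble A non-empty [conformer_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_ensemble <- function(ensemble, path) {
  if (!inherits(ensemble, "conformer_ensemble") || nrow(ensemble) == 0) {
    abort("ensemble must be a non-empty conformer_ensemble")
  }
  blocks <- vapply(seq_len(nrow(ensemble)), function(i) {
    at <- ensemble$atoms[[i]]
    meta <- c(
      paste0("id=", ensemble$id[i]),
      paste0("charge=", ensemble$charge[i]),
      if (!is.na(ensemble$energy[i]))
        paste0("energy=", sprintf("%.10g", ensemble$energy[i])),
      if (!is.na(ensemble$label_ccs[i]))
        paste0("ccs=", sprintf("%.10g", ensemble$label_ccs[i]))
    )
    paste(c(nrow(at), paste(meta, collapse = " "),
            sprintf("%-2s %14.6f %14.6f %14.6f", at$element, at$x, at$y, at$z)),
          collapse = "\n")
  }, character(1))
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) abort(paste0("cannot write to ", path)))
  on.exit(close(con))
  writeLines(blocks, con)
  invisible(path)
}
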