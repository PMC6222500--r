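# Cartesian structures and XYZ file handling.

#' Construct a molecular structure
#'
#' A light container for an ordered list of atoms with Cartesian
#' coordinates in Angstrom, the carrier for optimized geometries and for
#' synthetic backbone fragments.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param label optional character label (stored in the XYZ comment line).
#' @return object of class `"xyz_structure"` with fields `elements`,
#'   `coords` and `label`.
#' @export
xyz_structure <- function(elements, coords, label = "") {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("structure needs at least one atom", call. = FALSE)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != length(elements)) {
    stop("`coords` must be a numeric matrix with 3 columns and one row per element",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  out <- list(elements = elements, coords = coords,
              label = as.character(label)[1])
  class(out) <- "xyz_structure"
  out
}

#' @export
print.xyz_structure <- function(x, ...) {
  cat(sprintf("<xyz_structure> %d atoms%s\n", length(x$elements),
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an `"xyz_structure"`.
#' @return integer.
#' @export
n_atoms <- function(structure) length(structure$elements)

#' Read a structure from an XYZ file
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `element x y z` line per atom.
#'
#' @param path file path.
#' @return an `"xyz_structure"`; the comment line becomes `label`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop(sprintf("'%s': not an XYZ file (fewer than 2 lines)", path),
                               call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop(sprintf("'%s' line 1: invalid atom count '%s'", path, lines[1]), call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop(sprintf("'%s': header declares %d atoms but %d atom lines found",
                 path, n, length(body)), call. = FALSE)
  }
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L) {
      stop(sprintf("'%s' line %d: expected 'element x y z'", path, i + 2L), call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) {
      stop(sprintf("'%s' line %d: non-numeric coordinate", path, i + 2L), call. = FALSE)
    }
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  xyz_structure(elements, coords, label = lines[2])
}

#' Write a structure to an XYZ file
#'
#' Coordinates are written with 6 decimals, so a write/read round trip
#' preserves them to 1e-6 Angstrom.
#'
#' @param structure an `"xyz_structure"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  stopifnot(inherits(structure, "xyz_structure"))
  n <- n_atoms(structure)
  lines <- c(as.character(n),
             structure$label,
             sprintf("%-3s %14.6f %14.6f %14.6f",
                     structure$elements,
                     structure$coords[, 1],
                     structure$coords[, 2],
                     structure$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}
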