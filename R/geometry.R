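#' Construct a molecular geometry for the virtual-ligand penalty terms
#'
#' If atom roles are not given they are inferred: the single P atom is the
#' phosphorus center, the three Cl atoms closest to it are the Cl*
#' pseudo-substituents, and every remaining atom is an environment atom
#' (the set that feels the ovoid steric potential).
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (natoms x 3) of Cartesian coordinates
#'   (Angstrom).
#' @param pIndex index of the P atom (inferred if missing).
#' @param clIndices indices of the three Cl* atoms (inferred if missing).
#' @param envIndices indices of environment atoms (defaults to all others).
#' @return A \linkS4class{MolecularGeometry} object.
#' @export
molecularGeometry <- function(elements, coords, pIndex = NULL,
                              clIndices = NULL, envIndices = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(pIndex)) {
    pIndex <- which(elements == "P")
    if (length(pIndex) != 1L)
      stop("cannot infer P center: found ", length(pIndex),
           " P atoms; give pIndex explicitly")
  }
  if (is.null(clIndices)) {
    cl <- which(elements == "Cl")
    if (length(cl) < 3L)
      stop("cannot infer Cl* atoms: found ", length(cl),
           " Cl atoms; give clIndices explicitly")
    d <- sqrt(rowSums((coords[cl, , drop = FALSE] -
                       matrix(coords[pIndex, ], length(cl), 3,
                              byrow = TRUE))^2))
    clIndices <- cl[order(d)][1:3]
  }
  if (length(clIndices) != 3L)
    stop("exactly three Cl* indices required, got ", length(clIndices))
  if (is.null(envIndices))
    envIndices <- setdiff(seq_len(nrow(coords)), c(pIndex, clIndices))
  new("MolecularGeometry", elements = elements, coords = coords,
      pIndex = as.integer(pIndex), clIndices = as.integer(clIndices),
      envIndices = as.integer(envIndices))
}

setMethod("show", "MolecularGeometry", function(object) {
  cat(sprintf(
    "MolecularGeometry: %d atoms (P at %d; Cl* at %s; %d environment)\n",
    nrow(object@coords), object@pIndex,
    paste(object@clIndices, collapse = ","), length(object@envIndices)))
})

#' Number of atoms in a geometry
#' @param geom a \linkS4class{MolecularGeometry} object.
#' @return integer atom count.
#' @export
numAtoms <- function(geom) nrow(geom@coords)

#' Read a geometry from an XYZ file
#'
#' Standard XYZ layout: atom count line, comment line, then one
#' "element x y z" row per atom (coordinates in Angstrom).
#'
#' @param path file path.
#' @param ... passed to \code{\link{molecularGeometry}} (e.g. explicit
#'   atom role indices).
#' @return A \linkS4class{MolecularGeometry} object; the comment line is
#'   kept as attribute "comment" on the elements slot is not stored --
#'   use \code{readXYZRaw} for the raw records.
#' @export
readXYZ <- function(path, ...) {
  raw <- readXYZRaw(path)
  molecularGeometry(raw$elements, raw$coords, ...)
}

#' Read raw XYZ records
#'
#' @param path file path.
#' @return list(elements, coords, comment).
#' @export
readXYZRaw <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 2L) stop("XYZ file too short: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(nat)) stop("line 1: atom count is not an integer")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nat)
    stop("line 1 declares ", nat, " atoms but ", length(body),
         " atom rows follow")
  el <- character(nat); xyz <- matrix(NA_real_, nat, 3)
  for (i in seq_len(nat)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(tok) < 4L)
      stop("line ", i + 2L, ": expected 'element x y z'")
    if (!grepl("^[A-Z][a-z]?$", tok[1L]))
      stop("line ", i + 2L, ": bad element symbol '", tok[1L], "'")
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v)))
      stop("line ", i + 2L, ": non-numeric coordinate")
    el[i] <- tok[1L]; xyz[i, ] <- v
  }
  list(elements = el, coords = xyz, comment = lines[2L])
}

#' Write a geometry to an XYZ file
#'
#' Coordinates are written with 10 decimal places so that a read/write
#' round trip is lossless well below 1e-8 Angstrom.
#'
#' @param geom a \linkS4class{MolecularGeometry} object.
#' @param path output file path.
#' @param comment comment line content.
#' @return path, invisibly.
#' @export
writeXYZ <- function(geom, path, comment = "") {
  n <- nrow(geom@coords)
  rows <- sprintf("%-2s %16.10f %16.10f %16.10f", geom@elements,
                  geom@coords[, 1], geom@coords[, 2], geom@coords[, 3])
  writeLines(c(as.character(n), comment, rows), path)
  invisible(path)
}
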