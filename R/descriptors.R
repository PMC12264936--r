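## Descriptor space: dissociation-energy table, PCA transform, and the
## ligand parameter database.

#' Build a ligand x fragment dissociation-energy table
#'
#' Evaluates, for every ligand, the dissociation energies over the fixed
#' fragment set (one table column per fragment). Ligands may be given as
#' VL parameter vectors (evaluated through the backend descriptor map) or
#' as synthetic ligands carrying a precomputed energy vector in \code{$x}.
#'
#' @param ligands named list of ligands: \linkS4class{VLParams}, numeric
#'   parameter vectors, or lists with an \code{$x} energy vector.
#' @param fragments character vector of fragment identifiers; its length
#'   must equal the backend descriptor dimension m.
#' @param backend a \linkS4class{SyntheticSurface} (or any object accepted
#'   by \code{\link{evalDescriptors}}); may be NULL when every ligand
#'   carries its own energy vector.
#' @return numeric matrix (|ligands| x |fragments|) with dimnames.
#' @export
buildDissociationTable <- function(ligands, fragments, backend = NULL) {
  if (length(ligands) == 0L || length(fragments) == 0L)
    stop("ligand and fragment lists must be nonempty")
  if (!is.null(backend) && length(fragments) != backend@m)
    stop("fragment list length (", length(fragments),
         ") must equal backend descriptor dimension (", backend@m, ")")
  ids <- names(ligands)
  if (is.null(ids)) ids <- paste0("L", seq_along(ligands))
  tab <- matrix(NA_real_, length(ligands), length(fragments),
                dimnames = list(ids, fragments))
  for (i in seq_along(ligands)) {
    li <- ligands[[i]]
    e <- tryCatch({
      if (is.list(li) && !is.null(li$x)) as.numeric(li$x)
      else if (is.null(backend))
        stop("no backend and no precomputed energies")
      else evalDescriptors(backend, li)$value
    }, error = function(err)
      stop("backend failed for ligand '", ids[i], "': ",
           conditionMessage(err), call. = FALSE))
    if (length(e) != length(fragments) || !all(is.finite(e)))
      stop("incomplete table: ligand '", ids[i],
           "' produced a bad energy vector")
    tab[i, ] <- e
  }
  tab
}

#' Fit the PCA transform of the dissociation-energy space
#'
#' PCA on the covariance of the raw dissociation energies (no variance
#' standardization), retaining all m components, so that the descriptor
#' components are exactly uncorrelated over the training ligands and the
#' transform is an isometry (orthonormal loadings).
#'
#' @param table complete ligand x fragment energy matrix (>= 2 ligands).
#' @return A \linkS4class{PCAModel}. Components with numerically zero
#'   variance (rank-deficient tables) are flagged in \code{zeroVariance}.
#' @export
fitPCA <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L) stop("PCA requires at least 2 ligands")
  if (any(!is.finite(table))) stop("table must be complete (no missing cells)")
  pc <- stats::prcomp(table, center = TRUE, scale. = FALSE)
  m <- ncol(table)
  rot <- pc$rotation
  sdev <- pc$sdev
  ## prcomp drops no columns for n > m, but pads are needed when the
  ## sample count limits the rank; extend to a full orthonormal basis
  if (ncol(rot) < m) {
    full <- qr.Q(qr(cbind(rot, diag(m))))[, seq_len(m), drop = FALSE]
    full[, seq_len(ncol(rot))] <- rot
    rot <- full
    sdev <- c(sdev, rep(0, m - length(sdev)))
  }
  tol <- max(sdev) * 1e-10
  new("PCAModel", center = pc$center, rotation = rot, sdev = sdev,
      zeroVariance = sdev <= tol)
}

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components, %d with zero variance\n",
              length(object@sdev), sum(object@zeroVariance)))
})

#' Transform raw energies to descriptor scores
#'
#' x = Q' (e - center), the principal-component scores of a
#' dissociation-energy vector under the frozen PCA model.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param energies numeric vector of length m (kcal/mol).
#' @return numeric descriptor vector of length m.
#' @export
toDescriptor <- function(model, energies) {
  e <- as.numeric(energies)
  if (length(e) != length(model@center))
    stop("energies length (", length(e), ") does not match model dimension (",
         length(model@center), ")")
  as.vector(crossprod(model@rotation, e - model@center))
}

#' Invert the descriptor transform
#'
#' @param model a \linkS4class{PCAModel}.
#' @param x descriptor vector of length m.
#' @return raw energy vector e = Q x + center.
#' @export
fromDescriptor <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != length(model@center))
    stop("descriptor length does not match model dimension")
  as.vector(model@rotation %*% x + model@center)
}

#' Compose a backend with a PCA model
#'
#' Returns a descriptor backend mapping p to PCA scores, with the exact
#' chain-rule Jacobian. Because the loading matrix is orthonormal,
#' Euclidean distances (and hence projection residuals) are identical in
#' raw-energy and score coordinates.
#'
#' @param surface a \linkS4class{SyntheticSurface}.
#' @param model a \linkS4class{PCAModel}.
#' @return function(p) returning list(value, jacobian).
#' @export
pcaBackend <- function(surface, model) {
  force(surface); force(model)
  function(p) {
    gd <- evalDescriptors(surface, p)
    list(value = as.vector(crossprod(model@rotation,
                                     gd$value - model@center)),
         jacobian = crossprod(model@rotation, gd$jacobian))
  }
}

.dbColumns <- c("id", "name", "r0", "a1", "b1", "l_min")

.validateParamDb <- function(db, source = "database") {
  missingCols <- setdiff(.dbColumns, names(db))
  if (length(missingCols))
    stop(source, ": missing columns ", paste(missingCols, collapse = ", "))
  db <- db[, .dbColumns]
  for (col in c("r0", "a1", "b1", "l_min")) {
    v <- suppressWarnings(as.numeric(db[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(source, ": non-numeric '", col, "' in row ", bad[1L])
    db[[col]] <- v
  }
  dup <- which(duplicated(db$id))
  if (length(dup))
    stop(source, ": duplicate ligand id '", db$id[dup[1L]], "' in row ",
         dup[1L])
  if (any(db$l_min < 0)) stop(source, ": l_min must be nonnegative")
  if (any(db$r0 <= 0 | db$a1 <= 0 | db$b1 <= 0))
    stop(source, ": VL parameters must be strictly positive")
  db
}

#' Load a ligand parameter database
#'
#' Reads a CSV or JSON database with columns id, name, r0, a1, b1, l_min:
#' one row per real ligand with its projected VL parameters and the
#' projection residual.
#'
#' @param source file path (.csv or .json); defaults to the packaged
#'   database of 21 monodentate phosphine ligands.
#' @return data.frame with the six canonical columns.
#' @export
loadParamDb <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "ligand_vl_params.csv",
                          package = "vlscreen", mustWork = TRUE)
  db <- if (grepl("\\.json$", source, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(source), stringsAsFactors = FALSE)
  else
    utils::read.csv(source, stringsAsFactors = FALSE,
                    colClasses = "character")
  .validateParamDb(db, source)
}

#' Save a ligand parameter database
#'
#' Writes CSV (or JSON when the path ends in .json) at full double
#' precision, so that a save/load round trip is lossless.
#'
#' @param db data.frame with columns id, name, r0, a1, b1, l_min.
#' @param sink output file path.
#' @return sink, invisibly.
#' @export
saveParamDb <- function(db, sink) {
  db <- .validateParamDb(db)
  if (grepl("\\.json$", sink, ignore.case = TRUE)) {
    jsonlite::write_json(db, sink, digits = NA, dataframe = "rows")
  } else {
    out <- db
    for (col in c("r0", "a1", "b1", "l_min"))
      out[[col]] <- format(db[[col]], digits = 17, trim = TRUE,
                           scientific = FALSE)
    utils::write.csv(out, sink, row.names = FALSE, quote = FALSE)
  }
  invisible(sink)
}

#' The packaged phosphine ligand database
#'
#' VL parameters (r0, a1, b1) and projection residuals l_min for 21
#' monodentate phosphine ligands, obtained by projecting each ligand's
#' 16-fragment dissociation-energy descriptor onto the virtual-ligand
#' surface.
#'
#' @return data.frame with 21 rows.
#' @examples
#' db <- ligandDatabase()
#' db[db$id == "L9", ]  # PMe3
#' @export
ligandDatabase <- function() loadParamDb()

#' Identifiers of the standard fragment set
#'
#' The 16 metal-fragment complexes whose ligand dissociation energies
#' form the raw descriptor space.
#'
#' @return character vector of length 16.
#' @export
fragmentSet <- function() paste0("Fg", 1:16)
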