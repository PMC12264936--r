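## Reliability-filtered ranking of database ligands: the normalized
## parameter deviation metric, strict/loose filters, rank order by
## predicted performance, and the trial-order protocol.

#' Range-normalized parameter deviation
#'
#' ||dp'|| = sqrt(sum_i ((p_i - p*_i) / (p_i^Max - p_i^min))^2), the
#' deviation between a ligand's VL parameters and the surrogate reference
#' point, normalized by the accessible range of each component. Together
#' with l_min this is the second reliability index: the Taylor expansion
#' loses accuracy with anharmonicity as the deviation grows.
#'
#' @param p ligand VL parameters.
#' @param pStar surrogate reference point.
#' @param bounds \linkS4class{ParamBounds} with the accessible ranges.
#' @return nonnegative scalar.
#' @examples
#' deltaPNorm(c(1.424, 2.620, 1.364), c(1.35, 2.13, 1.64), defaultBounds())
#' @export
deltaPNorm <- function(p, pStar, bounds) {
  v <- if (is(p, "VLParams")) unname(paramVector(p)) else as.numeric(p)
  s <- if (is(pStar, "VLParams")) unname(paramVector(pStar))
       else as.numeric(pStar)
  w <- unname(bounds@upper - bounds@lower)
  if (length(v) != length(w) || length(s) != length(w))
    stop("parameter/bounds dimension mismatch")
  if (any(w <= 0)) stop("zero-width bound")
  sqrt(sum(((v - s) / w)^2))
}

#' Construct a reliability filter
#'
#' @param lMinMax threshold on the projection residual l_min.
#' @param dpNormMax threshold on the normalized parameter deviation.
#' @param name filter label.
#' @return A \linkS4class{FilterSpec}.
#' @export
filterSpec <- function(lMinMax, dpNormMax, name = "filter") {
  new("FilterSpec", lMinMax = as.numeric(lMinMax),
      dpNormMax = as.numeric(dpNormMax), name = name)
}

#' The standard strict and loose reliability filters
#'
#' Strict: l_min < 2.0 and deviation < 0.75; loose: l_min < 2.5 and
#' deviation < 1.0. Comparisons are strict inequalities.
#'
#' @return named list of two \linkS4class{FilterSpec} objects.
#' @export
defaultFilters <- function() {
  list(strict = filterSpec(2.0, 0.75, "strict"),
       loose = filterSpec(2.5, 1.0, "loose"))
}

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf("FilterSpec '%s': l_min < %g and ||dp'|| < %g\n",
              object@name, object@lMinMax, object@dpNormMax))
})

.dbParams <- function(db) {
  as.matrix(db[, c("r0", "a1", "b1")])
}

#' Apply a reliability filter to a ligand database
#'
#' Keeps ligands with l_min strictly below the l_min threshold and
#' normalized deviation from pStar strictly below the deviation
#' threshold.
#'
#' @param db parameter database data.frame (see
#'   \code{\link{loadParamDb}}).
#' @param pStar surrogate reference point.
#' @param bounds \linkS4class{ParamBounds} for the deviation metric.
#' @param filter a \linkS4class{FilterSpec}.
#' @return the passing subset of \code{db}, with a \code{dp_norm} column
#'   appended.
#' @export
applyFilter <- function(db, pStar, bounds, filter) {
  if (nrow(db) == 0L) stop("empty ligand database")
  P <- .dbParams(db)
  dp <- apply(P, 1L, deltaPNorm, pStar = pStar, bounds = bounds)
  out <- db
  out$dp_norm <- dp
  out[db$l_min < filter@lMinMax & dp < filter@dpNormMax, , drop = FALSE]
}

#' Rank database ligands by predicted performance
#'
#' Predicts the objective for every ligand with the given surrogate,
#' applies each reliability filter, and ranks the passing ligands by
#' predicted value (ascending for minimize, descending for maximize).
#' Ties are broken by smaller normalized deviation, then by id.
#'
#' @param db parameter database data.frame.
#' @param surrogate anything accepted by \code{\link{predictY}}.
#' @param pStar surrogate reference point (defaults to the surrogate's
#'   own reference point when available).
#' @param bounds \linkS4class{ParamBounds} for the deviation metric.
#' @param sense "minimize" or "maximize".
#' @param filters list of \linkS4class{FilterSpec} objects.
#' @return A \linkS4class{RankingReport}.
#' @export
rankLigands <- function(db, surrogate, pStar = NULL,
                        bounds = defaultBounds(),
                        sense = c("minimize", "maximize"),
                        filters = defaultFilters()) {
  sense <- match.arg(sense)
  if (is.null(pStar)) {
    if (is(surrogate, "TaylorSurrogate")) pStar <- surrogate@pStar
    else if (is(surrogate, "TrajectorySurrogate"))
      pStar <- surrogate@members[[length(surrogate@members)]]@pStar
    else stop("pStar must be given for this surrogate type")
  }
  P <- .dbParams(db)
  pred <- vapply(seq_len(nrow(db)),
                 function(i) predictY(surrogate, P[i, ]), numeric(1))
  dp <- apply(P, 1L, deltaPNorm, pStar = pStar, bounds = bounds)
  tab <- data.frame(id = db$id, name = db$name, predicted = pred,
                    l_min = db$l_min, dp_norm = dp,
                    stringsAsFactors = FALSE)
  if (is.null(names(filters)))
    names(filters) <- vapply(filters, function(f) f@name, character(1))
  for (fn in names(filters)) {
    f <- filters[[fn]]
    pass <- tab$l_min < f@lMinMax & tab$dp_norm < f@dpNormMax
    tab[[paste0("pass_", fn)]] <- pass
    rk <- rep(NA_integer_, nrow(tab))
    sub <- which(pass)
    if (length(sub)) {
      key <- if (sense == "minimize") tab$predicted[sub]
             else -tab$predicted[sub]
      ord <- order(key, tab$dp_norm[sub], tab$id[sub])
      rk[sub[ord]] <- seq_along(sub)
    }
    tab[[paste0("rank_", fn)]] <- rk
  }
  new("RankingReport", table = tab, sense = sense,
      pStar = as.numeric(pStar), bounds = bounds, filters = filters)
}

setMethod("show", "RankingReport", function(object) {
  cat(sprintf("RankingReport (%s): %d ligands, p* = (%s)\n",
              object@sense, nrow(object@table),
              paste(sprintf("%.3f", object@pStar), collapse = ", ")))
  for (fn in names(object@filters)) {
    pass <- object@table[[paste0("pass_", fn)]]
    rk <- object@table[[paste0("rank_", fn)]]
    top <- object@table$id[order(rk)][seq_len(min(3L, sum(pass)))]
    cat(sprintf("  %-8s %2d pass; top: %s\n", fn, sum(pass),
                paste(top, collapse = ", ")))
  }
})

#' Ranked table of a report
#' @param report a \linkS4class{RankingReport}.
#' @return the per-ligand data.frame.
#' @export
rankTable <- function(report) report@table

#' Count ligands passing each filter
#' @param report a \linkS4class{RankingReport}.
#' @return named integer vector of per-filter counts.
#' @export
filterCounts <- function(report) {
  vapply(names(report@filters),
         function(fn) sum(report@table[[paste0("pass_", fn)]]),
         integer(1))
}

#' Position of the true-best ligand in the trial order
#'
#' Simulates the experiment-order protocol: trials are run over the
#' ligands passing a filter, in order of predicted performance. Returns
#' the 1-based trial at which the ligand with the best true value (over
#' the whole database) is reached, or flags it as filtered out.
#'
#' @param report a \linkS4class{RankingReport}.
#' @param trueValues named numeric vector of true objective values
#'   (names are ligand ids).
#' @param filter name of the filter to use (default first).
#' @return list(position, id, filteredOut).
#' @export
trialOrder <- function(report, trueValues, filter = NULL) {
  tab <- report@table
  if (is.null(filter)) filter <- names(report@filters)[1L]
  tv <- trueValues[tab$id]
  bestIdx <- if (report@sense == "minimize") which.min(tv) else which.max(tv)
  bestId <- tab$id[bestIdx]
  rk <- tab[[paste0("rank_", filter)]][bestIdx]
  if (is.na(rk))
    list(position = NA_integer_, id = bestId, filteredOut = TRUE)
  else
    list(position = as.integer(rk), id = bestId, filteredOut = FALSE)
}

#' Write a ranking report to CSV
#'
#' Deterministic full-precision CSV: identical inputs give byte-identical
#' files.
#'
#' @param report a \linkS4class{RankingReport}.
#' @param path output path.
#' @return path, invisibly.
#' @export
writeRankingReport <- function(report, path) {
  tab <- report@table
  for (col in names(tab))
    if (is.numeric(tab[[col]]) && !is.integer(tab[[col]]))
      tab[[col]] <- format(tab[[col]], digits = 17, trim = TRUE,
                           scientific = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
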