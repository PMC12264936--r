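## Pipeline plumbing: configuration handling and the staged run
## build-db -> vlao -> predict -> rank, writing intermediate artifacts.

.configDefaults <- function() {
  list(
    seed = 1L,
    outputDir = NULL,
    database = "synthetic",
    backend = list(n = 3L, m = 16L, warp = 0, bumpFraction = 0.1),
    ligands = list(count = 21L, deltaRange = c(0.5, 3)),
    bounds = list(lower = c(1.3, 2.0, 1.5), upper = c(1.9, 3.5, 3.0)),
    vlao = list(sense = "minimize", pInit = c(1.6, 3.0, 2.0),
                tol = 1e-6, maxIter = 500L),
    surrogate = list(mode = "taylor", pStar = NULL),
    filters = list(strict = list(l_min = 2.0, dp_norm = 0.75),
                   loose = list(l_min = 2.5, dp_norm = 1.0)))
}

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML or JSON file path, or a list. Unknown top-level keys
#' are rejected; missing keys fall back to documented defaults except
#' \code{bounds}, which must always be present.
#'
#' @param config path or list.
#' @return validated config list.
#' @export
readConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$bounds))
    stop("config schema error: required field 'bounds' is missing")
  merged <- utils::modifyList(defaults, config)
  if (is.null(merged$bounds$lower) || is.null(merged$bounds$upper))
    stop("config schema error: bounds must have 'lower' and 'upper'")
  if (!merged$database %in% c("synthetic", "packaged"))
    stop("config schema error: database must be 'synthetic' or 'packaged'")
  if (!merged$surrogate$mode %in%
      c("taylor", "weighted", "direct", "filter-only"))
    stop("config schema error: surrogate mode must be one of ",
         "taylor, weighted, direct, filter-only")
  merged
}

.configFilters <- function(cfg) {
  fl <- lapply(names(cfg$filters), function(nm)
    filterSpec(cfg$filters[[nm]]$l_min, cfg$filters[[nm]]$dp_norm, nm))
  names(fl) <- names(cfg$filters)
  fl
}

#' Run the full virtual-ligand screening pipeline
#'
#' Executes the stages in order: build the ligand parameter database
#' (synthetic backend + PCA + projection, or the packaged database),
#' run the VLAO optimization, build the requested surrogate, and rank
#' the database ligands after reliability filtering. Intermediate
#' artifacts (database CSV, trajectory JSON, report CSV, summary text)
#' are written to \code{outputDir} when set. Deterministic for a fixed
#' config and seed.
#'
#' In "filter-only" mode no backend is needed: a reference point
#' \code{surrogate$pStar} from a completed VLAO run is combined with the
#' database and the filters, and the summary lists the per-filter
#' counts.
#'
#' @param config path to a YAML/JSON config or a config list (see
#'   \code{\link{readConfig}}).
#' @return list with elements db, trajectory, surrogate, report (a
#'   \linkS4class{RankingReport} or filter-only table), counts, and
#'   files (paths written).
#' @export
runPipeline <- function(config) {
  cfg <- readConfig(config)
  bounds <- paramBounds(unlist(cfg$bounds$lower), unlist(cfg$bounds$upper))
  filters <- .configFilters(cfg)
  outDir <- cfg$outputDir
  files <- character(0)
  emit <- function(name, writer) {
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      path <- file.path(outDir, name)
      writer(path)
      files[[length(files) + 1L]] <<- path
    }
  }

  ## stage: build-db
  surface <- NULL
  if (cfg$database == "packaged") {
    db <- ligandDatabase()
  } else {
    surface <- syntheticSurface(
      n = cfg$backend$n, m = cfg$backend$m, seed = cfg$seed,
      bounds = bounds, bumpFraction = cfg$backend$bumpFraction,
      warp = cfg$backend$warp)
    ligs <- syntheticLigandSet(surface, k = cfg$ligands$count,
                               deltaRange = unlist(cfg$ligands$deltaRange),
                               seed = cfg$seed)
    tab <- buildDissociationTable(ligs, paste0("Fg", seq_len(surface@m)),
                                  surface)
    pca <- fitPCA(tab)
    bk <- pcaBackend(surface, pca)
    xs <- lapply(seq_len(nrow(tab)),
                 function(i) toDescriptor(pca, tab[i, ]))
    names(xs) <- rownames(tab)
    prs <- projectAll(xs, bk, seed = cfg$seed)
    db <- data.frame(id = names(prs), name = names(prs),
                     r0 = vapply(prs, function(r) r@p[1L], numeric(1)),
                     a1 = vapply(prs, function(r) r@p[2L], numeric(1)),
                     b1 = vapply(prs, function(r) r@p[3L], numeric(1)),
                     l_min = vapply(prs, residual, numeric(1)),
                     row.names = NULL, stringsAsFactors = FALSE)
  }
  emit("param_db.csv", function(p) saveParamDb(db, p))

  ## stage: filter-only short-circuit
  if (cfg$surrogate$mode == "filter-only") {
    pStar <- as.numeric(unlist(cfg$surrogate$pStar))
    if (length(pStar) == 0L)
      stop("filter-only mode requires surrogate$pStar")
    counts <- vapply(filters, function(f)
      nrow(applyFilter(db, pStar, bounds, f)), numeric(1))
    summaryLines <- c(
      sprintf("filter-only summary, p* = (%s)",
              paste(format(pStar), collapse = ", ")),
      sprintf("%s: %d ligands pass", names(counts), as.integer(counts)))
    emit("summary.txt", function(p) writeLines(summaryLines, p))
    return(list(db = db, trajectory = NULL, surrogate = NULL,
                report = NULL, counts = counts, files = files))
  }

  ## stage: vlao
  if (is.null(surface))
    stop("surrogate modes other than filter-only require the synthetic ",
         "backend (database = 'synthetic')")
  traj <- vlaoOptimize(surface, bounds,
                       pInit = as.numeric(unlist(cfg$vlao$pInit)),
                       sense = cfg$vlao$sense, tol = cfg$vlao$tol,
                       maxIter = cfg$vlao$maxIter)
  emit("trajectory.json", function(p) writeTrajectory(traj, p))

  ## stage: predict + rank
  surrogate <- switch(cfg$surrogate$mode,
    taylor = taylorSurrogateAt(surface, traj@pStar),
    weighted = trajectorySurrogate(traj, surface, bounds),
    direct = surface)
  report <- rankLigands(db, surrogate, pStar = traj@pStar,
                        bounds = bounds, sense = cfg$vlao$sense,
                        filters = filters)
  counts <- filterCounts(report)
  emit("report.csv", function(p) writeRankingReport(report, p))
  emit("summary.txt", function(p) {
    lines <- c(sprintf("vlscreen pipeline summary (seed %d)", cfg$seed),
               sprintf("p* = (%s)",
                       paste(sprintf("%.4f", traj@pStar), collapse = ", ")),
               sprintf("%s: %d ligands pass", names(counts),
                       as.integer(counts)))
    writeLines(lines, p)
  })
  list(db = db, trajectory = traj, surrogate = surrogate, report = report,
       counts = counts, files = files)
}
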