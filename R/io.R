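#' @include AllClasses.R
NULL

parseBool <- function(x, column) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t")] <- TRUE
  out[v %in% c("0", "false", "f")] <- FALSE
  if (anyNA(out))
    stopData("column '", column, "' has unparseable boolean value(s) in ",
             "row(s) ", paste(head(which(is.na(out)), 5L), collapse = ", "),
             " (accepted: 0, 1, true, false, T, F)")
  out
}

#' Read a cell table from CSV
#'
#' Tolerant RFC-4180 reader for the documented cell-table format: one
#' row per detected cell, boolean marker columns accepting
#' `{0, 1, true, false, T, F}` case-insensitively, `#` comment lines
#' (used for embedded provenance headers) ignored.  Unknown extra
#' columns are preserved untouched.  Invariant violations (NeuN and
#' Sox9 both set, GAD67 without NeuN, nonpositive area) raise data
#' errors citing the offending rows.
#'
#' @param path CSV file path.
#' @return a [CellTable-class].
#' @seealso [writeCellTable()]
#' @export
readCellTable <- function(path) {
  if (!file.exists(path)) stopUsage("file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (nrow(df) == 0L) stopData("empty cell table: ", path)
  missing <- setdiff(CELLTABLE_COLUMNS, colnames(df))
  if (length(missing))
    stopData("missing required column(s) in ", path, ": ",
             paste(missing, collapse = ", "))
  for (m in intersect(c(MARKER_COLUMNS, TRUTH_COLUMNS), colnames(df)))
    df[[m]] <- parseBool(df[[m]], m)
  CellTable(df)
}

#' Write a cell table to CSV
#'
#' Writes the documented fixed-header CSV, preceded by `#` comment lines
#' embedding the seed and configuration fingerprint when supplied.
#' Latent ground-truth columns are dropped unless `truth = TRUE`, so
#' simulated tables can double as blinded fixtures.
#'
#' @param cells a [CellTable-class].
#' @param path output CSV path.
#' @param truth keep the `latent_active1` / `latent_active2` columns.
#' @param seed,configHash optional provenance recorded as `#` header
#'   comments.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(cells, path, truth = FALSE, seed = NULL,
                           configHash = NULL) {
  df <- asCellDF(cells)
  if (!truth) df <- df[setdiff(colnames(df), TRUTH_COLUMNS)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# retag cell table v1", con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(configHash)) writeLines(paste0("# config: ", configHash), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-animal overlap counts from CSV
#'
#' Expects columns `animal_id`, `region`, `N`, `K`, `n`, `O` (one row
#' per animal/region); `#` comment lines are ignored and extra columns
#' preserved.  Count invariants are enforced on load.
#'
#' @param path CSV file path.
#' @return an [OverlapCounts-class].
#' @export
readOverlapCounts <- function(path) {
  if (!file.exists(path)) stopUsage("file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (nrow(df) == 0L) stopData("empty overlap-count table: ", path)
  OverlapCounts(df)
}

#' Fingerprint a configuration object
#'
#' Deterministic 32-bit hash of the ASCII serialization of an R object,
#' reported as 8 hex digits.  Embedded in output headers so re-running
#' with the archived configuration reproduces the file.
#'
#' @param x any serializable R object.
#' @return 8-character hex string.
#' @export
configFingerprint <- function(x) {
  txt <- rawToChar(serialize(x, NULL, ascii = TRUE))
  sprintf("%08x", hashString(txt))
}

#' Run the full analysis pipeline
#'
#' Composes the stages end-to-end on real or simulated input:
#' quantification (marker densities per animal/region), reactivation
#' (overlap tabulation, per-animal RI, cohort t-test per condition-pair
#' arm) and group statistics (pooled t-test of the SD-SD vs NSD-NSD
#' overlap-of-tagged percentages when both arms are present).  Writes
#' `densities.csv`, `reactivation.csv` and `summary.json` into
#' `config$out_dir`, each embedding the seed and configuration
#' fingerprint; the run is deterministic given inputs and seed.
#'
#' @param config named list (or path to a YAML/JSON file) with fields:
#'   `cells` (input CSV path) or `simulate` (list of [simConfig()]
#'   arguments), `pairs` (condition pairs to simulate, default
#'   `c("SD-SD", "NSD-NSD")`), `region` (default `"CA1"`), `marker`
#'   (default `"cfos"`), `out_dir`, `seed`, and optional flags `truth`,
#'   `log_ri`, `area_weighted`.
#' @return the summary list, invisibly; stage errors propagate with the
#'   stage name prepended.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopUsage("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopUsage("config must be a list or a file path")
  region <- config$region %||% "CA1"
  marker <- config$marker %||% "cfos"
  outDir <- config$out_dir
  if (is.null(outDir)) stopUsage("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fingerprint <- configFingerprint(config)

  stage <- function(name, expr) {
    tryCatch(expr, retag_error = function(e) {
      retagStop(paste0("stage '", name, "': ", conditionMessage(e)),
                class(e)[1L])
    })
  }

  cells <- stage("input", {
    if (!is.null(config$cells)) readCellTable(config$cells)
    else {
      simArgs <- config$simulate %||% list()
      simArgs$seed <- seed
      if (!is.null(simArgs$act1)) simArgs$act1 <- as.matrix(simArgs$act1)
      if (!is.null(simArgs$act2)) simArgs$act2 <- as.matrix(simArgs$act2)
      simulateCohort(do.call(simConfig, simArgs),
                     config$pairs %||% c("SD-SD", "NSD-NSD"))
    }
  })

  densities <- stage("quantify",
    computeDensities(cells, marker,
                     areaWeighted = isTRUE(config$area_weighted)))

  react <- stage("react", {
    counts <- tabulateOverlap(cells, region)
    as.data.frame(reactivationIndex(counts))
  })

  react$pair <- paste(react$epoch1, react$epoch2, sep = "-")
  arms <- split(react, react$pair)
  riTests <- stage("react", lapply(arms, function(a) {
    if (sum(is.finite(a$RI)) < 2L) return(NULL)
    cohortRITest(a$RI, logScale = isTRUE(config$log_ri))
  }))

  overlapTest <- stage("stats", {
    if (all(c("SD-SD", "NSD-NSD") %in% names(arms)) &&
        nrow(arms[["SD-SD"]]) >= 2L && nrow(arms[["NSD-NSD"]]) >= 2L) {
      ht <- tFromRaw(arms[["SD-SD"]]$pct_of_tagged,
                     arms[["NSD-NSD"]]$pct_of_tagged)
      list(comparison = "pct_of_tagged SD-SD vs NSD-NSD",
           t = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value)
    }
  })

  header <- c("# retag pipeline output",
              paste0("# seed: ", seed),
              paste0("# config: ", fingerprint))
  writeCsvWithHeader <- function(df, file) {
    con <- file(file, "w"); on.exit(close(con))
    writeLines(header, con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  writeCsvWithHeader(densities, file.path(outDir, "densities.csv"))
  writeCsvWithHeader(react, file.path(outDir, "reactivation.csv"))

  summary <- list(
    seed = seed,
    config_fingerprint = fingerprint,
    region = region,
    marker = marker,
    n_animals = length(unique(cells$animal_id)),
    mean_density_by_arm = lapply(
      split(densities$density,
            paste(densities$epoch1, densities$epoch2, sep = "-")), mean),
    ri_test_by_arm = riTests[!vapply(riTests, is.null, logical(1L))],
    overlap_pct_test = overlapTest
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
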