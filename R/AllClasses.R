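#' @include conditions.R
NULL

CELL_CLASSES <- c("excitatory", "inhibitory", "astro", "other")
CONDITIONS <- c("NSD", "SD")
CONDITION_PAIRS <- c("NSD-NSD", "NSD-SD", "SD-NSD", "SD-SD")

MARKER_COLUMNS <- c("dapi", "neun", "sox9", "gad67", "ha", "cfos")
CELLTABLE_COLUMNS <- c(
  "cell_id", "animal_id", "epoch1", "epoch2", "region",
  "section_id", "section_area", MARKER_COLUMNS
)
TRUTH_COLUMNS <- c("latent_active1", "latent_active2")
OVERLAP_COLUMNS <- c("animal_id", "region", "N", "K", "n", "O")

checkProb <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    paste0(what, " must be a probability in [0, 1]")
  else NULL
}

checkActMap <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m) ||
      !identical(rownames(m), CONDITIONS) ||
      !identical(colnames(m), CELL_CLASSES))
    return(paste0(what, " must be a 2x4 numeric matrix with rownames ",
                  "NSD,SD and colnames ", paste(CELL_CLASSES, collapse = ",")))
  checkProb(as.vector(m), paste0(what, " entries"))
}

#' Simulation configuration for two-epoch tagging cohorts
#'
#' Holds the full parameterization of the generative model: cell-type
#' composition, per-condition/per-class activation probabilities for the
#' two epochs, the tagging channel (efficiency and background labeling),
#' the reactivation bias, the c-Fos detection channel, and the cohort
#' layout (animals, sections, quantified area).
#'
#' @slot cellsPerRegion integer, DAPI+ cells simulated per animal per region.
#' @slot fracNeuron probability a cell is a neuron (NeuN+).
#' @slot fracInhib probability a neuron is inhibitory (GAD67+).
#' @slot fracAstro probability a non-neuron is an astrocyte (Sox9+).
#' @slot act1,act2 2x4 matrices (rows `NSD`,`SD`; columns `excitatory`,
#'   `inhibitory`,`astro`,`other`) of epoch-1 / epoch-2 activation
#'   probabilities.
#' @slot tagEff probability an epoch-1-active cell becomes HA+.
#' @slot bgTag probability an epoch-1-inactive cell becomes HA+
#'   (background labeling).
#' @slot reactBias positive odds multiplier \eqn{\beta} applied to epoch-2
#'   activation of cells that were active in epoch 1, through a logistic
#'   link: \eqn{p_2' = \sigma(\mathrm{logit}(p_2) + \log\beta)}.
#' @slot cfosSens probability an epoch-2-active cell is scored c-Fos+.
#' @slot cfosFpr probability an epoch-2-inactive cell is scored c-Fos+.
#' @slot animalsPerArm integer, animals simulated per condition pair.
#' @slot sectionsPerAnimal integer in \{2, 3\}, imaged sections per animal.
#' @slot sectionArea positive quantified area per section, mm^2.
#' @slot regions character vector of region labels to simulate.
#' @slot seed integer master seed; per-animal streams are derived from it.
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  cellsPerRegion = "integer",
  fracNeuron = "numeric",
  fracInhib = "numeric",
  fracAstro = "numeric",
  act1 = "matrix",
  act2 = "matrix",
  tagEff = "numeric",
  bgTag = "numeric",
  reactBias = "numeric",
  cfosSens = "numeric",
  cfosFpr = "numeric",
  animalsPerArm = "integer",
  sectionsPerAnimal = "integer",
  sectionArea = "numeric",
  regions = "character",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msgs <- c(
    if (object@cellsPerRegion < 1L) "cellsPerRegion must be >= 1",
    checkProb(object@fracNeuron, "fracNeuron"),
    checkProb(object@fracInhib, "fracInhib"),
    checkProb(object@fracAstro, "fracAstro"),
    checkActMap(object@act1, "act1"),
    checkActMap(object@act2, "act2"),
    checkProb(object@tagEff, "tagEff"),
    checkProb(object@bgTag, "bgTag"),
    if (!is.finite(object@reactBias) || object@reactBias <= 0)
      "reactBias must be a finite positive odds multiplier",
    checkProb(object@cfosSens, "cfosSens"),
    checkProb(object@cfosFpr, "cfosFpr"),
    if (object@animalsPerArm < 1L) "animalsPerArm must be >= 1",
    if (!object@sectionsPerAnimal %in% c(2L, 3L))
      "sectionsPerAnimal must be 2 or 3",
    if (!is.finite(object@sectionArea) || object@sectionArea <= 0)
      "sectionArea must be positive (mm^2)",
    if (length(object@regions) < 1L) "at least one region label required",
    if (object@cellsPerRegion < object@sectionsPerAnimal)
      "cellsPerRegion must be >= sectionsPerAnimal"
  )
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SimConfig compact summary of the configuration.
#' @param object a `SimConfig`.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: two-epoch tagging cohort generator\n")
  cat(sprintf("  %d cells/region x %d region(s), %d animals/arm, %d sections of %.3g mm^2\n",
              object@cellsPerRegion, length(object@regions),
              object@animalsPerArm, object@sectionsPerAnimal,
              object@sectionArea))
  cat(sprintf("  composition: neuron %.2f (inhib %.2f), astro|non-neuron %.2f\n",
              object@fracNeuron, object@fracInhib, object@fracAstro))
  cat(sprintf("  excitatory activation  NSD %.3g / SD %.3g (epoch 1)\n",
              object@act1["NSD", "excitatory"], object@act1["SD", "excitatory"]))
  cat(sprintf("  tagging eff %.2f, background %.3g; reactivation bias beta = %.3g\n",
              object@tagEff, object@bgTag, object@reactBias))
  cat(sprintf("  c-Fos detection sens %.2f, fpr %.3g; seed %d\n",
              object@cfosSens, object@cfosFpr, object@seed))
  invisible(NULL)
})

#' Per-cell marker table
#'
#' A `DFrame` subclass holding one row per detected cell with boolean
#' marker columns (`dapi`, `neun`, `sox9`, `gad67`, `ha`, `cfos`) and
#' animal / condition-pair / region / section metadata.  Simulated tables
#' additionally carry the latent ground-truth activity columns
#' `latent_active1` / `latent_active2`.
#'
#' Invariants enforced by the validity method: `dapi` is TRUE for every
#' row (cells are nucleus-detected); `neun` and `sox9` are never both
#' TRUE; `gad67` implies `neun`; `section_area > 0`.
#'
#' @exportClass CellTable
setClass("CellTable", contains = "DFrame")

cellTableProblems <- function(df, checkArea = TRUE) {
  missing <- setdiff(CELLTABLE_COLUMNS, colnames(df))
  if (length(missing))
    return(paste0("missing required column(s): ",
                  paste(missing, collapse = ", ")))
  bad <- function(idx, what) {
    if (any(idx))
      paste0(what, " (row", if (sum(idx) > 1) "s", " ",
             paste(head(which(idx), 5L), collapse = ", "),
             if (sum(idx) > 5L) ", ...", ")")
  }
  for (m in MARKER_COLUMNS)
    if (!is.logical(df[[m]]) || anyNA(df[[m]]))
      return(paste0("marker column '", m, "' must be logical without NA"))
  c(
    bad(!df$dapi, "dapi must be TRUE for every detected cell"),
    bad(df$neun & df$sox9, "neun and sox9 are mutually exclusive"),
    bad(df$gad67 & !df$neun, "gad67 implies neun"),
    if (checkArea)
      bad(!is.finite(df$section_area) | df$section_area <= 0,
          "section_area must be positive"),
    bad(!df$epoch1 %in% CONDITIONS | !df$epoch2 %in% CONDITIONS,
        "epoch1/epoch2 must be 'NSD' or 'SD'")
  )
}

setValidity("CellTable", function(object) {
  msgs <- cellTableProblems(as.data.frame(object))
  if (length(msgs)) msgs else TRUE
})

#' Construct a validated CellTable
#'
#' @param x a `data.frame` or `DataFrame` with the documented columns.
#' @return a `CellTable`; invariant violations raise a data error naming
#'   the offending rows.
#' @export
CellTable <- function(x) {
  df <- as.data.frame(x)
  msgs <- cellTableProblems(df)
  if (length(msgs)) stopData("invalid cell table: ",
                             paste(msgs, collapse = "; "))
  new("CellTable", DataFrame(df, check.names = FALSE))
}

#' Per-animal overlap counts
#'
#' One row per animal/region with the four counts of the overlap model:
#' `N` (DAPI+ nuclei in the quantified region), `K` (HA-tagged cells),
#' `n` (c-Fos+ cells) and `O` (double-labeled cells).  Validity enforces
#' `0 <= K <= N`, `0 <= n <= N` and
#' `max(0, K + n - N) <= O <= min(K, n)`.
#'
#' @exportClass OverlapCounts
setClass("OverlapCounts", contains = "DFrame")

overlapProblems <- function(df) {
  missing <- setdiff(OVERLAP_COLUMNS, colnames(df))
  if (length(missing))
    return(paste0("missing required column(s): ",
                  paste(missing, collapse = ", ")))
  with(df, {
    bad <- !is.finite(N) | !is.finite(K) | !is.finite(n) | !is.finite(O) |
      N < 0 | K < 0 | n < 0 | O < 0 | K > N | n > N |
      O > pmin(K, n) | O < pmax(0, K + n - N)
    if (any(bad))
      paste0("overlap count invariants violated (0<=K,n<=N, ",
             "max(0,K+n-N)<=O<=min(K,n)) in row(s) ",
             paste(head(which(bad), 5L), collapse = ", "))
  })
}

setValidity("OverlapCounts", function(object) {
  msgs <- overlapProblems(as.data.frame(object))
  if (length(msgs)) msgs else TRUE
})

#' Construct validated per-animal overlap counts
#'
#' @param x a `data.frame` with columns `animal_id`, `region`,
#'   `N`, `K`, `n`, `O` (one row per animal/region).
#' @return an `OverlapCounts` object.
#' @export
OverlapCounts <- function(x) {
  df <- as.data.frame(x)
  msgs <- overlapProblems(df)
  if (length(msgs)) stopData("invalid overlap counts: ",
                             paste(msgs, collapse = "; "))
  new("OverlapCounts", DataFrame(df, check.names = FALSE))
}

#' Per-animal reactivation results
#'
#' `DFrame` subclass produced by [reactivationIndex()]: the input counts
#' plus expected overlap `E`, reactivation index `RI`, the two overlap
#' percentages (`pct_of_tagged` = 100*O/K, `pct_of_cfos` = 100*O/n) and
#' the one-sided upper-tail hypergeometric p-value `p_hyper`.
#'
#' @exportClass ReactivationTable
setClass("ReactivationTable", contains = "DFrame")

#' Condition-pair labels
#'
#' The four two-epoch arms of the design. `parseConditionPair` splits a
#' label such as `"SD-NSD"` into its epoch-1 and epoch-2 conditions.
#'
#' @param pair a single string, one of `"NSD-NSD"`, `"NSD-SD"`,
#'   `"SD-NSD"`, `"SD-SD"`.
#' @return a named character vector with elements `epoch1` and `epoch2`.
#' @examples
#' parseConditionPair("SD-NSD")
#' @export
parseConditionPair <- function(pair) {
  if (!is.character(pair) || length(pair) != 1L ||
      !pair %in% CONDITION_PAIRS)
    stopUsage("condition pair must be one of ",
              paste(CONDITION_PAIRS, collapse = ", "))
  parts <- strsplit(pair, "-", fixed = TRUE)[[1L]]
  c(epoch1 = parts[1L], epoch2 = parts[2L])
}

#' @rdname parseConditionPair
#' @export
conditionPairs <- function() CONDITION_PAIRS
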