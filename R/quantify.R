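#' @include AllClasses.R
NULL

asCellDF <- function(cells, checkArea = TRUE) {
  if (is(cells, "CellTable")) return(as.data.frame(cells))
  df <- as.data.frame(cells)
  msgs <- cellTableProblems(df, checkArea = checkArea)
  if (length(msgs)) stopData("invalid cell table: ",
                             paste(msgs, collapse = "; "))
  df
}

#' Area-normalized marker densities per animal and region
#'
#' For every section the density is the count of marker-positive cells
#' divided by the section's quantified area; the per-animal value is the
#' unweighted mean over that animal's sections, matching the convention
#' of averaging 2-3 imaged sections per mouse.  Setting
#' `areaWeighted = TRUE` instead pools counts over sections and divides
#' by the summed area.
#'
#' @param cells a [CellTable-class] (or data.frame with the same columns).
#' @param marker name of a logical marker column, e.g. `"cfos"` or `"ha"`.
#' @param areaWeighted pool counts/areas across sections instead of
#'   averaging per-section densities.
#' @return data.frame with one row per (animal, region): columns
#'   `animal_id`, `region`, `epoch1`, `epoch2`, `marker`, `density`
#'   (count per mm^2).
#' @examples
#' cells <- simulateAnimal(simConfig(cellsPerRegion = 300), "SD-SD", "m1")
#' computeDensities(cells, "cfos")
#' @export
computeDensities <- function(cells, marker, areaWeighted = FALSE) {
  # defer area validation to the per-section check below, which can
  # name the offending section rather than a bare row number
  df <- asCellDF(cells, checkArea = FALSE)
  if (!is.character(marker) || length(marker) != 1L ||
      !marker %in% colnames(df) || !is.logical(df[[marker]]))
    stopUsage("unknown marker column '", marker,
              "': expected one of ", paste(MARKER_COLUMNS, collapse = ", "))

  secArea <- aggregate(section_area ~ animal_id + region + section_id,
                       data = df, FUN = function(a) a[1L])
  inconsistent <- aggregate(section_area ~ animal_id + region + section_id,
                            data = df,
                            FUN = function(a) length(unique(a)) > 1L)
  if (any(inconsistent$section_area))
    stopData("section_area differs within section(s): ",
             paste(inconsistent$section_id[inconsistent$section_area],
                   collapse = ", "))
  badArea <- !is.finite(secArea$section_area) | secArea$section_area <= 0
  if (any(badArea))
    stopData("nonpositive or missing section_area for section(s): ",
             paste(secArea$section_id[badArea], collapse = ", "))

  pos <- aggregate(df[[marker]],
                   by = df[c("animal_id", "region", "section_id")],
                   FUN = sum)
  names(pos)[4L] <- "count"
  sec <- merge(secArea, pos,
               by = c("animal_id", "region", "section_id"), sort = TRUE)
  sec$density <- sec$count / sec$section_area

  perAnimal <- if (areaWeighted) {
    num <- aggregate(count ~ animal_id + region, data = sec, FUN = sum)
    den <- aggregate(section_area ~ animal_id + region, data = sec, FUN = sum)
    out <- merge(num, den, by = c("animal_id", "region"), sort = TRUE)
    out$density <- out$count / out$section_area
    out[c("animal_id", "region", "density")]
  } else {
    aggregate(density ~ animal_id + region, data = sec, FUN = mean)
  }

  meta <- unique(df[c("animal_id", "epoch1", "epoch2")])
  out <- merge(perAnimal, meta, by = "animal_id", sort = TRUE)
  out$marker <- marker
  out <- out[order(out$animal_id, out$region),
             c("animal_id", "region", "epoch1", "epoch2", "marker", "density")]
  rownames(out) <- NULL
  out
}

#' Fold induction of a treated mean over a control mean
#'
#' @param meanTreated,meanControl group means on the same scale
#'   (typically densities in cells per mm^2).
#' @return `meanTreated / meanControl`.
#' @examples
#' foldInduction(218.99, 142.53)
#' @export
foldInduction <- function(meanTreated, meanControl) {
  if (!is.numeric(meanTreated) || !is.numeric(meanControl))
    stopUsage("means must be numeric")
  if (any(!is.finite(meanControl)) || any(meanControl <= 0))
    stopDomain("control mean must be positive")
  meanTreated / meanControl
}

#' Cell-type composition of c-Fos+ cells in a region
#'
#' Among c-Fos+ cells of the region: the fraction that are neurons
#' (NeuN+), astrocytes (Sox9+) and other cell types (neither), which sum
#' to 1 exactly because NeuN and Sox9 are mutually exclusive; plus the
#' excitatory fraction (NeuN+ minus GAD67+, normalized to NeuN+) among
#' the c-Fos+ neurons.
#'
#' @param cells a [CellTable-class] or equivalent data.frame.
#' @param region region label to analyse.
#' @return one-row data.frame with columns `region`, `n_cfos`,
#'   `fraction_neun`, `fraction_sox9`, `fraction_other`,
#'   `fraction_excitatory`, `empty`.  When the region has no c-Fos+
#'   cells the fractions are `NA` and `empty` is `TRUE`.
#' @export
cfosComposition <- function(cells, region) {
  df <- asCellDF(cells)
  if (!region %in% df$region)
    stopUsage("region '", region, "' not present in the cell table")
  cf <- df[df$region == region & df$cfos, , drop = FALSE]
  if (nrow(cf) == 0L)
    return(data.frame(region = region, n_cfos = 0L,
                      fraction_neun = NA_real_, fraction_sox9 = NA_real_,
                      fraction_other = NA_real_,
                      fraction_excitatory = NA_real_, empty = TRUE))
  fNeun <- mean(cf$neun)
  fSox9 <- mean(cf$sox9)
  nNeun <- sum(cf$neun)
  data.frame(
    region = region, n_cfos = nrow(cf),
    fraction_neun = fNeun, fraction_sox9 = fSox9,
    fraction_other = 1 - fNeun - fSox9,
    fraction_excitatory = if (nNeun > 0)
      excitatoryFraction(nNeun, sum(cf$gad67)) else NA_real_,
    empty = FALSE
  )
}

#' Excitatory fraction of a neuronal population
#'
#' `(neunCount - gad67Count) / neunCount`: the NeuN+ fraction left after
#' subtracting the inhibitory (GAD67+) fraction, normalized to NeuN+.
#'
#' @param neunCount number of NeuN+ cells (> 0).
#' @param gad67Count number of GAD67+ cells (GAD67+ implies NeuN+, so
#'   this may not exceed `neunCount`).
#' @return proportion in \[0, 1\].
#' @examples
#' excitatoryFraction(100, 5)  # 0.95
#' @export
excitatoryFraction <- function(neunCount, gad67Count) {
  if (!is.numeric(neunCount) || !is.numeric(gad67Count) ||
      any(gad67Count < 0))
    stopUsage("counts must be non-negative numbers")
  if (any(neunCount == 0))
    stopDomain("neunCount must be positive")
  if (any(gad67Count > neunCount))
    stopData("gad67Count exceeds neunCount: GAD67+ implies NeuN+")
  (neunCount - gad67Count) / neunCount
}
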