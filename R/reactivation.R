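#' @include AllClasses.R
NULL

#' Tabulate two-epoch label overlap per animal
#'
#' Counts, per animal within the requested region: `N` DAPI+ nuclei,
#' `K` HA-tagged cells (epoch-1 label), `n` c-Fos+ cells (epoch-2
#' label) and `O` double-labeled cells.  The overlap-count invariants
#' hold by construction.
#'
#' @param cells a [CellTable-class] or equivalent data.frame.
#' @param region region label present in the table.
#' @return an [OverlapCounts-class] with one row per animal, carrying the
#'   condition pair alongside the counts.
#' @examples
#' cells <- simulateAnimal(simConfig(cellsPerRegion = 500), "SD-SD", "m1")
#' tabulateOverlap(cells, "CA1")
#' @export
tabulateOverlap <- function(cells, region) {
  df <- asCellDF(cells)
  if (!region %in% df$region)
    stopUsage("region '", region, "' not present in the cell table")
  df <- df[df$region == region, , drop = FALSE]
  tallies <- rowsum(
    cbind(N = as.integer(df$dapi), K = as.integer(df$ha),
          n = as.integer(df$cfos), O = as.integer(df$ha & df$cfos)),
    df$animal_id)
  ids <- rownames(tallies)
  meta <- match(ids, df$animal_id)
  counts <- data.frame(
    animal_id = ids, region = region,
    epoch1 = df$epoch1[meta], epoch2 = df$epoch2[meta],
    N = as.integer(tallies[, "N"]), K = as.integer(tallies[, "K"]),
    n = as.integer(tallies[, "n"]), O = as.integer(tallies[, "O"]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  OverlapCounts(counts[order(counts$animal_id), , drop = FALSE])
}

#' Expected overlap under random activation
#'
#' Under the random-activation model, epoch-2 activation is independent
#' of the epoch-1 tag, so the probability that a tagged cell is c-Fos+
#' equals the population c-Fos+ fraction and the expected double-label
#' count is \eqn{E = n \cdot (K / N)}.
#'
#' @param counts an [OverlapCounts-class] or data.frame with columns
#'   `N`, `K`, `n` (and optionally `O`).
#' @return numeric vector of expected overlaps, one per row.
#' @examples
#' expectedOverlap(data.frame(N = 1000, K = 100, n = 200))  # 20
#' @export
expectedOverlap <- function(counts) {
  df <- as.data.frame(counts)
  if (!all(c("N", "K", "n") %in% colnames(df)))
    stopUsage("counts must have columns N, K, n")
  if (any(df$N == 0)) stopDomain("N must be positive to define E = n*K/N")
  df$n * df$K / df$N
}

#' One-sided hypergeometric overlap test
#'
#' Upper-tail probability \eqn{P(X \ge O)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}: the chance of seeing
#' at least the observed number of double-labeled cells if the `n`
#' c-Fos+ cells were drawn uniformly at random from the `N` nuclei,
#' irrespective of the HA tag.  A per-animal exact counterpart of the
#' cohort-level random-activation null.
#'
#' @param counts an [OverlapCounts-class] or data.frame with columns
#'   `N`, `K`, `n`, `O` (invariants enforced).
#' @return numeric vector of p-values in (0, 1\].
#' @examples
#' hypergeomTest(data.frame(animal_id = "m1", region = "CA1",
#'                          N = 10, K = 3, n = 4, O = 3))  # 7/210
#' @export
hypergeomTest <- function(counts) {
  df <- as.data.frame(counts)
  need <- c("N", "K", "n", "O")
  if (!all(need %in% colnames(df)))
    stopUsage("counts must have columns N, K, n, O")
  bad <- overlapProblems(cbind(animal_id = "", region = "", df[need]))
  if (length(bad)) stopData(bad)
  phyper(df$O - 1, m = df$K, n = df$N - df$K, k = df$n, lower.tail = FALSE)
}

#' Per-animal reactivation index
#'
#' For each animal computes the expected overlap `E = n*K/N`, the
#' reactivation index `RI = O/E` (1 under random activation), the
#' overlap percentages `pct_of_tagged = 100*O/K` and
#' `pct_of_cfos = 100*O/n`, and the one-sided hypergeometric p-value.
#' Animals with `K = 0` or `n = 0` have undefined percentages / `RI`
#' (`NA`, with a logged notice) and are excluded downstream by
#' [cohortRITest()].
#'
#' @param counts an [OverlapCounts-class] or data.frame with columns
#'   `animal_id`, `region`, `N`, `K`, `n`, `O`.
#' @return a [ReactivationTable-class]: the input columns plus `E`, `RI`,
#'   `pct_of_tagged`, `pct_of_cfos`, `p_hyper`.
#' @examples
#' ri <- reactivationIndex(data.frame(animal_id = "m1", region = "CA1",
#'                                    N = 1000, K = 100, n = 200, O = 44))
#' ri$RI  # 2.2
#' @export
reactivationIndex <- function(counts) {
  df <- as.data.frame(if (is(counts, "OverlapCounts")) counts
                      else OverlapCounts(counts))
  df$E <- expectedOverlap(df)
  zeroE <- df$E == 0
  if (any(zeroE & df$O > 0))
    stopData("O > 0 with E = 0 is impossible under the overlap model ",
             "(O <= min(K, n) forces O = 0)")
  df$RI <- ifelse(zeroE, NA_real_, df$O / df$E)
  if (any(zeroE))
    message("reactivationIndex: RI undefined (K = 0 or n = 0) for animal(s) ",
            paste(df$animal_id[zeroE], collapse = ", "),
            "; excluded from cohort tests")
  df$pct_of_tagged <- ifelse(df$K > 0, 100 * df$O / df$K, NA_real_)
  df$pct_of_cfos <- ifelse(df$n > 0, 100 * df$O / df$n, NA_real_)
  df$p_hyper <- hypergeomTest(df[c("N", "K", "n", "O")])
  new("ReactivationTable", DataFrame(df, check.names = FALSE))
}

#' Cohort-level reactivation test
#'
#' Two-tailed one-sample t-test of the per-animal reactivation indices
#' against the random-activation value 1 (df = number of animals - 1).
#' With `logScale = TRUE` the test is instead of `log(RI)` against 0,
#' which is more robust to the right skew of a ratio statistic.
#' Non-finite values (animals with undefined RI) are dropped with a
#' logged notice.
#'
#' @param riValues numeric vector of per-animal reactivation indices.
#' @param logScale test `log(RI)` against 0 instead of RI against 1.
#' @return list with `mean`, `sem`, `t`, `df`, `p`, `n` (mean/sem are on
#'   the tested scale).
#' @examples
#' cohortRITest(c(1.5, 2.0, 2.5))
#' @export
cohortRITest <- function(riValues, logScale = FALSE) {
  x <- riValues[is.finite(riValues)]
  if (length(x) < length(riValues))
    message("cohortRITest: dropped ", length(riValues) - length(x),
            " animal(s) with undefined RI")
  if (length(x) < 2L)
    stopUsage("cohort test needs at least two animals with finite RI")
  mu <- 1
  if (logScale) {
    if (any(x <= 0)) stopData("log-scale test requires positive RI values")
    x <- log(x); mu <- 0
  }
  if (var(x) == 0)
    stopData("all RI values identical: the t-test is undefined; ",
             "report the exact per-animal values instead of a fabricated p")
  res <- oneSampleT(x, mu = mu)
  list(mean = mean(x), sem = sd(x) / sqrt(length(x)),
       t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, n = length(x))
}
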