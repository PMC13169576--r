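#' @include AllClasses.R
NULL

#' Group summary (mean, SEM, n)
#'
#' The unit of summary-statistic testing: a group's mean, standard error
#' of the mean, and number of animals, as printed in figure legends.
#'
#' @slot label group label.
#' @slot mean group mean.
#' @slot sem standard error of the mean (>= 0).
#' @slot n number of observations (>= 2).
#' @exportClass GroupSummary
setClass("GroupSummary", representation(
  label = "character", mean = "numeric", sem = "numeric", n = "integer"
))

setValidity("GroupSummary", function(object) {
  msgs <- c(
    if (!is.finite(object@mean)) "mean must be finite",
    if (!is.finite(object@sem) || object@sem < 0) "sem must be >= 0",
    if (object@n < 2L) "n must be >= 2"
  )
  if (length(msgs)) msgs else TRUE
})

#' @param label group label.
#' @param mean,sem,n group mean, standard error of the mean, group size.
#' @rdname GroupSummary-class
#' @examples
#' groupSummary("NSD", 180.64, 11.53, 5)
#' @export
groupSummary <- function(label, mean, sem, n) {
  obj <- try(new("GroupSummary", label = as.character(label),
                 mean = as.numeric(mean), sem = as.numeric(sem),
                 n = as.integer(n)), silent = TRUE)
  if (inherits(obj, "try-error"))
    stopUsage("invalid group summary: ", attr(obj, "condition")$message)
  obj
}

#' @describeIn GroupSummary-class summarize a numeric vector.
#' @param x numeric vector of raw observations.
#' @export
summarizeGroup <- function(x, label = "group") {
  if (length(x) < 2L) stopUsage("need at least two observations")
  groupSummary(label, mean(x), sd(x) / sqrt(length(x)), length(x))
}

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary '%s': %.4g ± %.4g (mean ± SEM), n = %d\n",
              object@label, object@mean, object@sem, object@n))
})

htestResult <- function(t, df, p, method, estimate, dataName) {
  structure(
    list(statistic = c(t = t), parameter = c(df = df), p.value = p,
         estimate = estimate, method = method, data.name = dataName,
         alternative = "two.sided"),
    class = "htest")
}

#' Student's t-test from printed summary statistics
#'
#' Reconstructs the unpaired two-tailed pooled (Student) t-test from each
#' group's mean, SEM and n, as printed in figure legends: per-group SDs
#' are recovered as `SEM * sqrt(n)`, variances pooled with
#' `df = n_a + n_b - 2`, and the two-tailed p taken from the t
#' distribution.  This is the reconstruction that reproduces the printed
#' t-statistics of standard analysis software from its own printed
#' summaries.
#'
#' @param a,b [GroupSummary-class] objects (see [groupSummary()]).
#' @return an object of class `"htest"` with the t statistic, df, and
#'   two-tailed p-value.
#' @examples
#' tFromSummary(groupSummary("NSD", 180.64, 11.53, 5),
#'              groupSummary("SD", 408.39, 14.27, 6))
#' @export
tFromSummary <- function(a, b) {
  if (!is(a, "GroupSummary") || !is(b, "GroupSummary"))
    stopUsage("a and b must be GroupSummary objects")
  validObject(a); validObject(b)
  va <- (a@sem * sqrt(a@n))^2  # per-group variance from SEM
  vb <- (b@sem * sqrt(b@n))^2
  df <- a@n + b@n - 2L
  pooled <- ((a@n - 1) * va + (b@n - 1) * vb) / df
  se <- sqrt(pooled * (1 / a@n + 1 / b@n))
  delta <- a@mean - b@mean
  if (se == 0) {
    t <- 0; p <- 1
    if (delta != 0) {
      warning("zero pooled variance with unequal means: |t| unbounded, ",
              "p reported below machine floor")
      t <- sign(delta) * Inf; p <- .Machine$double.xmin
    }
  } else {
    t <- delta / se
    p <- 2 * pt(-abs(t), df)
  }
  htestResult(t, df, p, "Two Sample t-test (pooled, from summary statistics)",
              c(`mean difference` = delta),
              paste(a@label, "vs", b@label))
}

#' Two-sample t-test on raw values
#'
#' Unpaired two-tailed t-test.  The pooled variant equals
#' [tFromSummary()] applied to the samples' own summaries to machine
#' precision (it is computed that way); the Welch variant uses
#' per-group variances with Welch-Satterthwaite df.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (Student, the default) or `"welch"`.
#' @return an object of class `"htest"`.
#' @examples
#' tFromRaw(c(1, 2, 3), c(4, 5, 6))
#' @export
tFromRaw <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    stopUsage("each group needs at least two observations")
  if (anyNA(x) || anyNA(y)) stopUsage("missing values not supported")
  if (variant == "pooled")
    return(tFromSummary(summarizeGroup(x, "x"), summarizeGroup(y, "y")))
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  se <- sqrt(vx + vy)
  delta <- mean(x) - mean(y)
  if (se == 0) {
    if (delta == 0)
      return(htestResult(0, length(x) + length(y) - 2L, 1,
                         "Welch Two Sample t-test",
                         c(`mean difference` = 0), "x vs y"))
    warning("zero variance with unequal means: |t| unbounded, ",
            "p reported below machine floor")
    return(htestResult(sign(delta) * Inf, length(x) + length(y) - 2L,
                       .Machine$double.xmin, "Welch Two Sample t-test",
                       c(`mean difference` = delta), "x vs y"))
  }
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  t <- delta / se
  htestResult(t, df, 2 * pt(-abs(t), df), "Welch Two Sample t-test",
              c(`mean difference` = delta), "x vs y")
}

#' One-sample t-test
#'
#' Two-tailed test of `mean(x)` against `mu`:
#' `t = (mean - mu) / (sd / sqrt(n))`, `df = n - 1`.  Used at cohort
#' level to test the mean reactivation index against 1.
#'
#' @param x numeric vector of length >= 2 with positive variance.
#' @param mu null value.
#' @return an object of class `"htest"`.
#' @examples
#' oneSampleT(c(1.5, 2.0, 2.5), mu = 1)
#' @export
oneSampleT <- function(x, mu = 0) {
  if (length(x) < 2L) stopUsage("need at least two observations")
  if (anyNA(x)) stopUsage("missing values not supported")
  if (var(x) == 0)
    stopData("zero variance: the t statistic is undefined; ",
             "report the exact values instead of a fabricated p")
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  htestResult(t, n - 1L, 2 * pt(-abs(t), n - 1L), "One Sample t-test",
              c(`mean` = mean(x)), deparse(substitute(x)))
}

#' Two-way ANOVA with Type III sums of squares
#'
#' Fits `values ~ factorA * factorB` with sum-to-zero contrasts and
#' reports Type III sums of squares, F and p per effect — the
#' convention of standard analysis software for unbalanced designs
#' (e.g. a 2x2 design with group sizes 5/6/6/6 and error df 19).  On
#' balanced data Type III coincides with the classical sequential
#' decomposition.
#'
#' @param values numeric response (e.g. per-animal densities).
#' @param factorA,factorB factors of the 2x2 (or larger) design, e.g.
#'   sleep condition (NSD/SD) and repetition (1x/2x).
#' @return data.frame with rows `A`, `B`, `A:B`, `Residuals` and columns
#'   `term`, `ss`, `df`, `F`, `p`; attribute `ss_type = "III"`.
#' @examples
#' twoWayAnova(c(1, 3, 1, 3, 5, 7, 5, 7),
#'             rep(c("a1", "a2"), each = 4),
#'             rep(c("b1", "b1", "b2", "b2"), 2))
#' @export
twoWayAnova <- function(values, factorA, factorB) {
  if (length(values) != length(factorA) || length(values) != length(factorB))
    stopUsage("values, factorA and factorB must have equal length")
  fA <- factor(factorA); fB <- factor(factorB)
  tab <- table(fA, fB)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1L, ]
    stopUsage("empty design cell: ", levels(fA)[empty[1L]], " x ",
              levels(fB)[empty[2L]])
  }
  if (nlevels(fA) < 2L || nlevels(fB) < 2L)
    stopUsage("each factor needs at least two levels")
  if (length(values) - nlevels(fA) * nlevels(fB) < 1L)
    stopUsage("no residual degrees of freedom")
  if (var(values) == 0) {
    # constant response: every sum of squares is zero, F defined as 0
    dfRes <- length(values) - nlevels(fA) * nlevels(fB)
    dfs <- c(nlevels(fA) - 1L, nlevels(fB) - 1L,
             (nlevels(fA) - 1L) * (nlevels(fB) - 1L), dfRes)
    out <- data.frame(term = c("A", "B", "A:B", "Residuals"),
                      ss = 0, df = dfs, F = c(0, 0, 0, NA),
                      p = NA_real_)
    attr(out, "ss_type") <- "III"
    return(out)
  }
  dat <- data.frame(y = values, A = fA, B = fB)
  fit <- lm(y ~ A * B, data = dat,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  a3 <- car::Anova(fit, type = "III")
  keep <- c("A", "B", "A:B", "Residuals")
  out <- data.frame(
    term = keep,
    ss = a3[keep, "Sum Sq"],
    df = a3[keep, "Df"],
    F = a3[keep, "F value"],
    p = a3[keep, "Pr(>F)"],
    row.names = NULL
  )
  # all-equal responses: car reports NaN F on zero MSE; report F = 0
  if (a3["Residuals", "Sum Sq"] == 0 && all(out$ss[1:3] == 0)) {
    out$F[1:3] <- 0
    out$p[1:3] <- NA_real_
  }
  attr(out, "ss_type") <- "III"
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m = length(pValues)`, order preserved.
#'
#' @param pValues numeric vector of p-values in (0, 1\].
#' @return adjusted p-values.
#' @examples
#' bonferroniAdjust(c(0.01, 0.02, 0.04))
#' @export
bonferroniAdjust <- function(pValues) {
  if (!is.numeric(pValues) || anyNA(pValues) ||
      any(pValues <= 0) || any(pValues > 1))
    stopUsage("p-values must lie in (0, 1]")
  p.adjust(pValues, method = "bonferroni")
}
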