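#' @include AllClasses.R
NULL

actMatrix <- function(nsd, sd) {
  m <- rbind(NSD = nsd, SD = sd)
  colnames(m) <- CELL_CLASSES
  m
}

#' Create a simulation configuration
#'
#' Constructor for [SimConfig-class] with defaults that emulate a
#' repeated-sleep-deprivation CA1 tagging cohort: sleep deprivation
#' activates roughly 20% of excitatory pyramidal neurons against a ~3%
#' undisturbed baseline, activation is almost exclusively excitatory
#' (~95% of activated neurons), tagging efficiency is imperfect with a
#' small background-labeling rate, and a reactivation bias beta = 2
#' doubles the odds that an epoch-1-active cell is active again in
#' epoch 2.  Under these defaults the overlap-of-tagged fraction lands
#' near 30% in SD-SD arms and 5-10% in NSD-NSD arms.
#'
#' @param cellsPerRegion cells (DAPI+ nuclei) per animal per region.
#' @param fracNeuron,fracInhib,fracAstro cell-type composition: fraction
#'   of cells that are neurons, of neurons that are inhibitory, of
#'   non-neurons that are astrocytes.
#' @param act1,act2 epoch-1 / epoch-2 activation probability matrices
#'   (rows `NSD`,`SD`; columns `excitatory`,`inhibitory`,`astro`,`other`).
#' @param tagEff,bgTag HA-tagging probability for epoch-1 active /
#'   inactive cells.
#' @param reactBias odds multiplier beta (> 0) for epoch-2 activation of
#'   epoch-1-active cells; beta = 1 is the random-activation null.
#' @param cfosSens,cfosFpr c-Fos scoring sensitivity / false-positive rate.
#' @param animalsPerArm animals per condition pair.
#' @param sectionsPerAnimal imaged sections per animal (2 or 3).
#' @param sectionArea quantified area per section, mm^2.
#' @param regions region labels to simulate.
#' @param seed master seed; per-animal streams derive from it.
#' @return a validated `SimConfig`.
#' @examples
#' cfg <- simConfig(cellsPerRegion = 500, animalsPerArm = 3, seed = 11)
#' cfg
#' @export
simConfig <- function(cellsPerRegion = 2000,
                      fracNeuron = 0.65,
                      fracInhib = 0.10,
                      fracAstro = 0.50,
                      act1 = actMatrix(nsd = c(0.03, 0.01, 0.004, 0.002),
                                       sd  = c(0.20, 0.02, 0.010, 0.005)),
                      act2 = act1,
                      tagEff = 0.80,
                      bgTag = 0.01,
                      reactBias = 2,
                      cfosSens = 1.0,
                      cfosFpr = 0.005,
                      animalsPerArm = 5,
                      sectionsPerAnimal = 3,
                      sectionArea = 0.25,
                      regions = "CA1",
                      seed = 1L) {
  force(act2)
  obj <- try(new(
    "SimConfig",
    cellsPerRegion = as.integer(cellsPerRegion),
    fracNeuron = fracNeuron, fracInhib = fracInhib, fracAstro = fracAstro,
    act1 = act1, act2 = act2,
    tagEff = tagEff, bgTag = bgTag, reactBias = reactBias,
    cfosSens = cfosSens, cfosFpr = cfosFpr,
    animalsPerArm = as.integer(animalsPerArm),
    sectionsPerAnimal = as.integer(sectionsPerAnimal),
    sectionArea = sectionArea,
    regions = as.character(regions),
    seed = as.integer(seed)
  ), silent = TRUE)
  if (inherits(obj, "try-error"))
    stopUsage("invalid simulation configuration: ",
              attr(obj, "condition")$message)
  obj
}

# Uniform-activation variant used for calibration: identical activation
# probability for every cell class, so the random-activation null is
# exactly true at beta = 1 (cell class no longer confounds the overlap).
uniformActConfig <- function(actNSD = 0.03, actSD = 0.08, ...) {
  simConfig(act1 = actMatrix(nsd = rep(actNSD, 4), sd = rep(actSD, 4)),
            act2 = actMatrix(nsd = rep(actNSD, 4), sd = rep(actSD, 4)),
            ...)
}

#' Simulate one animal's cell table
#'
#' Draws a cell class for every nucleus, epoch-1 activation and HA
#' tagging, epoch-2 activation with the reactivation bias applied to
#' epoch-1-active cells through the logistic link
#' \eqn{p_2' = \sigma(\mathrm{logit}(p_2) + \log\beta)}, and c-Fos
#' scoring with the configured sensitivity and false-positive rate.
#' Cells are assigned uniformly at random to sections.  The RNG stream
#' is derived deterministically from `(seed, animal_id)`, so animals are
#' reproducible independently of simulation order.
#'
#' @param config a [SimConfig-class].
#' @param pair condition pair label, e.g. `"SD-SD"` (see
#'   [parseConditionPair()]).
#' @param animalId unique animal identifier (string).
#' @return a [CellTable-class] including the latent ground-truth columns
#'   `latent_active1` / `latent_active2`.
#' @examples
#' cells <- simulateAnimal(simConfig(cellsPerRegion = 200), "SD-SD", "m1")
#' table(ha = cells$ha, cfos = cells$cfos)
#' @export
simulateAnimal <- function(config, pair, animalId) {
  CellTable(simulateAnimalDF(config, pair, animalId))
}

# Internal plain-data.frame path shared by simulateAnimal/simulateCohort:
# avoids repeated S4 construction and validation in tight Monte Carlo
# loops (invariants hold by construction; the public wrappers validate).
simulateAnimalDF <- function(config, pair, animalId) {
  validObject(config)
  ep <- parseConditionPair(pair)
  animalId <- as.character(animalId)
  seed <- hashString(paste(config@seed, animalId, sep = "/"))
  nSec <- config@sectionsPerAnimal
  logBeta <- log(config@reactBias)

  regionTables <- withSeed(seed, lapply(config@regions, function(region) {
    nc <- config@cellsPerRegion
    # cell class: neuron -> excitatory/inhibitory, else astro/other
    uClass <- runif(nc); uSub <- runif(nc)
    neuron <- uClass < config@fracNeuron
    inhib <- neuron & (uSub < config@fracInhib)
    astro <- !neuron & (uSub < config@fracAstro)
    # class index into the activation-matrix columns
    cls <- 4L - 3L * (neuron & !inhib) - 2L * inhib - 1L * astro
    p1 <- config@act1[ep[["epoch1"]], ][cls]
    active1 <- runif(nc) < p1
    ha <- runif(nc) < (config@bgTag + active1 * (config@tagEff - config@bgTag))
    p2 <- config@act2[ep[["epoch2"]], ][cls]
    p2bias <- plogis(qlogis(p2) + logBeta)
    active2 <- runif(nc) < (p2 + active1 * (p2bias - p2))
    cfos <- runif(nc) <
      (config@cfosFpr + active2 * (config@cfosSens - config@cfosFpr))
    section <- sample.int(nSec, nc, replace = TRUE)
    data.frame(
      cell_id = sprintf("%s_%s_c%05d", animalId, region, seq_len(nc)),
      animal_id = animalId,
      epoch1 = ep[["epoch1"]], epoch2 = ep[["epoch2"]],
      region = region,
      section_id = paste0(animalId, "_s", section),
      section_area = config@sectionArea,
      dapi = TRUE,
      neun = neuron,
      sox9 = astro,
      gad67 = inhib,
      ha = ha,
      cfos = cfos,
      latent_active1 = active1,
      latent_active2 = active2,
      stringsAsFactors = FALSE
    )
  }))
  do.call(rbind, regionTables)
}

#' Simulate a multi-arm cohort
#'
#' Generates `animalsPerArm` animals for each requested condition pair,
#' with unique animal identifiers of the form `<pair>_<i>`.  Each animal
#' uses its own RNG stream derived from `(seed, animal_id)`, so the
#' cohort is reproducible and animals are mutually independent.
#'
#' @param config a [SimConfig-class].
#' @param pairs character vector of condition-pair labels.
#' @return a [CellTable-class] concatenating all animals.
#' @examples
#' cohort <- simulateCohort(simConfig(cellsPerRegion = 100,
#'                                    animalsPerArm = 2),
#'                          c("SD-SD", "NSD-NSD"))
#' unique(cohort$animal_id)
#' @export
simulateCohort <- function(config, pairs) {
  if (length(pairs) < 1L) stopUsage("at least one condition pair required")
  tables <- lapply(pairs, function(pair) {
    parseConditionPair(pair)  # validate early
    do.call(rbind, lapply(seq_len(config@animalsPerArm), function(i) {
      simulateAnimalDF(config, pair, sprintf("%s_%d", pair, i))
    }))
  })
  CellTable(do.call(rbind, tables))
}

#' Plug-in estimator of the reactivation odds multiplier
#'
#' Estimates \eqn{\beta} from overlap counts as the odds ratio
#' \eqn{\hat\beta = \mathrm{odds}(O/K) / \mathrm{odds}((n-O)/(N-K))}:
#' the odds a tagged cell is c-Fos+ relative to the odds an untagged
#' cell is.  Consistent for the generative `reactBias` when activation
#' rates are class-uniform and detection is noise-free.
#'
#' @param counts an [OverlapCounts-class] or data.frame with columns
#'   `N`, `K`, `n`, `O`.
#' @return numeric vector of estimates, one per row.
#' @export
estimateBias <- function(counts) {
  df <- as.data.frame(counts)
  if (!all(c("N", "K", "n", "O") %in% colnames(df)))
    stopUsage("counts must have columns N, K, n, O")
  oddsTagged <- df$O / (df$K - df$O)
  oddsUntagged <- (df$n - df$O) / (df$N - df$K - (df$n - df$O))
  oddsTagged / oddsUntagged
}

#' Monte Carlo power of the cohort reactivation test
#'
#' Simulates `nReps` single-arm SD-SD cohorts from `config`, runs each
#' through the full pipeline (overlap tabulation, per-animal reactivation
#' index, cohort one-sample t-test of mean RI against 1) and reports the
#' rejection fraction at level `alpha` with its binomial standard error.
#' With `reactBias = 1` and class-uniform activation this measures the
#' test's type-I error; with `reactBias > 1` its power.
#'
#' @param config a [SimConfig-class]; `animalsPerArm` must be >= 2.
#' @param nReps number of simulated cohorts.
#' @param alpha significance level in (0, 1).
#' @param region region to analyse (default: first configured region).
#' @return list with elements `power`, `mc_se`, `n_reps`, `alpha`.
#' @examples
#' \donttest{
#' estimatePower(simConfig(cellsPerRegion = 500, animalsPerArm = 4),
#'               nReps = 50)
#' }
#' @export
estimatePower <- function(config, nReps, alpha = 0.05,
                          region = config@regions[1L]) {
  validObject(config)
  if (!is.numeric(nReps) || length(nReps) != 1L || nReps < 1)
    stopUsage("nReps must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopUsage("alpha must lie strictly between 0 and 1")
  if (config@animalsPerArm < 2L)
    stopUsage("animalsPerArm must be >= 2 (the cohort t-test needs ",
              "at least two animals)")
  nReps <- as.integer(nReps)
  reject <- vapply(seq_len(nReps), function(rep) {
    repConfig <- config
    repConfig@seed <- hashString(paste(config@seed, "rep", rep, sep = "/"))
    cohort <- simulateCohort(repConfig, "SD-SD")
    counts <- tabulateOverlap(cohort, region)
    ri <- reactivationIndex(counts)
    res <- cohortRITest(ri$RI)
    res$p < alpha
  }, logical(1L))
  power <- mean(reject)
  list(power = power,
       mc_se = sqrt(power * (1 - power) / nReps),
       n_reps = nReps, alpha = alpha)
}
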