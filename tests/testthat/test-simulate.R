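test_that("configuration invariants are enforced", {
  expect_s4_class(simConfig(), "SimConfig")
  expect_error(simConfig(tagEff = 1.2), class = "retag_usage_error")
  expect_error(simConfig(reactBias = 0), class = "retag_usage_error")
  expect_error(simConfig(reactBias = -1), class = "retag_usage_error")
  expect_error(simConfig(cellsPerRegion = 0), class = "retag_usage_error")
  expect_error(simConfig(sectionsPerAnimal = 4), class = "retag_usage_error")
  expect_error(simConfig(cellsPerRegion = 2, sectionsPerAnimal = 3),
               class = "retag_usage_error")
})

test_that("no activation and no background yields no tagged cells", {
  act0 <- rbind(NSD = rep(0, 4), SD = rep(0, 4))
  colnames(act0) <- c("excitatory", "inhibitory", "astro", "other")
  cfg <- simConfig(cellsPerRegion = 500, act1 = act0, bgTag = 0)
  cells <- simulateAnimal(cfg, "SD-SD", "m1")
  expect_false(any(cells$ha))
  expect_false(any(cells$latent_active1))
})

test_that("simulation is deterministic given seed and animal id", {
  cfg <- simConfig(cellsPerRegion = 400, seed = 42)
  a <- simulateAnimal(cfg, "SD-NSD", "m7")
  b <- simulateAnimal(cfg, "SD-NSD", "m7")
  expect_identical(as.data.frame(a), as.data.frame(b))
  # different animal id or different seed gives a different table
  c1 <- simulateAnimal(cfg, "SD-NSD", "m8")
  expect_false(identical(as.data.frame(a)[-1:-2], as.data.frame(c1)[-1:-2]))
  cfg2 <- simConfig(cellsPerRegion = 400, seed = 43)
  d <- simulateAnimal(cfg2, "SD-NSD", "m7")
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("simulated tables satisfy the cell-table invariants", {
  cells <- simulateCohort(simConfig(cellsPerRegion = 300, animalsPerArm = 2,
                                    seed = 5),
                          c("SD-SD", "NSD-SD"))
  df <- as.data.frame(cells)
  expect_true(all(df$dapi))
  expect_false(any(df$neun & df$sox9))
  expect_true(all(df$neun[df$gad67]))
  expect_true(all(df$section_area > 0))
})

test_that("cohorts have one block of animals per requested pair", {
  cfg <- simConfig(cellsPerRegion = 50, animalsPerArm = 5, seed = 2)
  cells <- simulateCohort(cfg, c("SD-SD", "NSD-NSD"))
  ids <- unique(cells$animal_id)
  expect_length(ids, 10L)
  expect_error(simulateCohort(cfg, character(0)), class = "retag_usage_error")
  expect_error(simulateCohort(cfg, "SD-XX"), class = "retag_usage_error")
})

test_that("condition pairs parse to their two epochs", {
  expect_identical(parseConditionPair("SD-NSD"),
                   c(epoch1 = "SD", epoch2 = "NSD"))
  expect_length(conditionPairs(), 4L)
  expect_error(parseConditionPair("SD"), class = "retag_usage_error")
})

test_that("SD arms are tagged more heavily than NSD arms", {
  cfg <- simConfig(cellsPerRegion = 1000, animalsPerArm = 20, seed = 9)
  cells <- simulateCohort(cfg, c("SD-SD", "NSD-NSD"))
  df <- as.data.frame(cells)
  haByAnimal <- tapply(df$ha, df$animal_id, sum)
  arm <- substr(names(haByAnimal), 1, 6)
  expect_gt(mean(haByAnimal[arm == "SD-SD_"]),
            mean(haByAnimal[arm == "NSD-NS"]))
})

test_that("without detection noise observed markers equal latent activity", {
  cells <- simulateAnimal(noiselessConfig(cellsPerRegion = 5000, seed = 3),
                          "SD-SD", "m1")
  expect_identical(cells$ha, cells$latent_active1)
  expect_identical(cells$cfos, cells$latent_active2)
})

test_that("per-class activation frequencies converge to the configured rates", {
  cfg <- simConfig(cellsPerRegion = 1e5, seed = 21,
                   tagEff = 1, bgTag = 0, cfosSens = 1, cfosFpr = 0,
                   reactBias = 1)
  cells <- as.data.frame(simulateAnimal(cfg, "SD-SD", "m1"))
  cls <- ifelse(cells$gad67, "inhibitory",
         ifelse(cells$neun, "excitatory",
         ifelse(cells$sox9, "astro", "other")))
  for (k in c("excitatory", "inhibitory", "astro", "other")) {
    idx <- cls == k
    p <- cfg@act1["SD", k]
    se <- sqrt(p * (1 - p) / sum(idx))
    expect_lt(abs(mean(cells$latent_active1[idx]) - p), 4 * se + 1e-12)
    expect_lt(abs(mean(cells$latent_active2[idx]) - p), 4 * se + 1e-12)
  }
})

test_that("c-Fos is conditionally independent of the tag when beta = 1", {
  cfg <- noiselessConfig(cellsPerRegion = 1e5, reactBias = 1, seed = 31,
                         actSD = 0.1)
  cells <- as.data.frame(simulateAnimal(cfg, "SD-SD", "m1"))
  pTag <- mean(cells$cfos[cells$ha])
  pUntag <- mean(cells$cfos[!cells$ha])
  se <- sqrt(pTag * (1 - pTag) / sum(cells$ha) +
               pUntag * (1 - pUntag) / sum(!cells$ha))
  expect_lt(abs(pTag - pUntag), 3 * se)
})

test_that("cohort mean RI is non-decreasing in the reactivation bias", {
  meanRI <- vapply(c(0.5, 1, 2, 4), function(beta) {
    cfg <- uniformConfig(cellsPerRegion = 5000, animalsPerArm = 5,
                         reactBias = beta, seed = 11, actSD = 0.1)
    cells <- simulateCohort(cfg, "SD-SD")
    ri <- reactivationIndex(tabulateOverlap(cells, "CA1"))
    mean(ri$RI)
  }, numeric(1L))
  expect_false(is.unsorted(meanRI))
  expect_lt(meanRI[1L], 1)
  expect_gt(meanRI[4L], 2)
})

test_that("the plug-in odds-ratio estimator recovers the bias", {
  for (beta in c(2, 4)) {
    cfg <- noiselessConfig(cellsPerRegion = 1e5, reactBias = beta,
                           seed = 57, actSD = 0.1)
    counts <- tabulateOverlap(simulateAnimal(cfg, "SD-SD", "m1"), "CA1")
    betaHat <- estimateBias(counts)
    expect_lt(abs(betaHat - beta) / beta, 0.15)
  }
})

test_that("power estimation validates its inputs", {
  cfg <- simConfig(cellsPerRegion = 100, animalsPerArm = 1)
  expect_error(estimatePower(cfg, 10), class = "retag_usage_error")
  cfg2 <- simConfig(cellsPerRegion = 100, animalsPerArm = 3)
  expect_error(estimatePower(cfg2, 0), class = "retag_usage_error")
  expect_error(estimatePower(cfg2, 10, alpha = 1.2),
               class = "retag_usage_error")
})

test_that("a strong bias with ample animals is detected with high power", {
  cfg <- uniformConfig(cellsPerRegion = 5000, animalsPerArm = 8,
                       reactBias = 5, seed = 13, actSD = 0.1)
  pw <- estimatePower(cfg, nReps = 60)
  expect_gt(pw$power, 0.9)
  expect_true(pw$mc_se >= 0 && pw$mc_se < 0.07)
})
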