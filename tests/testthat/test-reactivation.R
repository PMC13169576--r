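test_that("overlap tabulation counts the four cell populations", {
  df <- data.frame(
    cell_id = c("c1", "c2", "c3", "c4"),
    animal_id = "m1", epoch1 = "SD", epoch2 = "SD", region = "CA1",
    section_id = "s1", section_area = 0.5,
    dapi = TRUE, neun = TRUE, sox9 = FALSE, gad67 = FALSE,
    ha = c(TRUE, TRUE, FALSE, FALSE),
    cfos = c(TRUE, FALSE, TRUE, FALSE)
  )
  counts <- as.data.frame(tabulateOverlap(df, "CA1"))
  expect_equal(counts[c("N", "K", "n", "O")],
               data.frame(N = 4L, K = 2L, n = 2L, O = 1L))
  df$ha <- FALSE; df$cfos <- FALSE
  empty <- as.data.frame(tabulateOverlap(df, "CA1"))
  expect_equal(empty[c("N", "K", "n", "O")],
               data.frame(N = 4L, K = 0L, n = 0L, O = 0L))
  expect_error(tabulateOverlap(df, "DGsup"), class = "retag_usage_error")
})

test_that("tabulated overlap equals latent double-activation when noise-free", {
  cfg <- noiselessConfig(cellsPerRegion = 3000, reactBias = 3, seed = 37,
                         actSD = 0.1)
  cells <- simulateAnimal(cfg, "SD-SD", "m1")
  df <- as.data.frame(cells)
  counts <- as.data.frame(tabulateOverlap(cells, "CA1"))
  expect_equal(counts$O, sum(df$latent_active1 & df$latent_active2))
  expect_equal(counts$K, sum(df$latent_active1))
  expect_equal(counts$n, sum(df$latent_active2))
})

test_that("expected overlap is n*K/N with its boundary cases", {
  expect_equal(expectedOverlap(data.frame(N = 1000, K = 100, n = 200)), 20)
  expect_equal(expectedOverlap(data.frame(N = 1000, K = 0, n = 200)), 0)
  expect_equal(expectedOverlap(data.frame(N = 1000, K = 1000, n = 200)), 200)
  expect_error(expectedOverlap(data.frame(N = 0, K = 0, n = 0)),
               class = "retag_domain_error")
})

test_that("overlap count invariants are enforced at construction", {
  expect_error(OverlapCounts(data.frame(animal_id = "m", region = "CA1",
                                        N = 10, K = 12, n = 2, O = 1)),
               class = "retag_data_error")
  expect_error(OverlapCounts(data.frame(animal_id = "m", region = "CA1",
                                        N = 10, K = 4, n = 2, O = 3)),
               class = "retag_data_error")
  # O below the lower bound K + n - N
  expect_error(OverlapCounts(data.frame(animal_id = "m", region = "CA1",
                                        N = 10, K = 8, n = 7, O = 2)),
               class = "retag_data_error")
})

test_that("reactivation index is O/E with the documented percentages", {
  ri <- as.data.frame(reactivationIndex(
    data.frame(animal_id = "m1", region = "CA1",
               N = 1000, K = 100, n = 200, O = 44)))
  expect_equal(ri$E, 20)
  expect_equal(ri$RI, 2.2)
  expect_equal(ri$pct_of_tagged, 44)
  expect_equal(ri$pct_of_cfos, 22)
  # an observation exactly at its expectation gives RI = 1
  ri1 <- reactivationIndex(data.frame(animal_id = "m1", region = "CA1",
                                      N = 100, K = 10, n = 10, O = 1))
  expect_equal(ri1$RI, 1)
})

test_that("undefined RI (K = 0 or n = 0) is flagged, not fabricated", {
  expect_message(
    ri <- reactivationIndex(data.frame(animal_id = c("m1", "m2"),
                                       region = "CA1",
                                       N = c(100, 100), K = c(0, 10),
                                       n = c(5, 10), O = c(0, 2))),
    "m1")
  df <- as.data.frame(ri)
  expect_true(is.na(df$RI[1L]))
  expect_true(is.finite(df$RI[2L]))
})

test_that("RI * E reproduces O for every simulated animal", {
  cells <- simulateCohort(simConfig(cellsPerRegion = 800, animalsPerArm = 4,
                                    seed = 41),
                          c("SD-SD", "NSD-SD", "SD-NSD", "NSD-NSD"))
  ri <- as.data.frame(reactivationIndex(tabulateOverlap(cells, "CA1")))
  ok <- is.finite(ri$RI)
  expect_true(any(ok))
  expect_equal(ri$RI[ok] * ri$E[ok], as.numeric(ri$O[ok]))
})

test_that("hypergeometric tail matches exact enumeration", {
  expect_equal(hypergeomTest(data.frame(animal_id = "m", region = "CA1",
                                        N = 10, K = 3, n = 4, O = 3)),
               7 / 210)
  # p = 1 at the lower bound of the support
  expect_equal(hypergeomTest(data.frame(animal_id = "m", region = "CA1",
                                        N = 10, K = 8, n = 7, O = 5)), 1)
  expect_error(hypergeomTest(data.frame(N = 10, K = 3, n = 4)),
               class = "retag_usage_error")
})

test_that("hypergeometric p is monotone non-increasing in O", {
  p <- hypergeomTest(data.frame(animal_id = "m", region = "CA1",
                                N = 200, K = 30, n = 40, O = 0:30))
  expect_false(is.unsorted(rev(p)))
  expect_true(all(p > 0 & p <= 1))
})

test_that("hypergeometric p agrees with a label-permutation oracle", {
  p <- hypergeomTest(data.frame(animal_id = "m", region = "CA1",
                                N = 200, K = 30, n = 40, O = 12))
  draws <- 2e4
  pPerm <- permHyperUpper(200, 30, 40, 12, draws = draws, seed = 99)
  mcSE <- sqrt(pPerm * (1 - pPerm) / draws)
  expect_lt(abs(p - pPerm), 3 * mcSE)
})

test_that("cohort RI test matches the hand-computed one-sample t", {
  res <- cohortRITest(c(1.5, 2.0, 2.5))
  expect_equal(res$mean, 2.0)
  expect_equal(res$sem, 0.5 / sqrt(3), tolerance = 1e-12)
  expect_equal(res$t, 1 / (0.5 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p, 2 * pt(-res$t, 2), tolerance = 1e-12)
})

test_that("degenerate cohorts are rejected rather than mis-tested", {
  expect_error(cohortRITest(c(2)), class = "retag_usage_error")
  expect_error(cohortRITest(c(1, 1, 1)), class = "retag_data_error")
  expect_message(expect_error(cohortRITest(c(2, NA, NaN)),
                              class = "retag_usage_error"))
})

test_that("the log-scale variant tests log(RI) against zero", {
  x <- c(1.5, 2.0, 2.5)
  res <- cohortRITest(x, logScale = TRUE)
  ht <- oneSampleT(log(x), mu = 0)
  expect_equal(res$t, unname(ht$statistic))
  expect_equal(res$p, ht$p.value)
  expect_error(cohortRITest(c(-1, 2, 3), logScale = TRUE),
               class = "retag_data_error")
})

test_that("SD-SD overlap-of-tagged exceeds NSD-NSD at defaults", {
  cells <- simulateCohort(simConfig(seed = 61), c("SD-SD", "NSD-NSD"))
  ri <- as.data.frame(reactivationIndex(tabulateOverlap(cells, "CA1")))
  arm <- paste(ri$epoch1, ri$epoch2, sep = "-")
  expect_gt(mean(ri$pct_of_tagged[arm == "SD-SD"]),
            mean(ri$pct_of_tagged[arm == "NSD-NSD"]))
})
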