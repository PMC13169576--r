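# Independent oracles and shared fixtures for the suite.

# Class-uniform activation config: every cell class has the same
# activation probability, so HA and c-Fos are exactly independent at
# reactBias = 1 (no cell-class confounding of the overlap).
uniformConfig <- function(actNSD = 0.03, actSD = 0.08, ...) {
  act <- rbind(NSD = rep(actNSD, 4), SD = rep(actSD, 4))
  colnames(act) <- c("excitatory", "inhibitory", "astro", "other")
  simConfig(act1 = act, act2 = act, ...)
}

# Noise-free variant: tagging and c-Fos scoring are perfect, so the
# observed markers equal the latent activity indicators row by row.
noiselessConfig <- function(...) {
  uniformConfig(tagEff = 1, bgTag = 0, cfosSens = 1, cfosFpr = 0, ...)
}

# Exact upper-tail hypergeometric probability by direct enumeration of
# the support: P(X >= O) = sum_x C(K,x) C(N-K, n-x) / C(N, n).
enumHyperUpper <- function(N, K, n, O) {
  support <- max(0, K + n - N):min(K, n)
  num <- sum(choose(K, support[support >= O]) *
               choose(N - K, n - support[support >= O]))
  num / choose(N, n)
}

# Permutation oracle: shuffle which n of the N cells are c-Fos+ and
# count how often the overlap with the K tagged cells reaches O.
permHyperUpper <- function(N, K, n, O, draws, seed) {
  set.seed(seed)
  tagged <- seq_len(K)
  hits <- vapply(seq_len(draws), function(i) {
    sum(sample.int(N, n) <= K) >= O
  }, logical(1L))
  mean(hits)
}

# Textbook sequential two-way ANOVA on balanced data: sums of squares
# from cell/marginal means.
balancedAnovaOracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  g <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - g)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - g)^2))
  cellMeans <- tapply(y, list(A, B), mean)
  cellN <- table(A, B)
  ssCells <- sum(cellN * (cellMeans - g)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((y - cellMeans[cbind(A, B)])^2)
  list(ssA = ssA, ssB = ssB, ssAB = ssAB, ssE = ssE,
       ssTotal = sum((y - g)^2))
}

# Minimal hand-built cell table for quantification unit tests.
toyCellTable <- function() {
  data.frame(
    cell_id = sprintf("c%02d", 1:8),
    animal_id = "m1",
    epoch1 = "SD", epoch2 = "SD",
    region = "CA1",
    section_id = rep(c("s1", "s2"), each = 4),
    section_area = 0.5,
    dapi = TRUE,
    neun = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    sox9 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    gad67 = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    ha = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    cfos = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}
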