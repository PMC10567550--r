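# Reduced study design for fast unit tests: same architecture as the
# default 684-cell design, ~170 cells and 400 genes.
smallDesign <- function(seed = 1L, reversalStrength = 0.25, ...) {
  groups <- expand.grid(lineage = c("pos", "neg"),
                        timepoint = c(0, 6, 9, 11),
                        batch = c("b1", "b2"),
                        stringsAsFactors = FALSE)
  groups$n <- ifelse(groups$lineage == "pos", 14L, 8L)
  synthConfig(groups = groups, nGenes = 400L, seed = seed,
              reversalStrength = reversalStrength, ...)
}

# generator -> filtered, normalized, batch-corrected SCE
normSCE <- function(cfg) {
  sce <- synthCounts(synthCells(cfg), cfg)
  batchCorrect(normalizeCounts(filterCells(sce)))
}

# Exhaustive hypergeometric tail oracle: P(overlap >= k) when a module of
# size n is drawn uniformly from a background of size N containing K
# regulon targets. Enumerates all C(N, n) module draws.
hyperOracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # targets are items 1..K w.l.o.g.
  mean(hits >= k)
}

# Brute-force gliding-box lacunarity for one box size.
lacOracle <- function(mask, r) {
  masses <- c()
  for (i in seq_len(nrow(mask) - r + 1)) {
    for (j in seq_len(ncol(mask) - r + 1)) {
      masses <- c(masses, sum(mask[i:(i + r - 1), j:(j + r - 1)]))
    }
  }
  mu <- mean(masses)
  mean((masses - mu)^2) / mu^2 + 1
}

# Three planted trend archetypes over a pseudotime grid, with noise.
archetypeTrends <- function(nPerClass = 20L, noiseSd = 0.2, seed = 5L) {
  set.seed(seed)
  grid <- seq(0, 1, length.out = 100)
  arch <- rbind(grid, 1 - grid, 4 * grid * (1 - grid))
  tr <- arch[rep(1:3, each = nPerClass), ] +
    matrix(rnorm(3 * nPerClass * 100, 0, noiseSd), 3 * nPerClass)
  rownames(tr) <- sprintf("g%03d", seq_len(nrow(tr)))
  list(trends = methods::new("GeneTrendSet", trends = tr, grid = grid,
                             span = 0.3),
       truth = rep(1:3, each = nPerClass))
}
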