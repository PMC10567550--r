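test_that("cell filter applies the detected-gene boundary strictly", {
  set.seed(1)
  m <- matrix(rpois(300 * 4, 2), 300, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  m[, 1] <- 0; m[1:199, 1] <- 1   # exactly 199 detected genes
  m[, 2] <- 0; m[1:200, 2] <- 1   # exactly 200
  kept <- filterCells(m, minGenes = 200L)
  expect_false("c1" %in% colnames(kept))
  expect_true(all(c("c2", "c3", "c4") %in% colnames(kept)))
  expect_identical(filterCells(kept, minGenes = 1L), kept)
  expect_error(filterCells(matrix(numeric(), 0, 0)), "empty")
  expect_error(filterCells(m, minGenes = 1e6), "all cells removed")
})

test_that("size-factor normalization matches its definition", {
  set.seed(2)
  m <- matrix(rpois(100 * 9, 5), 100, 9,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:9)))
  norm <- normalizeCounts(m)
  sf <- attr(norm, "sizeFactors")
  expect_equal(sf, colSums(m) / median(colSums(m)))
  expect_equal(unname(norm[3, 5]), unname(log1p(m[3, 5] / sf[5])))
  # cell at the median total has size factor 1
  expect_true(any(abs(sf - 1) < 1e-12))

  # identical cells: size factors all 1, values = log1p(counts)
  same <- m[, rep(1, 6)]
  expect_equal(unname(normalizeCounts(same)), unname(log1p(same)),
               ignore_attr = TRUE)

  # doubling a non-median cell's counts leaves its normalized profile
  # unchanged (brute recomputation)
  m2 <- m
  big <- which.max(colSums(m))
  m2[, big] <- 2 * m2[, big]
  expect_equal(normalizeCounts(m2)[, big], norm[, big], tolerance = 1e-12)

  zero <- m; zero[, 4] <- 0
  expect_error(normalizeCounts(zero), "zero total")
})

test_that("HVG selection finds planted high-variance programs", {
  cfg <- smallDesign(seed = 11L)
  sce <- normalizeCounts(filterCells(synthCounts(synthCells(cfg), cfg)))
  hvg <- selectHVG(sce, n = 120L)
  programGenes <- rownames(sce)[rowData(sce)$program != "none"]
  expect_gt(mean(hvg %in% programGenes), 0.8)
  expect_identical(hvg, selectHVG(sce, n = 120L))
  expect_length(selectHVG(sce, n = 1e5), nrow(sce))
})

test_that("PCA embedding is scaled, ordered and covariate-aware", {
  set.seed(3)
  # rank-1 planted structure
  u <- rnorm(50); v <- rnorm(40)
  m <- outer(u, v) + matrix(rnorm(50 * 40, 0, 0.01), 50)
  rownames(m) <- paste0("g", 1:50); colnames(m) <- paste0("c", 1:40)
  emb <- pcaEmbed(m, nPcs = 5L)
  ev <- emb@explainedVariance
  expect_true(all(diff(ev) <= 1e-8))
  expect_gt(ev[1] / sum(ev), 0.99)
  expect_equal(crossprod(emb@loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)

  # a gene equal to the regressed covariate contributes nothing
  covar <- rnorm(40)
  m2 <- rbind(m, dup = 3 * covar + 1)
  e1 <- pcaEmbed(m2, nPcs = 5L, regressCovariate = covar)
  e2 <- pcaEmbed(m, nPcs = 5L, regressCovariate = covar)
  expect_equal(abs(cor(e1@coordinates[, 1], e2@coordinates[, 1])), 1,
               tolerance = 1e-6)
  expect_error(pcaEmbed(m, nPcs = 0L), "positive")
})

test_that("graph clustering separates planted blobs and is seeded", {
  set.seed(4)
  blobs <- rbind(matrix(rnorm(60 * 2, 0), ncol = 2),
                 matrix(rnorm(60 * 2, 8), ncol = 2))
  truth <- rep(0:1, each = 60)
  # resolution on the igraph modularity scale; 0.2 resolves macro structure
  cl <- clusterCells(blobs, kNeighbors = 10L, resolution = 0.2, seed = 1L)
  expect_equal(length(unique(cl$labels)), 2L)
  expect_equal(adjustedRand(cl$labels, truth), 1)
  expect_identical(cl$labels,
                   clusterCells(blobs, kNeighbors = 10L, resolution = 0.2,
                                seed = 1L)$labels)
  expect_equal(min(cl$labels), 0L)
  # labels ordered by decreasing size
  expect_true(sum(cl$labels == 0) >= sum(cl$labels == 1))
  expect_equal(unique(clusterCells(blobs, kNeighbors = 10L,
                                   resolution = 0, seed = 1L)$labels), 0L)
  expect_error(clusterCells(blobs[1:2, ], kNeighbors = 1L), "at least 3")
  expect_error(clusterCells(blobs, kNeighbors = 1000L), "< number of cells")
})

test_that("signature scores separate planted program cells", {
  cfg <- smallDesign(seed = 12L)
  sce <- normalizeCounts(filterCells(synthCounts(synthCells(cfg), cfg)))
  upGenes <- rownames(sce)[rowData(sce)$program == "uHF"]  # high at z ~ 1
  sc <- signatureScore(sce, upGenes, seed = 1L)
  hi <- colData(sce)$z > 0.7
  lo <- colData(sce)$z < 0.3
  expect_lt(wilcox.test(sc[hi], sc[lo])$p.value, 0.05)
  expect_gt(median(sc[hi]), median(sc[lo]))
  expect_identical(sc, signatureScore(sce, upGenes, seed = 1L))
  expect_error(signatureScore(sce, character()), "empty")
  expect_error(signatureScore(sce, "not_a_gene"), "absent")

  # null scores (random gene set, no matching structure) centre near 0
  set.seed(9)
  nullSet <- sample(rownames(sce)[rowData(sce)$program == "none"], 20)
  sc0 <- signatureScore(sce, nullSet, seed = 2L)
  expect_lt(abs(mean(sc0)), 3 * sd(sc0) / sqrt(length(sc0)) + 0.05)
})

test_that("cluster-compartment correlation identifies the source program", {
  cfg <- smallDesign(seed = 13L)
  sce <- normalizeCounts(filterCells(synthCounts(synthCells(cfg), cfg)))
  clusters <- ifelse(colData(sce)$z > 0.5, 0L, 1L)
  sets <- list(uHF = rownames(sce)[rowData(sce)$program == "uHF"],
               IFE = rownames(sce)[rowData(sce)$program == "IFE"])
  cc <- compartmentCorrelation(sce, clusters, sets)
  expect_true(all(cc >= -1 & cc <= 1, na.rm = TRUE))
  # cluster 0 (differentiated) correlates best with the up-program uHF
  expect_equal(colnames(cc)[which.max(cc["cluster0", ])], "uHF")
  expect_equal(colnames(cc)[which.max(cc["cluster1", ])], "IFE")
  cc2 <- compartmentCorrelation(sce, clusters, list(a = sets$uHF, b = sets$uHF))
  expect_equal(unname(cc2[, 1]), unname(cc2[, 2]))
  ccS <- compartmentCorrelation(sce, clusters, sets, mode = "score", seed = 1L)
  expect_true(all(ccS >= -1 & ccS <= 1))
})

test_that("rank-sum test matches the exact distribution and enumeration", {
  res <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1)
  expect_equal(res$statistic, 0)
  # property: equals wilcox.test's exact p for tie-free samples, sizes <= 8
  set.seed(5)
  for (i in 1:40) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    x <- sample(seq_len(60), m); y <- sample(setdiff(seq_len(60), x), n)
    expect_equal(rankSumTest(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # ties: identical samples are maximally compatible with the null
  expect_equal(rankSumTest(c(2, 2, 2), c(2, 2, 2))$p.value, 1)
})

test_that("Wilcoxon DE applies detection and fold-change gates", {
  m <- matrix(0, 3, 20, dimnames = list(c("gA", "gB", "gC"),
                                        paste0("c", 1:20)))
  m["gA", ] <- c(1, 2, 3, rep(0, 7), 4, 5, 6, rep(0, 7))  # exact-p example
  m["gB", ] <- rep(c(1, 1), each = 10)                     # identical groups
  m["gC", c(1, 11)] <- 5                                    # 10% detection
  de <- wilcoxonDE(m, 1:10, 11:20, minPct = 0.25, logfcThreshold = 0)
  expect_false("gC" %in% de$gene)  # detected in 10% of both groups
  deA <- wilcoxonDE(m[, c(1:3, 11:13), drop = FALSE], 1:3, 4:6,
                    minPct = 0, logfcThreshold = 0)
  expect_equal(unname(deA[deA$gene == "gA", "p"]), 0.1)  # exact, U = 0

  # identical values in both groups -> lfc 0 -> excluded by threshold
  deB <- wilcoxonDE(m, 1:10, 11:20, minPct = 0, logfcThreshold = 0.25)
  expect_false("gB" %in% deB$gene)

  expect_error(wilcoxonDE(m, 1:10, 5:15), "overlap")
  expect_error(wilcoxonDE(m, 1:2, 3:20), ">= 3 cells")

  # BH adjustment: monotone in p, >= p, <= 1
  set.seed(6)
  mm <- matrix(rnbinom(100 * 30, mu = 4, size = 2), 100,
               dimnames = list(paste0("g", 1:100), paste0("c", 1:30)))
  mm[1:10, 1:15] <- mm[1:10, 1:15] + 12
  de2 <- wilcoxonDE(log1p(mm), 1:15, 16:30, minPct = 0, logfcThreshold = 0)
  expect_true(all(de2$p_adj >= de2$p - 1e-12))
  expect_true(all(de2$p_adj <= 1))
  expect_true(all(diff(de2$p_adj[order(de2$p)]) >= -1e-12))
  expect_equal(de2$p_adj, p.adjust(de2$p, "BH"))
})

test_that("normalization invariance: scaling a cell scales only its size factor", {
  set.seed(7)
  m <- matrix(rpois(80 * 11, 6), 80, 11,
              dimnames = list(paste0("g", 1:80), paste0("c", 1:11)))
  norm1 <- normalizeCounts(m)
  m2 <- m
  big <- which.max(colSums(m))
  m2[, big] <- m2[, big] * 3
  norm2 <- normalizeCounts(m2)
  expect_equal(attr(norm2, "sizeFactors")[big],
               3 * attr(norm1, "sizeFactors")[big])
  expect_equal(norm2[, big], norm1[, big], tolerance = 1e-12)
})
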