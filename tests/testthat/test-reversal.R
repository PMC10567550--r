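# small SCE with hand-set marker expression for gate tests
gateFixture <- function() {
  m <- matrix(3, 4, 6,
              dimnames = list(c("Lrig1", "g1", "g2", "g3"), paste0("c", 1:6)))
  m["Lrig1", ] <- c(0.5, 1.0, 2.0, 0.5, 2.0, 1.0)
  sce <- SingleCellExperiment(
    assays = list(logcounts = m),
    colData = DataFrame(lineage = c("neg", "neg", "neg", "pos", "pos", "pos"),
                        timepoint = c(0, 0, 0, 9, 9, 0),
                        row.names = colnames(m)))
  sce
}

test_that("population gates follow strict threshold and design rules", {
  sce <- gateFixture()
  pops <- selectPopulations(sce, marker = "Lrig1", threshold = 1.0)
  # c1: neg/t0/0.5<1 in; c2 exactly at threshold: excluded from both;
  # c3 neg but Lrig1>1: not differentiating; c5 pos/t9/2>1 in;
  # c4 pos/t9 but Lrig1<1 out; c6 pos but t0 out
  expect_identical(pops@differentiating, "c1")
  expect_identical(pops@dedifferentiating, "c5")
  expect_error(selectPopulations(sce, marker = "Absent"), "not present")
  bad <- sce
  assay(bad, "logcounts")["Lrig1", ] <- 5
  expect_error(selectPopulations(bad), "differentiating population is empty")
})

test_that("planted reversal yields strongly negative R", {
  cfg <- synthConfig(seed = 1L)
  sce <- normSCE(cfg)
  pops <- selectPopulations(sce)
  rv <- reversalStatistic(pops, sce)
  expect_lte(rv@R, -0.6)
  expect_lt(rv@spearman, -0.4)
  expect_gte(rv@nGenes, 50L)
  expect_equal(nrow(geneTable(rv)), rv@nGenes)
  # loess curve is defined over the observed median range
  expect_equal(range(rv@loessFit$x),
               range(geneTable(rv)$median_diff))
})

test_that("R is invariant to gene and cell permutations", {
  cfg <- smallDesign(seed = 2L)
  sce <- normSCE(cfg)
  pops <- selectPopulations(sce)
  r0 <- reversalStatistic(pops, sce, deOptions = list(pAdjThreshold = 1))@R
  set.seed(3)
  shuffled <- sce[sample(nrow(sce)), sample(ncol(sce))]
  r1 <- reversalStatistic(pops, shuffled,
                          deOptions = list(pAdjThreshold = 1))@R
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("self-comparison of identical populations returns R = 1", {
  set.seed(4)
  m <- matrix(rnorm(60 * 12, 2, 1), 60, 12,
              dimnames = list(paste0("g", 1:60), paste0("c", 1:12)))
  m[m < 0] <- 0
  m[, 7:12] <- m[, 1:6]  # dedifferentiating cells duplicate the others
  sce <- SingleCellExperiment(
    assays = list(logcounts = m),
    colData = DataFrame(lineage = rep(c("neg", "pos"), each = 6),
                        timepoint = rep(c(0, 9), each = 6),
                        row.names = colnames(m)))
  pops <- methods::new("ReversalPopulations",
                       differentiating = paste0("c", 1:6),
                       dedifferentiating = paste0("c", 7:12),
                       marker = "Lrig1", threshold = 1)
  rv <- reversalStatistic(pops, sce,
                          deOptions = list(minPct = 0, logfcThreshold = 0,
                                           pAdjThreshold = 1, useHVG = FALSE))
  expect_equal(rv@R, 1)

  # constant medians in one population -> undefined correlation
  m2 <- m
  m2[, 1:6] <- 1
  sce2 <- SingleCellExperiment(assays = list(logcounts = m2),
                               colData = colData(sce))
  expect_error(reversalStatistic(pops, sce2,
                                 deOptions = list(minPct = 0,
                                                  logfcThreshold = 0,
                                                  pAdjThreshold = 1,
                                                  useHVG = FALSE)),
               "constant medians")
})

test_that("R decreases with reversal strength in the responsive regime", {
  rs <- vapply(c(0.1, 0.15, 0.2), function(r) {
    cfg <- synthConfig(seed = 4L, reversalStrength = r)
    sce <- normSCE(cfg)
    reversalStatistic(selectPopulations(sce), sce)@R
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("permutation test is seeded and detects the planted reversal", {
  cfg <- synthConfig(seed = 1L)
  sce <- normSCE(cfg)
  pops <- selectPopulations(sce)
  res <- permutationTest(pops, sce, nPerm = 99L, seed = 7L)
  expect_lte(res@permutationP, 0.05)
  res2 <- permutationTest(pops, sce, nPerm = 19L, seed = 8L)
  res3 <- permutationTest(pops, sce, nPerm = 19L, seed = 8L)
  expect_identical(res2@permutationP, res3@permutationP)
  expect_error(permutationTest(pops, sce, nPerm = 0L), "nPerm")
})

test_that("volcano flags use the strict non-log fold-change rule", {
  de <- S4Vectors::DataFrame(gene = c("a", "b", "c", "d"),
                             lfc = log(c(1.7, 1.5, 1.6, 1 / 1.7)))
  flagged <- volcanoTable(de, fcThreshold = 1.6)
  expect_identical(flagged$flagged, c(TRUE, FALSE, FALSE, TRUE))
  empty <- volcanoTable(de[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("reversal results serialize to JSON/TSV/CSV", {
  cfg <- smallDesign(seed = 6L)
  sce <- normSCE(cfg)
  rv <- reversalStatistic(selectPopulations(sce), sce,
                          deOptions = list(pAdjThreshold = 1))
  prefix <- file.path(withr::local_tempdir(), "rev")
  writeReversalResult(rv, prefix)
  j <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(j$R, rv@R, tolerance = 1e-12)
  expect_equal(j$n_genes, rv@nGenes)
  tab <- read.delim(paste0(prefix, "_genes.tsv"))
  expect_equal(nrow(tab), rv@nGenes)
})
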