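# noisy 1-D manifold in a higher-dimensional space
linearManifold <- function(n = 600L, dims = 5L, noise = 0.3, seed = 1L) {
  set.seed(seed)
  z <- runif(n)
  coords <- cbind(10 * z, matrix(rnorm(n * (dims - 1), 0, noise), n))
  rownames(coords) <- paste0("c", seq_len(n))
  list(coords = coords, z = z)
}

test_that("principal graph on collinear data is a path", {
  lm1 <- linearManifold(200L, dims = 3L, noise = 1e-3, seed = 2L)
  g <- fitPrincipalGraph(lm1$coords, nNodes = 8L, seed = 1L)
  expect_equal(nrow(g@edges), 7L)
  degrees <- table(factor(as.vector(g@edges), levels = 1:8))
  expect_true(all(degrees <= 2))
  g2 <- fitPrincipalGraph(lm1$coords, nNodes = 8L, seed = 1L)
  expect_identical(g@edges, g2@edges)
  expect_error(fitPrincipalGraph(lm1$coords, nNodes = 1L), ">= 2")
})

test_that("pseudotime recovers a planted ordering and scales to [0, 1]", {
  lm1 <- linearManifold(seed = 3L)
  g <- fitPrincipalGraph(lm1$coords, nNodes = 12L, seed = 1L)
  t <- computePseudotime(g, rootScore = -lm1$z)  # root at low z
  expect_equal(min(t), 0)
  expect_equal(max(t), 1)
  expect_gt(cor(t, lm1$z, method = "spearman"), 0.9)
  # cells mapped to the root node sit at the low end
  rootCells <- g@cellNode == g@cellNode[which.min(t)]
  expect_lt(max(t[rootCells]), 0.25)

  # flipping the planted axis and re-rooting reverses the ordering
  flipped <- lm1$coords
  flipped[, 1] <- -flipped[, 1]
  g2 <- fitPrincipalGraph(flipped, nNodes = 12L, seed = 1L)
  t2 <- computePseudotime(g2, rootScore = lm1$z)
  expect_lt(cor(t2, t, method = "spearman"), -0.9)
})

test_that("explicit root node is honoured and errors are raised", {
  lm1 <- linearManifold(100L, seed = 4L)
  g <- fitPrincipalGraph(lm1$coords, nNodes = 6L, seed = 1L)
  t <- computePseudotime(g, rootNode = 3L)
  expect_equal(min(t), 0)
  expect_error(computePseudotime(g), "rootNode or rootScore")
})

test_that("pseudotime kernel is row-stochastic with forward bias", {
  lm1 <- linearManifold(seed = 5L)
  g <- fitPrincipalGraph(lm1$coords, nNodes = 12L, seed = 1L)
  t <- computePseudotime(g, rootScore = -lm1$z)
  tm <- pseudotimeKernel(lm1$coords, t, kNeighbors = 15L)
  P <- transitionProbs(tm)
  expect_lt(max(abs(Matrix::rowSums(P) - 1)), 1e-9)
  expect_true(all(P@x >= 0))
  ms <- transitionMassSplit(tm, t)
  interior <- t > quantile(t, 0.1) & t < quantile(t, 0.9)
  expect_gte(mean(ms$forward[interior] >= ms$backward[interior]), 0.9)
  expect_error(pseudotimeKernel(lm1$coords, t, sigma = -1), "sigma")
})

test_that("a cell whose neighbours all lie forward sees no damping", {
  # points on a line; the first cell's neighbours all have larger t
  coords <- cbind(seq(0, 1, length.out = 30), 0)
  t <- seq(0, 1, length.out = 30)
  tm <- pseudotimeKernel(coords, t, kNeighbors = 5L, sigma = 0.05)
  nn <- epiRewind:::knnIndex(coords, 5L)
  s <- exp(-(nn$dist[1, ] / median(nn$dist))^2)
  expect_equal(as.vector(transitionProbs(tm)[1, nn$index[1, ]]),
               unname(s / sum(s)), tolerance = 1e-12)
})

test_that("gene trends reproduce constants and linear signals", {
  set.seed(6)
  n <- 150L
  t <- sort(runif(n))
  noiseSd <- 0.05
  m <- rbind(const = rep(2.5, n),
             lin = 1 + 2 * t + rnorm(n, 0, noiseSd))
  colnames(m) <- paste0("c", 1:n)
  tr <- geneTrends(m, t, span = 0.5)
  expect_length(tr@grid, 100L)
  expect_true(all(diff(tr@grid) > 0))
  expect_true(all(abs(tr@trends["const", ] - 2.5) < 1e-9))
  # local-linear fit of a line stays within a few SE of the line
  se <- noiseSd / sqrt(0.5 * n)
  expect_lt(max(abs(tr@trends["lin", ] - (1 + 2 * tr@grid))), 5 * se)
  expect_error(geneTrends(m, t, span = 1.5), "span")
  expect_error(geneTrends(m[, 1:5], t[1:5]), "at least 10")
})

test_that("module detection recovers trend archetypes", {
  fx <- archetypeTrends(nPerClass = 20L, noiseSd = 0.2, seed = 7L)
  mods <- detectModules(fx$trends, seed = 1L)
  expect_length(unique(mods), 3L)
  expect_gte(adjustedRand(mods, fx$truth), 0.9)
  expect_identical(mods, detectModules(fx$trends, seed = 1L))
  expect_true(all(names(mods) == rownames(fx$trends@trends)))

  # identical (non-constant) trends collapse to one module
  same <- fx$trends
  same@trends <- same@trends[rep(1L, 10L), ]
  rownames(same@trends) <- paste0("s", 1:10)
  expect_length(unique(detectModules(same, seed = 1L)), 1L)

  flat <- fx$trends
  flat@trends <- matrix(1, 5, 100)
  expect_error(detectModules(flat), "constant")
})

test_that("mclust cross-check agrees with the internal Rand index", {
  a <- c(1, 1, 2, 2, 3, 3, 1, 2)
  b <- c(2, 2, 1, 1, 3, 3, 2, 3)
  expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b))
  expect_equal(adjustedRand(a, a), 1)
})
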