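#' Two-sided Wilcoxon / Mann-Whitney rank-sum test
#'
#' Shared test used by the differential-expression stage and by AFM region
#' comparison. For small samples (both groups of size at most `exactMax`)
#' the null distribution of the rank-sum statistic is enumerated
#' exhaustively over all assignments of the pooled observations to the two
#' groups, which handles ties exactly; the two-sided p-value is twice the
#' smaller tail, capped at 1. Larger samples use the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @param exactMax enumerate exactly when both groups have at most this
#'   many observations (default 10).
#' @return list with elements `statistic` (Mann-Whitney U of `x`),
#'   `p.value`, and `method` ("exact" or "normal").
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
#' @export
rankSumTest <- function(x, y, exactMax = 10L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  if (m <= exactMax && n <= exactMax) {
    idx <- utils::combn(m + n, m)
    Wnull <- colSums(matrix(r[idx], nrow = m))
    pLow <- mean(Wnull <= W + 1e-9)
    pHigh <- mean(Wnull >= W - 1e-9)
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  N <- m + n
  ties <- table(pooled)
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- m * n / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p.value = 1, method = "normal"))
  zc <- U - m * n / 2
  zc <- sign(zc) * max(0, abs(zc) - 0.5)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(zc / sqrt(sigma2))))
  list(statistic = U, p.value = p, method = "normal")
}

# Rank-sum p-values for every row of a matrix, groups given as column
# indices. Normal approximation with tie correction and continuity
# correction; exact enumeration per gene when both groups are small.
rowRankSumP <- function(mat, idxA, idxB, exactMax = 10L) {
  m <- length(idxA); n <- length(idxB)
  sub <- mat[, c(idxA, idxB), drop = FALSE]
  if (m <= exactMax && n <= exactMax) {
    return(apply(sub, 1L, function(v)
      rankSumTest(v[seq_len(m)], v[m + seq_len(n)], exactMax = exactMax)$p.value))
  }
  N <- m + n
  apply(sub, 1L, function(v) {
    r <- rank(v)
    U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    ties <- table(v)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- m * n / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    zc <- U - m * n / 2
    zc <- sign(zc) * max(0, abs(zc) - 0.5)
    min(1, 2 * stats::pnorm(-abs(zc / sqrt(sigma2))))
  })
}

# k-nearest-neighbour index matrix (rows = points, columns = neighbour
# ranks) from a coordinate matrix, Euclidean metric. Also returns the
# corresponding distances. Brute force; fine at the cell counts used here.
knnIndex <- function(coords, k) {
  n <- nrow(coords)
  stopifnot(k < n)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  idx <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  dist <- t(vapply(seq_len(n), function(i) d[i, idx[i, ]], numeric(k)))
  list(index = idx, dist = dist)
}

# Undirected igraph from a KNN index matrix (union of directed edges).
knnGraph <- function(idx) {
  n <- nrow(idx)
  from <- rep(seq_len(n), ncol(idx))
  el <- cbind(from, as.vector(idx))
  el <- t(apply(el, 1L, sort))
  el <- unique(el)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Deterministically derive per-stage seeds (< 2^31) from one global seed.
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Adjusted Rand index between two labelings (used by tests and the
# acceptance script to score planted-structure recovery).
#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxIndex <- (si + sj) / 2
  if (maxIndex == expected) return(1)
  (sij - expected) / (maxIndex - expected)
}

# loess wrapper that muffles the numeric chatter emitted for heavily tied
# predictors (degenerate local neighbourhoods); the fit itself is fine for
# the smoothing purposes it serves here.
quietLoess <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    msg <- conditionMessage(w)
    if (grepl(paste("pseudoinverse|neighborhood radius|reciprocal condition",
                    "number|near singularities|span too small",
                    sep = "|"), msg))
      invokeRestart("muffleWarning")
  })
}

# Internal: fetch the log-normalized matrix from an SCE or pass a matrix
# through unchanged.
.logMat <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    if (!"logcounts" %in% assayNames(x))
      stop("object has no 'logcounts' assay; run normalizeCounts() first")
    as.matrix(assay(x, "logcounts"))
  } else {
    as.matrix(x)
  }
}

.countMat <- function(x) {
  if (is(x, "SummarizedExperiment")) as.matrix(assay(x, "counts")) else as.matrix(x)
}
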