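#' Remove low-complexity cells
#'
#' Cells with fewer than `minGenes` detected genes (count > 0) are
#' removed; a cell with exactly `minGenes` detected genes is retained.
#'
#' @param sce SingleCellExperiment with assay `counts` (or a count matrix).
#' @param minGenes detected-gene threshold (default 200).
#' @return the filtered object, same class as the input.
#' @export
filterCells <- function(sce, minGenes = 200L) {
  counts <- .countMat(sce)
  if (ncol(counts) == 0L || nrow(counts) == 0L) stop("empty count matrix")
  detected <- colSums(counts > 0)
  keep <- detected >= minGenes
  if (!any(keep)) stop("all cells removed by the detected-gene filter")
  if (is(sce, "SummarizedExperiment")) sce[, keep] else counts[, keep, drop = FALSE]
}

#' Size-factor normalization and log transform
#'
#' Per-cell size factor = total counts / median of totals; normalized
#' expression = `log(1 + count / sizeFactor)` (natural log). Scaling a
#' cell's counts by c > 0 scales its size factor by c and leaves the
#' normalized values unchanged (when the median total is unaffected).
#'
#' @param sce SingleCellExperiment with assay `counts`.
#' @return the object with a `logcounts` assay and `sizeFactors()` set.
#' @export
normalizeCounts <- function(sce) {
  counts <- .countMat(sce)
  totals <- colSums(counts)
  if (any(totals == 0)) stop("cell(s) with zero total counts: ",
                             paste(colnames(counts)[totals == 0], collapse = ", "))
  sf <- totals / stats::median(totals)
  norm <- log1p(sweep(counts, 2L, sf, "/"))
  if (is(sce, "SummarizedExperiment")) {
    assay(sce, "logcounts") <- norm
    SingleCellExperiment::sizeFactors(sce) <- sf
    sce
  } else {
    attr(norm, "sizeFactors") <- sf
    norm
  }
}

#' Select highly variable genes by binned standardized dispersion
#'
#' Genes are binned (20 quantile bins) by mean log-normalized expression;
#' within each bin the dispersion (variance / mean) is z-scored, and the
#' top `n` genes by standardized dispersion are returned. Deterministic on
#' fixed input; ties break by gene order.
#'
#' @param x SingleCellExperiment with `logcounts`, or a matrix.
#' @param n number of genes to keep (default 5000; capped at the gene count).
#' @param nBins number of mean bins (default 20).
#' @return character vector of gene names (or integer indices if unnamed).
#' @export
selectHVG <- function(x, n = 5000L, nBins = 20L) {
  stopifnot(n >= 1L)
  m <- .logMat(x)
  if (n >= nrow(m)) {
    return(if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m))
  }
  mu <- rowMeans(m)
  v <- apply(m, 1L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  zd <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    zd[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-zd)
  top <- sort(ord[seq_len(n)])
  if (is.null(rownames(m))) top else rownames(m)[top]
}

#' Empirical-Bayes (ComBat-style) batch correction
#'
#' Parametric location/scale adjustment: each gene is standardized against
#' its batch-design fit, additive and multiplicative batch effects are
#' estimated, shrunk towards batch-level priors (normal prior on the
#' location, inverse-gamma on the scale, solved by the standard fixed-point
#' iteration), removed, and the gene's grand mean and pooled scale are
#' restored. As a final contract the per-gene grand mean is re-centred so
#' it is preserved exactly. A single batch is returned unchanged.
#'
#' @param x SingleCellExperiment with `logcounts`, or a matrix
#'   (genes x cells).
#' @param batch batch label per cell; defaults to `colData(x)$batch`.
#' @return object of the same class with corrected `logcounts`.
#' @export
batchCorrect <- function(x, batch = NULL) {
  m <- .logMat(x)
  if (is.null(batch)) {
    if (!is(x, "SummarizedExperiment") || is.null(colData(x)$batch))
      stop("batch labels required")
    batch <- colData(x)$batch
  }
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(m))
  levs <- unique(batch)
  if (length(levs) == 1L) return(x)
  nPer <- table(batch)
  if (any(nPer < 2L))
    stop("each batch needs >= 2 cells; offending: ",
         paste(names(nPer)[nPer < 2], collapse = ", "))
  corrected <- combatAdjust(m, batch)
  # standardization contract: per-gene grand mean preserved exactly
  corrected <- corrected - rowMeans(corrected) + rowMeans(m)
  if (is(x, "SummarizedExperiment")) {
    assay(x, "logcounts") <- corrected
    x
  } else {
    corrected
  }
}

# Core parametric ComBat algorithm (no covariates beyond batch).
combatAdjust <- function(m, batch) {
  levs <- unique(batch)
  nB <- length(levs)
  n <- ncol(m)
  nPer <- vapply(levs, function(b) sum(batch == b), numeric(1))
  w <- nPer / n
  batchMeans <- vapply(levs, function(b) rowMeans(m[, batch == b, drop = FALSE]),
                       numeric(nrow(m)))
  grand <- as.vector(batchMeans %*% w)
  # pooled within-batch residual variance
  resid <- m - batchMeans[, match(batch, levs), drop = FALSE]
  sig2 <- rowMeans(resid^2)
  sig <- sqrt(pmax(sig2, .Machine$double.eps))
  Z <- (m - grand) / sig
  gammaHat <- vapply(levs, function(b) rowMeans(Z[, batch == b, drop = FALSE]),
                     numeric(nrow(m)))
  delta2Hat <- vapply(levs, function(b) {
    zb <- Z[, batch == b, drop = FALSE]
    rowSums((zb - rowMeans(zb))^2) / (sum(batch == b) - 1)
  }, numeric(nrow(m)))
  out <- Z
  for (j in seq_len(nB)) {
    gh <- gammaHat[, j]; d2 <- delta2Hat[, j]; ni <- nPer[j]
    gBar <- mean(gh); t2 <- stats::var(gh)
    # inverse-gamma prior moments for the scale effects
    V <- stats::var(d2); Dm <- mean(d2)
    aPrior <- if (V > 0) (2 * V + Dm^2) / V else 100
    bPrior <- if (V > 0) (Dm * V + Dm^3) / V else Dm
    cells <- which(batch == levs[j])
    gStar <- gh; dStar <- d2
    # standard EB fixed-point iteration
    for (it in 1:200) {
      gNew <- (ni * t2 * gh + dStar * gBar) / (ni * t2 + dStar)
      sse <- rowSums((Z[, cells, drop = FALSE] - gNew)^2)
      dNew <- (0.5 * sse + bPrior) / (ni / 2 + aPrior - 1)
      if (max(abs(gNew - gStar), abs(dNew - dStar)) < 1e-8 * (1 + max(abs(dStar)))) {
        gStar <- gNew; dStar <- dNew; break
      }
      gStar <- gNew; dStar <- dNew
    }
    out[, cells] <- (Z[, cells, drop = FALSE] - gStar) / sqrt(pmax(dStar, .Machine$double.eps))
  }
  out * sig + grand
}

#' PCA embedding with optional covariate regression
#'
#' Restricts to the supplied gene set, optionally residualizes each gene on
#' a per-cell covariate (least squares with intercept; e.g. mitochondrial
#' content), centres and unit-scales genes, and runs PCA.
#'
#' @param x SingleCellExperiment with `logcounts`, or a matrix.
#' @param hvg gene names/indices to embed (default: all genes).
#' @param nPcs number of components (default 15).
#' @param regressCovariate optional per-cell numeric covariate.
#' @return a [PCAEmbedding-class].
#' @export
pcaEmbed <- function(x, hvg = NULL, nPcs = 15L, regressCovariate = NULL) {
  if (nPcs <= 0L) stop("nPcs must be positive")
  m <- .logMat(x)
  if (!is.null(hvg)) m <- m[hvg, , drop = FALSE]
  if (nPcs > min(dim(m))) stop("nPcs exceeds matrix rank bound")
  if (!is.null(regressCovariate)) {
    stopifnot(length(regressCovariate) == ncol(m))
    X <- cbind(1, regressCovariate)
    beta <- solve(crossprod(X), crossprod(X, t(m)))
    m <- m - t(X %*% beta)
  }
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  keep <- s > 0
  scaled <- (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
  pc <- stats::prcomp(t(scaled), center = FALSE, scale. = FALSE, rank. = nPcs)
  coords <- pc$x
  rownames(coords) <- colnames(m)
  methods::new("PCAEmbedding", coordinates = coords, loadings = pc$rotation,
               explainedVariance = pc$sdev[seq_len(nPcs)]^2,
               hvg = if (is.null(hvg)) rownames(.logMat(x))
                     else as.character(hvg))
}

#' Graph-based clustering of an embedding
#'
#' Builds a KNN graph (Euclidean in PC space) and partitions it with
#' Louvain modularity optimization at the given resolution. Labels are
#' integers from 0, relabelled by decreasing cluster size.
#'
#' @param embedding [PCAEmbedding-class] or a coordinate matrix.
#' @param kNeighbors neighbourhood size (default 20).
#' @param resolution modularity resolution (default 0.5).
#' @param seed integer seed for the community search.
#' @return list(labels = integer vector from 0, resolution, kNeighbors).
#' @export
clusterCells <- function(embedding, kNeighbors = 20L, resolution = 0.5,
                         seed = 1L) {
  coords <- if (is(embedding, "PCAEmbedding")) embedding@coordinates else as.matrix(embedding)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 cells to cluster")
  if (kNeighbors >= n) stop("kNeighbors must be < number of cells")
  g <- knnGraph(knnIndex(coords, kNeighbors)$index)
  set.seed(as.integer(seed))
  if (resolution <= 0) {
    labels <- rep(0L, n)
  } else {
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    raw <- igraph::membership(comm)
    sizes <- sort(table(raw), decreasing = TRUE)
    relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
    labels <- unname(relabel[as.character(raw)])
  }
  names(labels) <- rownames(coords)
  list(labels = as.integer(labels), resolution = resolution,
       kNeighbors = as.integer(kNeighbors))
}

#' Per-cell signature score with expression-matched controls
#'
#' Module-score scheme: all genes are binned (25 bins) by mean expression;
#' for each signature gene, `controlPerGene` control genes are sampled from
#' its bin; score = mean signature expression minus mean control
#' expression per cell.
#'
#' @param x SingleCellExperiment with `logcounts`, or a matrix.
#' @param geneSet character vector of signature genes (must be present).
#' @param controlPerGene control genes sampled per signature gene
#'   (default 100, capped at bin size).
#' @param seed integer seed for control sampling.
#' @param nBins number of expression bins (default 25).
#' @return numeric score per cell.
#' @export
signatureScore <- function(x, geneSet, controlPerGene = 100L, seed = 1L,
                           nBins = 25L) {
  m <- .logMat(x)
  if (length(geneSet) == 0L) stop("gene set is empty")
  missing <- setdiff(geneSet, rownames(m))
  if (length(missing))
    stop("gene set members absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  mu <- rowMeans(m)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  names(bin) <- rownames(m)
  set.seed(as.integer(seed))
  controls <- character()
  for (gene in geneSet) {
    pool <- setdiff(rownames(m)[bin == bin[gene]], geneSet)
    if (!length(pool)) pool <- setdiff(rownames(m), geneSet)
    controls <- c(controls, sample(pool, min(controlPerGene, length(pool))))
  }
  controls <- unique(controls)
  colMeans(m[geneSet, , drop = FALSE]) - colMeans(m[controls, , drop = FALSE])
}

#' Cluster-by-compartment correlation matrix
#'
#' In mode "indicator" each entry is the Pearson correlation, over genes,
#' between the cluster centroid expression profile and the 0/1 membership
#' indicator of the signature set. In mode "score" it is the correlation,
#' over cells, between the per-cell signature score and cluster
#' membership. Zero-variance centroids give NA entries and are flagged in
#' `attr(, "degenerate")`.
#'
#' @param x SingleCellExperiment with `logcounts`, or a matrix.
#' @param clusters integer labels per cell (e.g. from [clusterCells()]).
#' @param signatureSets named list of gene sets.
#' @param mode "indicator" (default) or "score".
#' @param ... passed to [signatureScore()] in mode "score".
#' @return matrix clusters x compartments with values in [-1, 1] (or NA).
#' @export
compartmentCorrelation <- function(x, clusters, signatureSets,
                                   mode = c("indicator", "score"), ...) {
  mode <- match.arg(mode)
  m <- .logMat(x)
  if (is.list(clusters)) clusters <- clusters$labels
  stopifnot(length(clusters) == ncol(m), length(signatureSets) >= 1L)
  cl <- sort(unique(clusters))
  out <- matrix(NA_real_, length(cl), length(signatureSets),
                dimnames = list(paste0("cluster", cl), names(signatureSets)))
  degenerate <- character()
  if (mode == "indicator") {
    for (i in seq_along(cl)) {
      centroid <- rowMeans(m[, clusters == cl[i], drop = FALSE])
      if (stats::sd(centroid) == 0) {
        degenerate <- c(degenerate, rownames(out)[i])
        next
      }
      for (j in seq_along(signatureSets)) {
        ind <- as.numeric(rownames(m) %in% signatureSets[[j]])
        out[i, j] <- stats::cor(centroid, ind)
      }
    }
  } else {
    for (j in seq_along(signatureSets)) {
      sc <- signatureScore(x, signatureSets[[j]], ...)
      for (i in seq_along(cl)) {
        memb <- as.numeric(clusters == cl[i])
        out[i, j] <- stats::cor(sc, memb)
      }
    }
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Wilcoxon rank-sum differential expression
#'
#' Seurat-style DE between two cell groups: genes detected in fewer than
#' `minPct` of cells in both groups, or with absolute log fold change below
#' `logfcThreshold`, are excluded before testing; remaining genes get a
#' two-sided rank-sum p (exact enumeration when both groups have at most 10
#' cells, tie-corrected normal approximation otherwise) and
#' Benjamini-Hochberg adjustment over the tested genes. The log fold change
#' is the natural log of the ratio of mean (de-logged) normalized
#' expression with pseudocount 1.
#'
#' @param x SingleCellExperiment with `logcounts`, or a matrix.
#' @param cellsA,cellsB disjoint cell id (or index) vectors, each >= 3.
#' @param minPct detection-fraction cutoff (default 0.25).
#' @param logfcThreshold absolute log-fold-change cutoff (default 0.25).
#' @return DataFrame(gene, lfc, pct1, pct2, p, p_adj) ordered by p.
#' @export
wilcoxonDE <- function(x, cellsA, cellsB, minPct = 0.25,
                       logfcThreshold = 0.25) {
  m <- .logMat(x)
  if (is.character(cellsA)) cellsA <- match(cellsA, colnames(m))
  if (is.character(cellsB)) cellsB <- match(cellsB, colnames(m))
  if (anyNA(cellsA) || anyNA(cellsB)) stop("unknown cell ids")
  if (length(intersect(cellsA, cellsB))) stop("groups must not overlap")
  if (length(cellsA) < 3L || length(cellsB) < 3L)
    stop("both groups need >= 3 cells")
  A <- m[, cellsA, drop = FALSE]
  B <- m[, cellsB, drop = FALSE]
  pct1 <- rowMeans(A > 0)
  pct2 <- rowMeans(B > 0)
  lfc <- log((rowMeans(expm1(A)) + 1) / (rowMeans(expm1(B)) + 1))
  tested <- (pmax(pct1, pct2) >= minPct) & (abs(lfc) >= logfcThreshold)
  genes <- rownames(m)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(m)))
  if (!any(tested)) {
    return(DataFrame(gene = character(), lfc = numeric(), pct1 = numeric(),
                     pct2 = numeric(), p = numeric(), p_adj = numeric()))
  }
  p <- rowRankSumP(m[tested, , drop = FALSE], cellsA, cellsB)
  out <- DataFrame(gene = genes[tested], lfc = lfc[tested],
                   pct1 = pct1[tested], pct2 = pct2[tested],
                   p = p, p_adj = stats::p.adjust(p, method = "BH"))
  out[order(out$p), ]
}

#' Write a differential-expression table as TSV
#'
#' Fixed column order: gene, lfc, pct1, pct2, p, p_adj.
#'
#' @param de table from [wilcoxonDE()].
#' @param path output file.
#' @export
writeDETable <- function(de, path) {
  utils::write.table(as.data.frame(de)[, c("gene", "lfc", "pct1", "pct2",
                                           "p", "p_adj")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
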