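#' Gate differentiating and dedifferentiating populations
#'
#' Differentiating cells: lineage-negative, timepoint 0, marker expression
#' strictly below the threshold. Dedifferentiating cells: lineage-positive,
#' timepoint > 0, marker expression strictly above it. A cell exactly at
#' the threshold belongs to neither population. Thresholds are in
#' log-normalized units.
#'
#' @param sce SingleCellExperiment with `logcounts` and colData columns
#'   `lineage` ("pos"/"neg") and `timepoint`.
#' @param marker gate marker (default "Lrig1").
#' @param threshold gate threshold (default 1.0).
#' @return a [ReversalPopulations-class].
#' @export
selectPopulations <- function(sce, marker = "Lrig1", threshold = 1.0) {
  if (!marker %in% rownames(sce))
    stop("marker '", marker, "' not present in the gene list")
  expr <- .logMat(sce)[marker, ]
  cd <- colData(sce)
  diffCells <- colnames(sce)[cd$lineage == "neg" & cd$timepoint == 0 &
                               expr < threshold]
  dediffCells <- colnames(sce)[cd$lineage == "pos" & cd$timepoint > 0 &
                                 expr > threshold]
  if (!length(diffCells)) stop("differentiating population is empty")
  if (!length(dediffCells)) stop("dedifferentiating population is empty")
  methods::new("ReversalPopulations", differentiating = diffCells,
               dedifferentiating = dediffCells, marker = marker,
               threshold = threshold)
}

#' Trajectory-reversal correlation statistic
#'
#' The central comparison of forward differentiation against wound-induced
#' dedifferentiation: (1) restrict to highly variable genes across the two
#' populations; (2) Wilcoxon DE between the populations with BH
#' adjustment; (3) per retained gene, median log-normalized expression in
#' each population; (4) loess fit (span `loessSpan`) of dedifferentiating
#' medians on differentiating medians; (5) R = Pearson correlation of the
#' raw median pairs (Spearman reported alongside). A strongly negative R
#' indicates that the dedifferentiation transcriptome retraces the forward
#' trajectory in reverse.
#'
#' @param populations a [ReversalPopulations-class].
#' @param sce SingleCellExperiment with `logcounts`.
#' @param deOptions list overriding any of: minPct (0.25), logfcThreshold
#'   (0.25), pAdjThreshold (0.05), useHVG (TRUE), nHVG (NULL = top quarter
#'   of the genes by dispersion, the proportion the study's 5,000-HVG
#'   restriction corresponds to).
#' @param loessSpan span of the fitted curve (default 0.75).
#' @return a [ReversalResult-class].
#' @export
reversalStatistic <- function(populations, sce, deOptions = list(),
                              loessSpan = 0.75) {
  opts <- utils::modifyList(list(minPct = 0.25, logfcThreshold = 0.25,
                                 pAdjThreshold = 0.05, useHVG = TRUE,
                                 nHVG = NULL), deOptions)
  dCells <- populations@differentiating
  wCells <- populations@dedifferentiating
  if (length(dCells) < 3L || length(wCells) < 3L)
    stop("both populations need >= 3 cells")
  m <- .logMat(sce)[, c(dCells, wCells), drop = FALSE]
  if (opts$useHVG) {
    nHVG <- if (is.null(opts$nHVG)) ceiling(nrow(m) / 4) else opts$nHVG
    hvg <- selectHVG(m, n = nHVG)
    m <- m[hvg, , drop = FALSE]
  }
  de <- wilcoxonDE(m, dCells, wCells, minPct = opts$minPct,
                   logfcThreshold = opts$logfcThreshold)
  # pAdjThreshold >= 1 disables significance filtering (all tested genes)
  if (opts$pAdjThreshold < 1)
    de <- de[de$p_adj < opts$pAdjThreshold, , drop = FALSE]
  if (nrow(de) < 3L)
    stop("fewer than 3 genes retained for the reversal statistic")
  med1 <- apply(m[de$gene, dCells, drop = FALSE], 1L, stats::median)
  med2 <- apply(m[de$gene, wCells, drop = FALSE], 1L, stats::median)
  if (stats::sd(med1) == 0 || stats::sd(med2) == 0)
    stop("constant medians in one population; correlation undefined")
  R <- stats::cor(med1, med2)
  rho <- stats::cor(med1, med2, method = "spearman")
  lo <- quietLoess(stats::loess(med2 ~ med1, span = loessSpan, degree = 1))
  ord <- order(med1)
  loessFit <- data.frame(x = med1[ord], y = med2[ord],
                         fitted = stats::fitted(lo)[ord])
  tab <- de
  tab$median_diff <- med1
  tab$median_dediff <- med2
  methods::new("ReversalResult", geneTable = tab, loessFit = loessFit,
               R = R, spearman = rho, permutationP = NA_real_,
               nGenes = nrow(tab), options = opts)
}

#' Permutation null for the reversal statistic
#'
#' Population labels are permuted over the pooled cells `nPerm` times, the
#' full statistic (HVG restriction, DE, medians, correlation) is recomputed
#' each time, and the empirical p-value is
#' `(1 + #{|R_perm| >= |R_obs|}) / (nPerm + 1)`. Permutations whose DE step
#' retains too few genes contribute |R_perm| = 0 (conservative).
#'
#' @param populations a [ReversalPopulations-class].
#' @param sce SingleCellExperiment with `logcounts`.
#' @param nPerm number of permutations (default 99).
#' @param seed integer seed.
#' @param deOptions passed to [reversalStatistic()].
#' @return the observed [ReversalResult-class] with `permutationP` filled
#'   in and the permuted R values in `options$permR`.
#' @export
permutationTest <- function(populations, sce, nPerm = 99L, seed = 1L,
                            deOptions = list()) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  obs <- reversalStatistic(populations, sce, deOptions = deOptions)
  pool <- c(populations@differentiating, populations@dedifferentiating)
  n1 <- length(populations@differentiating)
  set.seed(as.integer(seed))
  permR <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    perm <- sample(pool)
    pops <- methods::new("ReversalPopulations",
                         differentiating = perm[seq_len(n1)],
                         dedifferentiating = perm[-seq_len(n1)],
                         marker = populations@marker,
                         threshold = populations@threshold)
    permR[b] <- tryCatch(
      reversalStatistic(pops, sce, deOptions = deOptions)@R,
      error = function(e) 0)
  }
  p <- (1 + sum(abs(permR) >= abs(obs@R))) / (nPerm + 1)
  obs@permutationP <- p
  obs@options$permR <- permR
  obs
}

#' Flag volcano-plot genes by fold change
#'
#' Flags genes whose non-log fold change is strictly greater than
#' `fcThreshold` in either direction (ratio > threshold or
#' < 1/threshold); a gene at exactly the threshold is not flagged.
#'
#' @param de DE table with a natural-log `lfc` column (e.g. from
#'   [wilcoxonDE()]).
#' @param fcThreshold non-log fold-change threshold (default 1.6).
#' @return the table with logical column `flagged` added.
#' @export
volcanoTable <- function(de, fcThreshold = 1.6) {
  fc <- exp(de$lfc)
  de$flagged <- if (length(fc)) fc > fcThreshold | fc < 1 / fcThreshold else logical(0)
  de
}

#' Serialize a ReversalResult
#'
#' Writes the summary as JSON (R, spearman, permutation p, n_genes,
#' options), the gene table as TSV, and the loess scatter as CSV of
#' (x, y, fitted).
#'
#' @param result a [ReversalResult-class].
#' @param prefix path prefix; files `<prefix>.json`, `<prefix>_genes.tsv`,
#'   `<prefix>_loess.csv` are written.
#' @export
writeReversalResult <- function(result, prefix) {
  opts <- result@options
  opts$permR <- NULL
  jsonlite::write_json(list(R = result@R, spearman = result@spearman,
                            permutation_p = result@permutationP,
                            n_genes = result@nGenes, options = opts),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  utils::write.table(as.data.frame(result@geneTable),
                     paste0(prefix, "_genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(result@loessFit, paste0(prefix, "_loess.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
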