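#' Load a TRRUST-dialect regulon file
#'
#' Parses a 4-column tab-separated edge list (TF, target, mode,
#' references; no header). Duplicate (TF, target) pairs are dropped,
#' keeping the first occurrence; the number dropped is recorded.
#'
#' @param path file path.
#' @return a [RegulonDB-class].
#' @export
loadRegulons <- function(path) {
  if (!file.exists(path)) stop("regulon file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("malformed regulon line ", bad[1], ": expected 4 tab-separated ",
         "columns, found ", lengths(parts)[bad[1]])
  df <- data.frame(tf = vapply(parts, `[`, "", 1L),
                   target = vapply(parts, `[`, "", 2L),
                   mode = vapply(parts, `[`, "", 3L),
                   references = vapply(parts, `[`, "", 4L),
                   stringsAsFactors = FALSE)
  key <- paste(df$tf, df$target, sep = "\r")
  dup <- duplicated(key)
  db <- df[!dup, , drop = FALSE]
  methods::new("RegulonDB",
               edges = DataFrame(db),
               index = split(db$target, db$tf),
               nDuplicates = sum(dup))
}

# RegulonDB from an in-memory edge data.frame (synthetic pipelines)
regulonsFromFrame <- function(df) {
  key <- paste(df$tf, df$target, sep = "\r")
  dup <- duplicated(key)
  db <- df[!dup, , drop = FALSE]
  methods::new("RegulonDB", edges = DataFrame(db),
               index = split(db$target, db$tf),
               nDuplicates = sum(dup))
}

#' Hypergeometric TF-regulon enrichment of a gene module
#'
#' For each TF with at least one target in the background, the
#' hypergeometric upper-tail probability of the observed module/regulon
#' overlap is computed, BH-adjusted over TFs, and combined with an
#' effect-size filter. The second filter is a configurable stand-in for a
#' non-canonical score reported alongside q-values in this literature: by
#' default the normalized rank of the (Haldane-corrected) odds ratio,
#' retained when above `effectThreshold`.
#'
#' @param module character vector of module genes (subset of background).
#' @param db a [RegulonDB-class].
#' @param background character vector: the gene universe.
#' @param qThreshold BH q cutoff (default 0.5).
#' @param effectThreshold normalized odds-ratio-rank cutoff (default 0.9).
#' @return DataFrame(tf, overlap, regulon_size, module_size, p, q,
#'   odds_ratio, effect, retained), ordered by p; filters echoed in
#'   `metadata()`.
#' @export
regulonEnrichment <- function(module, db, background, qThreshold = 0.5,
                              effectThreshold = 0.9) {
  if (!length(background)) stop("background gene set is empty")
  extra <- setdiff(module, background)
  if (length(extra))
    stop("module genes missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  N <- length(background)
  n <- length(module)
  rows <- list()
  for (tf in names(db@index)) {
    targets <- intersect(db@index[[tf]], background)
    K <- length(targets)
    if (K == 0L) next
    k <- length(intersect(targets, module))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- ((k + 0.5) * (N - K - n + k + 0.5)) /
      ((K - k + 0.5) * (n - k + 0.5))
    rows[[tf]] <- data.frame(tf = tf, overlap = k, regulon_size = K,
                             module_size = n, p = p, odds_ratio = or,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- DataFrame(tf = character(), overlap = integer(),
                     regulon_size = integer(), module_size = integer(),
                     p = numeric(), q = numeric(), odds_ratio = numeric(),
                     effect = numeric(), retained = logical())
    metadata(out) <- list(qThreshold = qThreshold,
                          effectThreshold = effectThreshold)
    return(out)
  }
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$effect <- rank(tab$odds_ratio, ties.method = "average") / nrow(tab)
  tab$retained <- tab$q < qThreshold & tab$effect > effectThreshold
  tab <- tab[order(tab$p), ]
  out <- DataFrame(tab, row.names = NULL)
  metadata(out) <- list(qThreshold = qThreshold,
                        effectThreshold = effectThreshold)
  out
}

#' TF expression matrix ordered by pseudotime
#'
#' Returns the log-normalized expression of the requested TFs with columns
#' (cells) sorted by ascending pseudotime. Missing TF symbols are skipped
#' and collected in `attr(, "missing")` with a warning.
#'
#' @param x SingleCellExperiment with `logcounts`, or a matrix.
#' @param tfs character vector of TF symbols.
#' @param t pseudotime per cell (all cells must be covered).
#' @return TFs x cells matrix, pseudotime-ordered columns.
#' @export
tfOrderedMatrix <- function(x, tfs, t) {
  m <- .logMat(x)
  stopifnot(length(t) == ncol(m))
  present <- intersect(tfs, rownames(m))
  missing <- setdiff(tfs, rownames(m))
  if (!length(present)) stop("none of the requested TFs are present")
  if (length(missing))
    warning("TF symbols not found and skipped: ",
            paste(missing, collapse = ", "))
  out <- m[present, order(t), drop = FALSE]
  attr(out, "missing") <- missing
  attr(out, "pseudotime") <- sort(t)
  out
}

#' Write a regulon edge list in the TRRUST dialect
#'
#' @param edges data.frame(tf, target, mode, references).
#' @param path output TSV (4 columns, tab-separated, no header).
#' @export
writeRegulons <- function(edges, path) {
  utils::write.table(edges[, c("tf", "target", "mode", "references")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
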