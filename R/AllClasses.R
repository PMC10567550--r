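#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SingleCellExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<- rowData rowData<-
NULL

#' Configuration for the synthetic single-cell generator
#'
#' Holds the study design emulated by [synthCells()] and [synthCounts()]:
#' per-(lineage, timepoint, batch) cell numbers, gene-program architecture,
#' the strength of the wound-induced reversal of the latent differentiation
#' coordinate, and noise parameters of the negative-binomial count model.
#'
#' @slot groups data.frame with columns `lineage` ("pos"/"neg"),
#'   `timepoint` (days), `batch` and `n` (cells per group).
#' @slot nGenes total number of genes simulated.
#' @slot markerPrograms named list; each element has `genes` (1-based gene
#'   indices), `effect` (log-fold units) and `shape` (one of "up", "down",
#'   "transient" in the latent coordinate, or "wound" for
#'   timepoint-keyed induction).
#' @slot reversalStrength rate (per day) at which the latent coordinate of
#'   wounded lineage-positive cells is pulled back towards the stem state.
#' @slot dispersion shared negative-binomial inverse-dispersion (size).
#' @slot librarySize lognormal (meanlog, sdlog) of the per-cell library
#'   scaling factor.
#' @slot batchShiftSd SD of per-gene, per-batch log-scale shifts.
#' @slot seed integer seed owning all randomness of the generator.
#' @export
setClass("SynthConfig", representation(
  groups = "data.frame",
  nGenes = "integer",
  markerPrograms = "list",
  reversalStrength = "numeric",
  dispersion = "numeric",
  librarySize = "numeric",
  batchShiftSd = "numeric",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  g <- object@groups
  if (nrow(g) == 0L) msg <- c(msg, "group table is empty")
  need <- c("lineage", "timepoint", "batch", "n")
  if (!all(need %in% names(g))) {
    msg <- c(msg, paste("group table must have columns:",
                        paste(need, collapse = ", ")))
  } else {
    if (any(g$n < 0)) msg <- c(msg, "group cell counts must be >= 0")
    if (!all(g$lineage %in% c("pos", "neg")))
      msg <- c(msg, "lineage must be 'pos' or 'neg'")
  }
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  idx <- unlist(lapply(object@markerPrograms, `[[`, "genes"))
  if (length(idx) && (any(idx < 1L) || any(idx > object@nGenes)))
    msg <- c(msg, "marker program gene indices out of range")
  for (nm in names(object@markerPrograms)) {
    p <- object@markerPrograms[[nm]]
    if (anyDuplicated(p$genes))
      msg <- c(msg, paste0("program '", nm, "' has duplicated gene indices"))
    if (!p$shape %in% c("up", "down", "transient", "wound"))
      msg <- c(msg, paste0("program '", nm, "' has unknown shape"))
  }
  if (object@reversalStrength < 0) msg <- c(msg, "reversalStrength must be >= 0")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (length(object@librarySize) != 2L || object@librarySize[2] < 0)
    msg <- c(msg, "librarySize must be (meanlog, sdlog) with sdlog >= 0")
  if (object@batchShiftSd < 0) msg <- c(msg, "batchShiftSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Principal-component embedding of a normalized expression matrix
#'
#' @slot coordinates cells x nPcs score matrix.
#' @slot loadings genes x nPcs orthonormal loading matrix.
#' @slot explainedVariance per-component variance, non-increasing.
#' @slot hvg character vector of genes the embedding was computed on.
#' @export
setClass("PCAEmbedding", representation(
  coordinates = "matrix",
  loadings = "matrix",
  explainedVariance = "numeric",
  hvg = "character"
))

setValidity("PCAEmbedding", function(object) {
  ev <- object@explainedVariance
  if (length(ev) && any(diff(ev) > 1e-8))
    return("explainedVariance must be non-increasing")
  if (ncol(object@coordinates) != length(ev))
    return("coordinates/explainedVariance dimension mismatch")
  TRUE
})

#' Principal graph (MST over k-means centroids) in embedding space
#'
#' @slot nodePositions nodes x dims centroid matrix.
#' @slot edges two-column integer matrix of tree edges (1-based nodes).
#' @slot edgeLengths Euclidean edge lengths.
#' @slot cellNode integer node assignment per cell.
#' @slot cellCoordinates the embedding coordinates the graph was fitted on.
#' @export
setClass("PrincipalGraph", representation(
  nodePositions = "matrix",
  edges = "matrix",
  edgeLengths = "numeric",
  cellNode = "integer",
  cellCoordinates = "matrix"
))

setValidity("PrincipalGraph", function(object) {
  n <- nrow(object@nodePositions)
  if (nrow(object@edges) != n - 1L)
    return("a tree over n nodes must have n - 1 edges")
  g <- igraph::graph_from_edgelist(object@edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (!igraph::is_connected(g)) return("principal graph must be connected")
  if (any(object@cellNode < 1L) || any(object@cellNode > n))
    return("cell assignments out of node range")
  TRUE
})

#' Row-stochastic directed transition matrix on a KNN graph
#'
#' @slot probs sparse row-stochastic cells x cells matrix.
#' @slot kNeighbors neighbourhood size of the underlying KNN graph.
#' @slot sigma pseudotime softness scale of the directed damping.
#' @export
setClass("TransitionMatrix", representation(
  probs = "Matrix",
  kNeighbors = "integer",
  sigma = "numeric"
))

setValidity("TransitionMatrix", function(object) {
  rs <- Matrix::rowSums(object@probs)
  if (any(abs(rs - 1) > 1e-9)) return("rows must sum to 1 within 1e-9")
  if (any(object@probs@x < 0)) return("entries must be >= 0")
  TRUE
})

#' Smoothed gene trends over a pseudotime grid
#'
#' @slot trends genes x grid matrix of fitted values.
#' @slot grid strictly increasing pseudotime grid.
#' @slot span loess span used for the local-linear fits.
#' @export
setClass("GeneTrendSet", representation(
  trends = "matrix",
  grid = "numeric",
  span = "numeric"
))

setValidity("GeneTrendSet", function(object) {
  if (any(diff(object@grid) <= 0)) return("grid must be strictly increasing")
  if (ncol(object@trends) != length(object@grid))
    return("trends/grid dimension mismatch")
  if (any(!is.finite(object@trends))) return("trends must be finite")
  TRUE
})

#' Gated differentiating / dedifferentiating populations
#'
#' Differentiating cells are lineage-negative, unwounded (timepoint 0)
#' cells whose marker expression lies strictly below the threshold;
#' dedifferentiating cells are lineage-positive wound cells (timepoint > 0)
#' strictly above it. Cells exactly at the threshold belong to neither.
#'
#' @slot differentiating cell ids of the forward-differentiating gate.
#' @slot dedifferentiating cell ids of the dedifferentiating gate.
#' @slot marker marker gene used for gating (default "Lrig1").
#' @slot threshold gate threshold in log-normalized units.
#' @export
setClass("ReversalPopulations", representation(
  differentiating = "character",
  dedifferentiating = "character",
  marker = "character",
  threshold = "numeric"
))

setValidity("ReversalPopulations", function(object) {
  if (length(intersect(object@differentiating, object@dedifferentiating)))
    return("populations must be disjoint")
  TRUE
})

#' Result of the trajectory-reversal correlation statistic
#'
#' @slot geneTable per-gene table: DE statistics and the median
#'   log-normalized expression in each population.
#' @slot loessFit data.frame (x, y, fitted) of the loess curve through the
#'   median-median scatter, ordered by x.
#' @slot R Pearson correlation of the median pairs.
#' @slot spearman Spearman correlation of the median pairs.
#' @slot permutationP empirical permutation p-value (NA until computed).
#' @slot nGenes number of genes entering the statistic.
#' @slot options list of the DE/retention options used.
#' @export
setClass("ReversalResult", representation(
  geneTable = "DataFrame",
  loessFit = "data.frame",
  R = "numeric",
  spearman = "numeric",
  permutationP = "numeric",
  nGenes = "integer",
  options = "list"
))

setValidity("ReversalResult", function(object) {
  if (is.finite(object@R) && (object@R < -1 - 1e-12 || object@R > 1 + 1e-12))
    return("R must lie in [-1, 1]")
  if (object@nGenes != nrow(object@geneTable))
    return("nGenes must equal rows of geneTable")
  TRUE
})

#' TF -> target regulon database (TRRUST dialect)
#'
#' @slot edges DataFrame with columns tf, target, mode, references.
#' @slot index named list mapping each TF to its target set.
#' @slot nDuplicates duplicated (tf, target) rows dropped at load.
#' @export
setClass("RegulonDB", representation(
  edges = "DataFrame",
  index = "list",
  nDuplicates = "integer"
))

setValidity("RegulonDB", function(object) {
  e <- object@edges
  if (anyDuplicated(paste(e$tf, e$target, sep = "\r")))
    return("duplicate (tf, target) pairs after load")
  if (any(!nzchar(e$tf)) || any(!nzchar(e$target)))
    return("gene symbols must be non-empty")
  TRUE
})

#' A single AFM force-distance curve
#'
#' @slot z piezo extension samples (m), strictly monotone on approach.
#' @slot d calibrated cantilever deflection (m).
#' @slot kSpring cantilever spring constant (N/m).
#' @slot sensitivity deflection sensitivity (m/V).
#' @slot RTip indenter sphere radius (m).
#' @slot nu sample Poisson ratio.
#' @slot direction "approach" or "retract".
#' @export
setClass("ForceCurve", representation(
  z = "numeric",
  d = "numeric",
  kSpring = "numeric",
  sensitivity = "numeric",
  RTip = "numeric",
  nu = "numeric",
  direction = "character"
))

setValidity("ForceCurve", function(object) {
  if (length(object@z) != length(object@d))
    return("z and d must have equal length")
  dz <- diff(object@z)
  if (length(dz) && !(all(dz > 0) || all(dz < 0)))
    return("z must be strictly monotone")
  if (object@kSpring <= 0) return("kSpring must be > 0")
  if (object@nu < 0 || object@nu > 0.5) return("nu must lie in [0, 0.5]")
  TRUE
})

#' Spherical-Hertz fit of one force curve
#'
#' @slot E fitted Young's modulus (Pa).
#' @slot z0 contact point (m).
#' @slot window force-fraction fit window (lower, upper).
#' @slot rSquared coefficient of determination on windowed points.
#' @slot nPoints number of points inside the fit window.
#' @slot qcFlags character flags ("no_contact", "negative_slope", ...).
#' @export
setClass("HertzFit", representation(
  E = "numeric",
  z0 = "numeric",
  window = "numeric",
  rSquared = "numeric",
  nPoints = "integer",
  qcFlags = "character"
))

setValidity("HertzFit", function(object) {
  w <- object@window
  if (length(w) != 2L || w[1] <= 0 || w[2] >= 1 || w[1] >= w[2])
    return("window bounds must satisfy 0 < lower < upper < 1")
  if (length(object@qcFlags) == 0L && (!is.finite(object@E) || object@E <= 0))
    return("accepted fits must have E > 0")
  TRUE
})

#' Gridded Young's-modulus map
#'
#' @slot E matrix of moduli (Pa); rejected/masked positions are NA.
#' @slot mask logical matrix of excluded positions (e.g. hair shaft).
#' @slot pixelPitch grid pitch (m), e.g. 40 um / 24 points.
#' @export
setClass("StiffnessMap", representation(
  E = "matrix",
  mask = "matrix",
  pixelPitch = "numeric"
))

setValidity("StiffnessMap", function(object) {
  if (!identical(dim(object@E), dim(object@mask)))
    return("E and mask must have the same shape")
  if (any(!is.na(object@E[object@mask])))
    return("masked entries must carry no E value")
  TRUE
})

#' Pipeline configuration
#'
#' @slot paths named list of input/output paths.
#' @slot params named list of stage parameters (validated defaults).
#' @slot seed global integer seed from which all stage seeds derive.
#' @export
setClass("PipelineConfig", representation(
  paths = "list",
  params = "list",
  seed = "integer"
))
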