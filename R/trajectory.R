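#' Fit a principal graph (MST over k-means centroids)
#'
#' Simplified Monocle-style backbone: seeded k-means centroids in the
#' embedding space joined by the Euclidean minimum spanning tree; each cell
#' is assigned to its nearest centroid.
#'
#' @param embedding [PCAEmbedding-class] or a coordinate matrix; trajectory
#'   fitting is typically done in a low-dimensional space (the pipeline
#'   uses the top 5 PCs).
#' @param nNodes number of graph nodes (default 12).
#' @param seed integer seed for k-means.
#' @return a [PrincipalGraph-class].
#' @export
fitPrincipalGraph <- function(embedding, nNodes = 12L, seed = 1L) {
  coords <- if (is(embedding, "PCAEmbedding")) embedding@coordinates else as.matrix(embedding)
  if (nNodes < 2L) stop("nNodes must be >= 2")
  if (nNodes > nrow(coords)) stop("nNodes must not exceed the cell count")
  set.seed(as.integer(seed))
  km <- stats::kmeans(coords, centers = nNodes, nstart = 10L, iter.max = 100L)
  centers <- km$centers
  d <- as.matrix(stats::dist(centers))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  el <- igraph::as_edgelist(tree, names = FALSE)
  lens <- igraph::E(tree)$weight
  # nearest-centroid assignment (k-means clusters are exactly that)
  assign <- km$cluster
  methods::new("PrincipalGraph",
               nodePositions = centers,
               edges = matrix(as.integer(el), ncol = 2L),
               edgeLengths = lens,
               cellNode = as.integer(assign),
               cellCoordinates = coords)
}

# igraph tree with edge weights from a PrincipalGraph
.pgTree <- function(graph) {
  g <- igraph::graph_from_edgelist(graph@edges, directed = FALSE)
  n <- nrow(graph@nodePositions)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- graph@edgeLengths
  g
}

#' Pseudotime along a principal graph
#'
#' Pseudotime = geodesic distance from the root node to the cell's node
#' plus a local projection of the cell onto the incident tree edges, then
#' min-max scaled to [0, 1]. The root can be an explicit node index or be
#' resolved as the node with the highest mean value of `rootScore` (e.g. a
#' differentiated-state signature score), mirroring rooting at the most
#' differentiated cluster.
#'
#' @param graph a [PrincipalGraph-class].
#' @param rootNode explicit root node index (1-based), or NULL.
#' @param rootScore per-cell numeric score used to resolve the root when
#'   `rootNode` is NULL.
#' @return numeric pseudotime per cell in [0, 1], named by cell.
#' @export
computePseudotime <- function(graph, rootNode = NULL, rootScore = NULL) {
  g <- .pgTree(graph)
  if (!igraph::is_connected(g)) stop("principal graph is disconnected")
  if (is.null(rootNode)) {
    if (is.null(rootScore)) stop("supply rootNode or rootScore")
    stopifnot(length(rootScore) == length(graph@cellNode))
    nodeScore <- tapply(rootScore, graph@cellNode, mean)
    rootNode <- as.integer(names(nodeScore)[which.max(nodeScore)])
  }
  nodeDist <- as.vector(igraph::distances(g, v = rootNode))
  coords <- graph@cellCoordinates
  pos <- graph@nodePositions
  t <- nodeDist[graph@cellNode]
  # within-node projection onto the incident edge pointing away from /
  # towards the root, signed by the neighbour's geodesic offset
  adj <- igraph::as_adj_list(g)
  for (i in seq_len(nrow(coords))) {
    v <- graph@cellNode[i]
    nbs <- as.integer(adj[[v]])
    if (!length(nbs)) next
    disp <- coords[i, ] - pos[v, ]
    best <- 0
    bestProj <- 0
    for (u in nbs) {
      e <- pos[u, ] - pos[v, ]
      len <- sqrt(sum(e^2))
      if (len == 0) next
      proj <- sum(disp * e) / len
      if (proj > bestProj) {
        bestProj <- proj
        best <- sign(nodeDist[u] - nodeDist[v]) * min(proj, len)
      }
    }
    t[i] <- t[i] + best
  }
  rng <- range(t)
  t <- if (rng[2] > rng[1]) (t - rng[1]) / (rng[2] - rng[1]) else t * 0
  names(t) <- rownames(coords)
  t
}

#' Directed pseudotime-kernel transition matrix
#'
#' Builds a KNN graph in embedding space with Gaussian similarities
#' `s_ij = exp(-d_ij^2 / scale^2)` (scale = median KNN distance) and damps
#' edges that run backward in pseudotime:
#' `w_ij = s_ij * exp(-max(0, t_i - t_j) / sigma)`; rows are normalized to
#' sum to 1. The default sigma is the median over cells of the SD of the
#' neighbours' pseudotimes (the local pseudotime spread).
#'
#' @param embedding [PCAEmbedding-class] or coordinate matrix.
#' @param t pseudotime per cell.
#' @param kNeighbors neighbourhood size (default 15).
#' @param sigma pseudotime softness scale; NULL for the default.
#' @return a [TransitionMatrix-class].
#' @export
pseudotimeKernel <- function(embedding, t, kNeighbors = 15L, sigma = NULL) {
  coords <- if (is(embedding, "PCAEmbedding")) embedding@coordinates else as.matrix(embedding)
  n <- nrow(coords)
  stopifnot(length(t) == n)
  nn <- knnIndex(coords, kNeighbors)
  if (is.null(sigma)) {
    # softness from the neighbour pseudotime spread: a fifth of the median
    # absolute pseudotime step across KNN edges, so a typical backward
    # step is damped by ~e^-5 while sub-resolution steps stay soft
    steps <- abs(t[as.vector(t(nn$index))] - rep(t, each = kNeighbors))
    sigma <- stats::median(steps[steps > 0]) / 5
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-3
  }
  if (sigma <= 0) stop("sigma must be > 0")
  scale <- stats::median(nn$dist)
  if (scale <= 0) scale <- 1
  i <- rep(seq_len(n), each = kNeighbors)
  j <- as.vector(t(nn$index))
  s <- exp(-(as.vector(t(nn$dist)) / scale)^2)
  w <- s * exp(-pmax(0, t[i] - t[j]) / sigma)
  P <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  rs <- Matrix::rowSums(P)
  if (any(rs == 0)) stop("isolated cell(s) in the KNN graph")
  P <- Matrix::Diagonal(x = 1 / rs) %*% P
  # renormalize exactly (guards 1e-9 row-sum contract against fp drift)
  P <- Matrix::Diagonal(x = 1 / Matrix::rowSums(P)) %*% P
  dimnames(P) <- list(rownames(coords), rownames(coords))
  methods::new("TransitionMatrix", probs = methods::as(P, "CsparseMatrix"),
               kNeighbors = as.integer(kNeighbors), sigma = sigma)
}

#' Forward versus backward transition mass
#'
#' For each cell, the summed transition probability towards neighbours of
#' higher pseudotime (forward) and lower pseudotime (backward).
#'
#' @param tm a [TransitionMatrix-class].
#' @param t pseudotime per cell.
#' @return data.frame(forward, backward) per cell.
#' @export
transitionMassSplit <- function(tm, t) {
  P <- transitionProbs(tm)
  n <- nrow(P)
  stopifnot(length(t) == n)
  Ps <- Matrix::summary(P)
  fwd <- bwd <- numeric(n)
  higher <- t[Ps$j] > t[Ps$i]
  lower <- t[Ps$j] < t[Ps$i]
  fwdAgg <- tapply(Ps$x[higher], Ps$i[higher], sum)
  bwdAgg <- tapply(Ps$x[lower], Ps$i[lower], sum)
  fwd[as.integer(names(fwdAgg))] <- fwdAgg
  bwd[as.integer(names(bwdAgg))] <- bwdAgg
  data.frame(forward = fwd, backward = bwd)
}

#' Smoothed gene trends along pseudotime
#'
#' Per-gene local linear regression (loess, degree 1, tricube weights) of
#' log-normalized expression on pseudotime, evaluated on a fixed
#' 100-point grid spanning the observed pseudotime range.
#'
#' @param x SingleCellExperiment with `logcounts`, or a matrix.
#' @param t pseudotime per cell.
#' @param genes genes to fit (default: all rows).
#' @param span loess span in (0, 1] (default 0.3).
#' @param gridLength grid resolution (default 100).
#' @return a [GeneTrendSet-class].
#' @export
geneTrends <- function(x, t, genes = NULL, span = 0.3, gridLength = 100L) {
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  m <- .logMat(x)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (ncol(m) < 10L) stop("need at least 10 cells to fit trends")
  stopifnot(length(t) == ncol(m))
  grid <- seq(min(t), max(t), length.out = gridLength)
  fits <- matrix(NA_real_, nrow(m), gridLength,
                 dimnames = list(rownames(m), NULL))
  for (g in seq_len(nrow(m))) {
    y <- m[g, ]
    if (stats::sd(y) == 0) {
      fits[g, ] <- y[1]
      next
    }
    fit <- quietLoess(
      stats::loess(y ~ t, span = span, degree = 1,
                   control = stats::loess.control(surface = "direct")))
    fits[g, ] <- stats::predict(fit, newdata = data.frame(t = grid))
  }
  methods::new("GeneTrendSet", trends = fits, grid = grid, span = span)
}

#' Detect gene modules from trend shapes
#'
#' Each fitted trend is z-scored, a gene-gene KNN graph is built on the
#' standardized trend vectors, and Louvain modularity optimization assigns
#' every gene to exactly one module. Modules are relabelled by decreasing
#' size (1 = largest).
#'
#' @param trends a [GeneTrendSet-class].
#' @param kNeighbors gene-graph neighbourhood size (default 10).
#' @param resolution modularity resolution (default 1).
#' @param seed integer seed.
#' @return named integer vector: module id per gene.
#' @export
detectModules <- function(trends, kNeighbors = 10L, resolution = 1,
                          seed = 1L) {
  tr <- trends@trends
  if (nrow(tr) < 2L) stop("need at least 2 genes")
  s <- apply(tr, 1L, stats::sd)
  if (all(s == 0)) stop("all trends are constant; z-scoring undefined")
  z <- (tr - rowMeans(tr)) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  k <- min(kNeighbors, nrow(z) - 1L)
  g <- knnGraph(knnIndex(z, k)$index)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(unname(relabel[as.character(raw)]))
  names(out) <- rownames(tr)
  out
}
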