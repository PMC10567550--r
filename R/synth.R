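#' Construct a synthetic study design
#'
#' Builds a [SynthConfig-class] describing the lineage-tracing wound
#' time-course the generator emulates: Smart-seq2-scale data (684 cells by
#' default), two batches per timepoint, four timepoints (days 0, 6, 9, 11),
#' lineage-positive and lineage-negative cells, compartment marker programs
#' (uHF / IFE / OB / SG / SD), wound-induced genes, and a latent
#' differentiation coordinate z in [0, 1] (0 = Lrig1-like stem state,
#' 1 = Gata6-like differentiated state) that reverses in wounded
#' lineage-positive cells.
#'
#' @param groups data.frame(lineage, timepoint, batch, n); default is the
#'   684-cell design (57/55 lineage-positive and 30 lineage-negative cells
#'   per timepoint x batch).
#' @param nGenes number of genes (default 2000).
#' @param markerPrograms named list of programs (see [SynthConfig-class]);
#'   `NULL` builds the default compartment architecture.
#' @param reversalStrength per-day rate pulling wounded lineage-positive
#'   cells back towards z = 0, applied to the time since dedifferentiation
#'   onset (~5 days post-wounding; default 0.25).
#' @param dispersion shared NB inverse-dispersion (size; default 2).
#' @param librarySize lognormal (meanlog, sdlog) of per-cell library
#'   scaling (default c(0, 0.3)).
#' @param batchShiftSd SD of per-gene per-batch log shifts (default 0.2).
#' @param seed integer seed (default 1).
#' @return a validated [SynthConfig-class].
#' @examples
#' cfg <- synthConfig()
#' sum(cfg@groups$n)  # 684
#' @export
synthConfig <- function(groups = NULL, nGenes = 2000L, markerPrograms = NULL,
                        reversalStrength = 0.25, dispersion = 2,
                        librarySize = c(0, 0.3), batchShiftSd = 0.2,
                        seed = 1L) {
  if (is.null(groups)) {
    groups <- expand.grid(lineage = c("pos", "neg"),
                          timepoint = c(0, 6, 9, 11),
                          batch = c("b1", "b2"),
                          stringsAsFactors = FALSE)
    groups$n <- ifelse(groups$lineage == "pos",
                       ifelse(groups$timepoint == 0, 57L, 55L), 30L)
  }
  if (nrow(groups) == 0L) stop("group table must not be empty")
  if (is.null(markerPrograms)) {
    markerPrograms <- defaultPrograms(nGenes)
  }
  nMarker <- length(unique(unlist(lapply(markerPrograms, `[[`, "genes"))))
  if (nGenes < nMarker)
    stop("nGenes (", nGenes, ") is smaller than the number of marker genes (",
         nMarker, ")")
  methods::new("SynthConfig", groups = groups, nGenes = as.integer(nGenes),
               markerPrograms = markerPrograms,
               reversalStrength = reversalStrength, dispersion = dispersion,
               librarySize = as.numeric(librarySize),
               batchShiftSd = batchShiftSd, seed = as.integer(seed))
}

# Default gene-program architecture. Gene 1 is "Lrig1" (decreasing in z),
# gene 2 "Gata6" (increasing); five compartment programs of 40 genes with
# the three trend archetypes; 30 wound-response genes whose induction in
# wounded skin grows with loss of differentiation (basal/activation
# markers re-expressed by dedifferentiating cells). Compartment markers
# are near-binary (low baseline, ~20-fold effect), as epidermal
# compartment markers are.
defaultPrograms <- function(nGenes) {
  if (nGenes < 252L)
    stop("nGenes (", nGenes, ") is smaller than the number of genes in ",
         "the default marker programs (252)")
  blk <- function(start, len) seq.int(start, start + len - 1L)
  list(
    Lrig1 = list(genes = 1L, effect = 7.0, shape = "down"),
    Gata6 = list(genes = 2L, effect = 7.0, shape = "up"),
    uHF = list(genes = blk(3L, 40L), effect = 3.0, shape = "up"),
    SD  = list(genes = blk(43L, 40L), effect = 3.0, shape = "up"),
    IFE = list(genes = blk(83L, 40L), effect = 3.0, shape = "down"),
    OB  = list(genes = blk(123L, 40L), effect = 3.0, shape = "down"),
    SG  = list(genes = blk(163L, 25L), effect = 2.5, shape = "transient"),
    wound = list(genes = blk(203L, 30L), effect = 2.5, shape = "wound")
  )
}

# Trend archetypes on the latent coordinate. The wound response scales
# with (1 - z) in wounded skin: activation keratins rise as cells lose
# their differentiated identity, so wounding adds no axis of variation
# orthogonal to the differentiation coordinate.
programShape <- function(shape, z, timepoint) {
  switch(shape,
         up = z,
         down = 1 - z,
         transient = 4 * z * (1 - z),
         wound = as.numeric(timepoint > 0) * (1 - z),
         stop("unknown program shape: ", shape))
}

#' Draw latent cell states
#'
#' Samples one latent state per configured cell. Unwounded
#' lineage-positive cells concentrate near z = 1 (z = 0.8 + 0.2 Beta(2,2));
#' lineage-negative basal cells sit lower (Beta(1.8, 2.2)); wounded
#' lineage-positive cells start from the unwounded distribution and are
#' displaced towards 0 by reversalStrength x timepoint x Beta(4,2), so with
#' reversalStrength = 0 all wounded lineage-positive cells keep z >= 0.8.
#'
#' @param config a [SynthConfig-class].
#' @return data.frame(cell_id, lineage, timepoint, batch, z).
#' @export
synthCells <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  methods::validObject(config)
  seeds <- deriveSeeds(config@seed, 3L)
  set.seed(seeds[1])
  g <- config@groups
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    n <- g$n[i]
    if (n == 0L) next
    if (g$lineage[i] == "neg") {
      # unwounded/wounded interfollicular mix: mostly basal stem-like
      # cells near z = 0 plus a suprabasal differentiating tail
      supra <- stats::runif(n) < 0.35
      z <- ifelse(supra, 0.5 + 0.5 * stats::rbeta(n, 2, 2),
                  stats::rbeta(n, 2, 8))
    } else {
      z <- 0.8 + 0.2 * stats::rbeta(n, 2, 2)
      if (g$timepoint[i] > 0) {
        # dedifferentiation sets in ~5 days post-wounding (day 6 stays
        # close to day 0; days 9 and 11 are strongly reversed)
        disp <- config@reversalStrength * max(0, g$timepoint[i] - 5) *
          stats::rbeta(n, 4, 2)
        z <- pmin(1, pmax(0.02, z - disp))
      }
    }
    rows[[i]] <- data.frame(lineage = g$lineage[i], timepoint = g$timepoint[i],
                            batch = g$batch[i], z = z,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("group table yields no cells")
  out <- cbind(cell_id = sprintf("cell%04d", seq_len(nrow(out))), out)
  # Itga6 sort gate: basal (low z) cells are Itga6-high, suprabasal
  # differentiated cells low/mid, with a small sorting error rate
  flip <- stats::runif(nrow(out)) < 0.04
  gate <- ifelse(out$z < 0.5, "high", "low_mid")
  out$itga6_gate <- ifelse(flip, ifelse(gate == "high", "low_mid", "high"),
                           gate)
  rownames(out) <- out$cell_id
  out
}

#' Simulate counts from latent states
#'
#' Negative-binomial counts with mean
#' `librarySize_c * exp(baseline_g + effect_p * f_p(z_c) + batchShift_gb)`
#' and a shared inverse-dispersion. The planted truth (latent z, library
#' sizes, baselines, batch shifts, program membership) is stored in
#' `metadata(sce)$truth` so recovery can be scored exactly.
#'
#' @param states output of [synthCells()].
#' @param config the [SynthConfig-class] used to draw the states.
#' @return a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#'   with assay `counts`, lineage/timepoint/batch/z in `colData` and
#'   program annotations in `rowData`.
#' @export
synthCounts <- function(states, config) {
  stopifnot(is(config, "SynthConfig"), nrow(states) >= 1L)
  seeds <- deriveSeeds(config@seed, 3L)
  set.seed(seeds[2])
  nG <- config@nGenes
  nC <- nrow(states)
  geneIds <- sprintf("gene%04d", seq_len(nG))
  program <- rep("none", nG)
  shape <- rep(NA_character_, nG)
  effect <- rep(0, nG)
  for (nm in names(config@markerPrograms)) {
    p <- config@markerPrograms[[nm]]
    program[p$genes] <- nm
    shape[p$genes] <- p$shape
    effect[p$genes] <- p$effect
  }
  if ("Lrig1" %in% names(config@markerPrograms))
    geneIds[config@markerPrograms$Lrig1$genes] <- "Lrig1"
  if ("Gata6" %in% names(config@markerPrograms))
    geneIds[config@markerPrograms$Gata6$genes] <- "Gata6"

  baseline <- stats::rnorm(nG, 0.5, 0.5)
  # program genes are markers: uniformly low outside their compartment
  baseline[program != "none"] <- stats::rnorm(sum(program != "none"), -0.5, 0.15)
  # marker baselines calibrated so the log-normalized gate threshold of 1
  # (count ~ e - 1) crosses the latent axis where the populations should
  # split: Lrig1 stays clearly ON over the whole basal/stem range and
  # switches off at z = 0.6, Gata6 mirrors at z = 0.4
  gateCross <- log(expm1(1))
  if ("Lrig1" %in% names(config@markerPrograms))
    baseline[geneIds == "Lrig1"] <-
      gateCross - config@markerPrograms$Lrig1$effect * (1 - 0.6)
  if ("Gata6" %in% names(config@markerPrograms))
    baseline[geneIds == "Gata6"] <-
      gateCross - config@markerPrograms$Gata6$effect * 0.4

  batches <- sort(unique(states$batch))
  batchShift <- matrix(stats::rnorm(nG * length(batches), 0, config@batchShiftSd),
                       nrow = nG, dimnames = list(geneIds, batches))
  libSize <- stats::rlnorm(nC, config@librarySize[1], config@librarySize[2])

  logMu <- matrix(baseline, nrow = nG, ncol = nC)
  for (nm in names(config@markerPrograms)) {
    p <- config@markerPrograms[[nm]]
    f <- programShape(p$shape, states$z, states$timepoint)
    logMu[p$genes, ] <- logMu[p$genes, , drop = FALSE] +
      p$effect * matrix(f, nrow = length(p$genes), ncol = nC, byrow = TRUE)
  }
  logMu <- logMu + batchShift[, states$batch, drop = FALSE]
  mu <- sweep(exp(logMu), 2L, libSize, "*")
  counts <- matrix(stats::rnbinom(nG * nC, mu = mu, size = config@dispersion),
                   nrow = nG,
                   dimnames = list(geneIds, states$cell_id))
  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(states, row.names = states$cell_id),
    rowData = DataFrame(gene_id = geneIds, program = program, shape = shape,
                        effect = effect, baseline = baseline,
                        row.names = geneIds))
  metadata(sce)$truth <- list(z = states$z, librarySize = libSize,
                              baseline = baseline, batchShift = batchShift,
                              expectedMean = mu)
  metadata(sce)$config <- config
  sce
}

#' Spherical-Hertz force at given indentation
#'
#' Forward contact-mechanics model `F = 4 E sqrt(R) delta^(3/2) /
#' (3 (1 - nu^2))` for a spherical indenter.
#'
#' @param delta indentation depth (m).
#' @param E Young's modulus (Pa).
#' @param RTip sphere radius (m).
#' @param nu Poisson ratio (default 0.5, incompressible tissue).
#' @return force (N).
#' @examples
#' hertzForce(1e-6, 10e3, 2.5e-6)  # ~2.81e-8 N = 28.1 nN
#' @export
hertzForce <- function(delta, E, RTip, nu = 0.5) {
  stopifnot(E > 0, RTip > 0, nu >= 0, nu <= 0.5)
  4 * E * sqrt(RTip) / (3 * (1 - nu^2)) * pmax(0, delta)^1.5
}

#' Simulate an AFM force-distance curve
#'
#' Generates an approach curve of known modulus: flat (zero-deflection)
#' baseline before the contact point `z0`, then deflection `d` solving the
#' implicit cantilever/contact balance `k d = F_hertz((z - z0) - d)`.
#' Gaussian force noise of SD `noiseSd` is added to the deflection channel.
#'
#' @param ETrue true Young's modulus (Pa).
#' @param RTip sphere radius (m; default 2.5e-6, a 5 um sphere).
#' @param kSpring cantilever spring constant (N/m; default 0.25).
#' @param z0 contact point (m).
#' @param noiseSd Gaussian force noise SD (N; default 0 = noiseless).
#' @param seed integer seed for the noise.
#' @param n number of samples (default 400).
#' @param maxIndentation deepest indentation simulated (m; default 1e-6).
#' @param nu Poisson ratio (default 0.5).
#' @param sensitivity deflection sensitivity recorded in the metadata
#'   (m/V; default 5e-8).
#' @return a [ForceCurve-class]; the true contact point is available as
#'   `attr(curve, "z0True")`.
#' @export
synthForceCurve <- function(ETrue, RTip = 2.5e-6, kSpring = 0.25, z0 = 2e-6,
                            noiseSd = 0, seed = 1L, n = 400L,
                            maxIndentation = 1e-6, nu = 0.5,
                            sensitivity = 5e-8) {
  if (ETrue <= 0 || RTip <= 0 || kSpring <= 0 || maxIndentation <= 0)
    stop("ETrue, RTip, kSpring and maxIndentation must be positive")
  C <- 4 * ETrue * sqrt(RTip) / (3 * (1 - nu^2))
  dMax <- hertzForce(maxIndentation, ETrue, RTip, nu) / kSpring
  z <- seq(0, z0 + maxIndentation + dMax, length.out = n)
  d <- numeric(n)
  post <- which(z > z0)
  for (i in post) {
    s <- z[i] - z0
    di <- 0
    # Newton iteration on g(d) = k d - C (s - d)^{3/2}; converges to
    # machine precision so the generator/fitter round trip is exact.
    for (it in 1:100) {
      delta <- s - di
      g <- kSpring * di - C * delta^1.5
      gp <- kSpring + 1.5 * C * sqrt(max(delta, 0))
      step <- g / gp
      di <- di - step
      if (di < 0) di <- 0
      if (di > s) di <- s
      if (abs(step) < 1e-22) break
    }
    d[i] <- di
  }
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    d <- d + stats::rnorm(n, 0, noiseSd / kSpring)
  }
  curve <- methods::new("ForceCurve", z = z, d = d, kSpring = kSpring,
                        sensitivity = sensitivity, RTip = RTip, nu = nu,
                        direction = "approach")
  attr(curve, "z0True") <- z0
  curve
}

#' Rasterize straight fiber segments into a binary mask
#'
#' Draws 1-pixel-wide Bresenham lines; the ground-truth total length is the
#' sum of Euclidean endpoint distances times the pixel size.
#'
#' @param segments list of numeric vectors c(r0, c0, r1, c1), 1-based pixel
#'   coordinates; may be empty.
#' @param imageShape c(rows, cols).
#' @param pxSize pixel size (um/px; default 1).
#' @return list(mask = binary matrix, length = ground-truth length in um).
#' @export
synthFiberMask <- function(segments, imageShape, pxSize = 1) {
  stopifnot(length(imageShape) == 2L, all(imageShape >= 1L), pxSize > 0)
  mask <- matrix(0L, imageShape[1], imageShape[2])
  total <- 0
  for (s in segments) {
    stopifnot(length(s) == 4L)
    if (any(s[c(1, 3)] < 1) || any(s[c(1, 3)] > imageShape[1]) ||
        any(s[c(2, 4)] < 1) || any(s[c(2, 4)] > imageShape[2]))
      stop("segment endpoints must lie inside the image")
    px <- bresenham(s[1], s[2], s[3], s[4])
    mask[px] <- 1L
    total <- total + sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2) * pxSize
  }
  list(mask = mask, length = total)
}

# Integer Bresenham line; returns a 2-column (row, col) index matrix.
bresenham <- function(r0, c0, r1, c1) {
  r0 <- as.integer(round(r0)); c0 <- as.integer(round(c0))
  r1 <- as.integer(round(r1)); c1 <- as.integer(round(c1))
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dr - dc
  out <- matrix(0L, dr + dc + 1L, 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    out[i, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r0 <- r0 + sr }
    if (e2 < dr) { err <- err + dr; c0 <- c0 + sc }
  }
  out[seq_len(i), , drop = FALSE]
}

#' Generate a planted TF -> target edge list
#'
#' Emits a TRRUST-dialect regulon table in which one synthetic TF targets
#' each planted gene program (so enrichment against detected modules has
#' ground truth), plus decoy TFs with random target sets.
#'
#' @param sce a [synthCounts()] object (its rowData provides programs).
#' @param nDecoys number of decoy TFs (default 20).
#' @param targetsPerDecoy targets drawn per decoy TF (default 20).
#' @param seed integer seed.
#' @return data.frame(tf, target, mode, references).
#' @export
synthRegulons <- function(sce, nDecoys = 20L, targetsPerDecoy = 20L, seed = 1L) {
  rd <- rowData(sce)
  set.seed(as.integer(seed))
  rows <- list()
  for (p in setdiff(unique(rd$program), "none")) {
    targets <- rownames(sce)[rd$program == p]
    if (length(targets) < 3L) next
    rows[[p]] <- data.frame(tf = paste0("TF_", p), target = targets,
                            mode = "Activation", references = "synthetic",
                            stringsAsFactors = FALSE)
  }
  for (i in seq_len(nDecoys)) {
    targets <- sample(rownames(sce), targetsPerDecoy)
    rows[[paste0("decoy", i)]] <-
      data.frame(tf = sprintf("TF_decoy%02d", i), target = targets,
                 mode = sample(c("Activation", "Repression", "Unknown"),
                               targetsPerDecoy, replace = TRUE),
                 references = "synthetic", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write counts as MTX triplet plus TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells, 1-based triplets), `genes.tsv`,
#' `barcodes.tsv` and `cell_metadata.tsv` (cell_id, lineage, timepoint,
#' batch) into `dir`; the planted latent coordinate goes to a
#' `ground_truth.json` sidecar.
#'
#' @param sce a [synthCounts()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCountsMTX <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(.countMat(sce), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(colData(sce))
  utils::write.table(cd[, c("cell_id", "lineage", "timepoint", "batch")],
                     file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if ("z" %in% names(cd)) {
    jsonlite::write_json(list(z = cd$z, cell_id = cd$cell_id),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read counts written by [writeCountsMTX()]
#'
#' @param dir directory holding matrix.mtx + genes.tsv + barcodes.tsv +
#'   cell_metadata.tsv.
#' @return a SingleCellExperiment with assay `counts`.
#' @export
readCountsMTX <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(genes, cells)
  meta <- utils::read.delim(file.path(dir, "cell_metadata.tsv"),
                            stringsAsFactors = FALSE)
  stopifnot(identical(meta$cell_id, cells))
  SingleCellExperiment(assays = list(counts = m),
                       colData = DataFrame(meta, row.names = cells))
}

#' Read a dense CSV count matrix (genes as rows, header = cell ids)
#'
#' @param path CSV file.
#' @param metadataPath TSV with columns cell_id, lineage, timepoint, batch.
#' @return a SingleCellExperiment with assay `counts`.
#' @export
readCountsCSV <- function(path, metadataPath) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
  need <- c("cell_id", "lineage", "timepoint", "batch")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  m <- m[, meta$cell_id, drop = FALSE]
  SingleCellExperiment(assays = list(counts = m),
                       colData = DataFrame(meta, row.names = meta$cell_id))
}
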