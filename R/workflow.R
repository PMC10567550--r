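
# declared parameter domains; unknown keys are rejected at load
.paramSpec <- list(
  min_genes = list(default = 200L, check = function(v) v >= 1),
  n_hvg = list(default = 5000L, check = function(v) v >= 1),
  n_pcs = list(default = 15L, check = function(v) v >= 1),
  k_neighbors = list(default = 20L, check = function(v) v >= 2),
  resolution = list(default = 0.5, check = function(v) v >= 0),
  n_nodes = list(default = 12L, check = function(v) v >= 2),
  trajectory_dims = list(default = 5L, check = function(v) v >= 2),
  trend_span = list(default = 0.3, check = function(v) v > 0 && v <= 1),
  module_resolution = list(default = 1, check = function(v) v > 0),
  marker = list(default = "Lrig1", check = function(v) is.character(v) && nzchar(v)),
  threshold = list(default = 1.0, check = function(v) is.finite(v)),
  fc_threshold = list(default = 1.6, check = function(v) v > 0),
  q_threshold = list(default = 0.5, check = function(v) v > 0 && v <= 1),
  effect_threshold = list(default = 0.9, check = function(v) v >= 0 && v <= 1),
  n_perm = list(default = 99L, check = function(v) v >= 1),
  reversal_p_adj = list(default = 0.05, check = function(v) v > 0 && v <= 1),
  hertz_window = list(default = c(0.2, 0.8),
                      check = function(v) length(v) == 2 && v[1] > 0 &&
                        v[2] < 1 && v[1] < v[2]),
  nu = list(default = 0.5, check = function(v) v >= 0 && v <= 0.5),
  r2_min = list(default = 0.9, check = function(v) v >= 0 && v <= 1),
  e_max = list(default = 1e6, check = function(v) v > 0),
  afm_grid = list(default = c(24L, 24L),
                  check = function(v) length(v) == 2 && all(v >= 1))
)

#' Build or load a pipeline configuration
#'
#' `pipelineConfig()` builds a validated [PipelineConfig-class] from
#' defaults plus overrides; `loadConfig()` reads one from a YAML file.
#' Unknown keys and out-of-domain values are rejected, with all
#' violations reported together.
#'
#' @param params named list of parameter overrides (see the vignette for
#'   the catalogue and defaults).
#' @param paths named list of input/output paths; `outdir` is used by
#'   [runPipeline()].
#' @param seed global integer seed (default 1).
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(params = list(), paths = list(), seed = 1L) {
  errs <- character()
  unknown <- setdiff(names(params), names(.paramSpec))
  if (length(unknown))
    errs <- c(errs, paste("unknown parameter(s):", paste(unknown, collapse = ", ")))
  full <- lapply(names(.paramSpec), function(k) {
    v <- if (k %in% names(params)) params[[k]] else .paramSpec[[k]]$default
    if (!k %in% unknown && !isTRUE(.paramSpec[[k]]$check(v)))
      errs <<- c(errs, paste0("parameter '", k, "' out of domain: ",
                              paste(v, collapse = ", ")))
    v
  })
  names(full) <- names(.paramSpec)
  if (length(errs)) stop(paste(errs, collapse = "; "))
  methods::new("PipelineConfig", paths = paths, params = full,
               seed = as.integer(seed))
}

#' @rdname pipelineConfig
#' @param path YAML file with optional top-level keys `params`, `paths`,
#'   `seed`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  extra <- setdiff(names(y), c("params", "paths", "seed"))
  if (length(extra))
    stop("unknown top-level config key(s): ", paste(extra, collapse = ", "))
  pipelineConfig(params = if (is.null(y$params)) list() else y$params,
                 paths = if (is.null(y$paths)) list() else y$paths,
                 seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Save a pipeline configuration as YAML
#'
#' Round-trips through [loadConfig()].
#'
#' @param config a [PipelineConfig-class].
#' @param path output YAML.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(list(params = config@params, paths = config@paths,
                        seed = config@seed), path)
  invisible(path)
}

#' Run the full synthetic-mode pipeline
#'
#' Executes the declared stage order on generator output: simulate ->
#' filter -> normalize -> batch-correct -> HVG -> PCA -> cluster ->
#' principal graph -> pseudotime -> transition kernel -> trends -> modules
#' -> regulon enrichment -> reversal statistic, plus the independent AFM
#' and actin branches. All randomness derives deterministically from the
#' global seed. Numeric outputs are written under `paths$outdir` (TSV/CSV/
#' JSON) and checksummed into the run report.
#'
#' @param config a [PipelineConfig-class]; `paths$outdir` required.
#' @param design optional [SynthConfig-class]; the default design is
#'   used when NULL (its seed is overridden by the pipeline stage seed).
#' @return run report list: per-stage counts, parameter echo, output
#'   checksums and warnings.
#' @export
runPipeline <- function(config, design = NULL) {
  outdir <- config@paths$outdir
  if (is.null(outdir)) stop("config paths$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config@params
  seeds <- deriveSeeds(config@seed, 12L)
  report <- list(seed = config@seed, params = p, stages = list(),
                 warnings = character())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- res$info
    res$value
  }

  sce <- stage("simulate", {
    sc <- if (is.null(design)) synthConfig(seed = seeds[1]) else {
      design@seed <- seeds[1]; design
    }
    states <- synthCells(sc)
    v <- synthCounts(states, sc)
    list(value = v, info = list(cells = ncol(v), genes = nrow(v)))
  })
  sce <- stage("filter", {
    v <- filterCells(sce, minGenes = p$min_genes)
    list(value = v, info = list(cells_kept = ncol(v)))
  })
  sce <- stage("normalize", {
    v <- normalizeCounts(sce)
    list(value = v, info = list(median_size_factor =
                                  stats::median(SingleCellExperiment::sizeFactors(v))))
  })
  sce <- stage("batch_correct", {
    v <- batchCorrect(sce)
    list(value = v, info = list(batches = length(unique(colData(sce)$batch))))
  })
  hvg <- stage("hvg", {
    v <- selectHVG(sce, n = p$n_hvg)
    list(value = v, info = list(n_hvg = length(v)))
  })
  emb <- stage("pca", {
    v <- pcaEmbed(sce, hvg = hvg, nPcs = p$n_pcs)
    list(value = v, info = list(n_pcs = ncol(v@coordinates)))
  })
  clusters <- stage("cluster", {
    v <- clusterCells(emb, kNeighbors = p$k_neighbors,
                      resolution = p$resolution, seed = seeds[2])
    list(value = v, info = list(n_clusters = length(unique(v$labels))))
  })
  # pseudotemporal ordering is performed on lineage-positive cells, in a
  # low-dimensional trajectory space (top PCs)
  pos <- colData(sce)$lineage == "pos"
  tdims <- min(p$trajectory_dims, p$n_pcs)
  embPos <- emb@coordinates[pos, seq_len(tdims), drop = FALSE]
  graph <- stage("principal_graph", {
    v <- fitPrincipalGraph(embPos, nNodes = p$n_nodes, seed = seeds[3])
    list(value = v, info = list(n_nodes = nrow(v@nodePositions)))
  })
  t <- stage("pseudotime", {
    # root at the most differentiated state: high Gata6, low Lrig1
    score <- .logMat(sce)["Gata6", pos] - .logMat(sce)["Lrig1", pos]
    v <- computePseudotime(graph, rootScore = score)
    list(value = v, info = list(range = range(v)))
  })
  tm <- stage("transition_kernel", {
    v <- pseudotimeKernel(embPos, t, kNeighbors = min(p$k_neighbors,
                                                      sum(pos) - 1L))
    list(value = v, info = list(sigma = v@sigma))
  })
  trends <- stage("trends", {
    v <- geneTrends(sce[, pos], t,
                    genes = hvg[seq_len(min(300L, length(hvg)))],
                    span = p$trend_span)
    list(value = v, info = list(genes = nrow(v@trends)))
  })
  modules <- stage("modules", {
    v <- detectModules(trends, resolution = p$module_resolution,
                       seed = seeds[4])
    list(value = v, info = list(n_modules = length(unique(v))))
  })
  enrich <- stage("enrichment", {
    db <- regulonsFromFrame(synthRegulons(sce, seed = seeds[5]))
    background <- rownames(trends@trends)
    tabs <- lapply(sort(unique(modules)), function(mod) {
      regulonEnrichment(names(modules)[modules == mod], db, background,
                        qThreshold = p$q_threshold,
                        effectThreshold = p$effect_threshold)
    })
    list(value = tabs, info = list(modules_tested = length(tabs)))
  })
  rev <- stage("reversal", {
    pops <- selectPopulations(sce, marker = p$marker,
                              threshold = p$threshold)
    v <- permutationTest(pops, sce, nPerm = p$n_perm, seed = seeds[6],
                         deOptions = list(pAdjThreshold = p$reversal_p_adj))
    list(value = v, info = list(R = v@R, permutation_p = v@permutationP,
                                n_genes = v@nGenes,
                                n_differentiating = length(pops@differentiating),
                                n_dedifferentiating = length(pops@dedifferentiating)))
  })
  afm <- stage("afm", {
    set.seed(seeds[7])
    shape <- as.integer(p$afm_grid)
    nCurves <- prod(shape)
    ETrue <- exp(stats::runif(nCurves, log(2e3), log(50e3)))
    fits <- vector("list", nCurves)
    for (i in seq_len(nCurves)) {
      cv <- synthForceCurve(ETrue[i], noiseSd = 1e-10, seed = seeds[7] + i,
                            n = 200L)
      fits[[i]] <- fitForceCurve(cv, window = p$hertz_window)
    }
    qc <- qcFilter(fits, r2Min = p$r2_min, EMax = p$e_max)
    coords <- cbind(rep(seq_len(shape[1]), each = shape[2]),
                    rep(seq_len(shape[2]), shape[1]))
    map <- buildStiffnessMap(fits, coords, shape = shape)
    list(value = map, info = list(curves = nCurves,
                                  accepted = length(qc$accepted)))
  })
  act <- stage("actin", {
    set.seed(seeds[8])
    segs <- lapply(1:12, function(i) {
      c(sample(10:110, 1), sample(10:110, 1), sample(10:110, 1),
        sample(10:110, 1))
    })
    fm <- synthFiberMask(segs, c(120L, 120L))
    v <- actinMetrics(fm$mask)
    v$ground_truth_length <- fm$length
    list(value = v, info = list(total_length_um = v$total_length_um,
                                mean_lacunarity = v$mean_lacunarity))
  })

  # write numeric outputs and checksum them
  utils::write.table(data.frame(cell_id = names(t), t = t),
                     file.path(outdir, "pseudotime.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(modules), module = modules),
                     file.path(outdir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Matrix::writeMM(transitionProbs(tm), file.path(outdir, "transition.mtx"))
  writeReversalResult(rev, file.path(outdir, "reversal"))
  writeStiffnessMap(afm, file.path(outdir, "stiffness_map"))
  jsonlite::write_json(act[c("total_length_um", "mean_lacunarity")],
                       file.path(outdir, "actin_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  report$checksums <- as.list(tools::md5sum(files))
  names(report$checksums) <- basename(files)
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report
}

#' Write a run report
#'
#' Emits the report as JSON plus a short human-readable text file.
#'
#' @param report list from [runPipeline()].
#' @param path output path for the JSON; a `.txt` sibling is written too.
#' @export
writeReport <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  txt <- c(sprintf("run seed: %d", report$seed),
           sprintf("stages executed: %d", length(report$stages)),
           vapply(names(report$stages), function(s) {
             info <- report$stages[[s]]
             paste0("  ", s, ": ",
                    paste(names(info),
                          vapply(info, function(v)
                            paste(signif(unlist(v), 6), collapse = ","), ""),
                          sep = "=", collapse = ", "))
           }, ""),
           if (length(report$warnings))
             c("warnings:", paste(" ", report$warnings)) else "no warnings")
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}
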