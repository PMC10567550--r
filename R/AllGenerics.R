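#' @rdname accessors
#' @export
setGeneric("youngsModulus", function(x, ...) standardGeneric("youngsModulus"))

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x, ...) standardGeneric("qcFlags"))

#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(x, ...) standardGeneric("transitionProbs"))

#' @rdname accessors
#' @export
setGeneric("regulonTargets", function(x, tf, ...) standardGeneric("regulonTargets"))

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x, ...) standardGeneric("geneTable"))

#' Accessors for epiRewind classes
#'
#' Small accessor layer so downstream code never touches slots directly:
#' `youngsModulus()` returns the fitted modulus of a [HertzFit-class] or the
#' modulus grid of a [StiffnessMap-class]; `qcFlags()` the QC flags of a fit;
#' `transitionProbs()` the sparse row-stochastic matrix of a
#' [TransitionMatrix-class]; `regulonTargets()` the target set of one TF in a
#' [RegulonDB-class]; `geneTable()` the per-gene table of a
#' [ReversalResult-class].
#'
#' @param x object.
#' @param tf transcription-factor symbol.
#' @param ... unused.
#' @return see above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("youngsModulus", "HertzFit", function(x, ...) x@E)

#' @rdname accessors
#' @export
setMethod("youngsModulus", "StiffnessMap", function(x, ...) x@E)

#' @rdname accessors
#' @export
setMethod("qcFlags", "HertzFit", function(x, ...) x@qcFlags)

#' @rdname accessors
#' @export
setMethod("transitionProbs", "TransitionMatrix", function(x, ...) x@probs)

#' @rdname accessors
#' @export
setMethod("regulonTargets", "RegulonDB", function(x, tf, ...) {
  if (!tf %in% names(x@index)) character() else x@index[[tf]]
})

#' @rdname accessors
#' @export
setMethod("geneTable", "ReversalResult", function(x, ...) x@geneTable)

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", sum(object@groups$n), "cells in",
      nrow(object@groups), "groups;", object@nGenes, "genes;",
      length(object@markerPrograms), "programs; reversal strength",
      object@reversalStrength, "\n")
})

setMethod("show", "PCAEmbedding", function(object) {
  cat("PCAEmbedding:", nrow(object@coordinates), "cells x",
      ncol(object@coordinates), "PCs (", length(object@hvg), "HVGs )\n")
})

setMethod("show", "PrincipalGraph", function(object) {
  cat("PrincipalGraph:", nrow(object@nodePositions), "nodes,",
      nrow(object@edges), "edges,", length(object@cellNode), "cells\n")
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix:", nrow(object@probs), "cells, k =",
      object@kNeighbors, ", sigma =", signif(object@sigma, 3), "\n")
})

setMethod("show", "ReversalPopulations", function(object) {
  cat("ReversalPopulations:", length(object@differentiating),
      "differentiating /", length(object@dedifferentiating),
      "dedifferentiating cells (", object@marker, "gate at",
      object@threshold, ")\n")
})

setMethod("show", "ReversalResult", function(object) {
  cat("ReversalResult:", object@nGenes, "genes; R =",
      signif(object@R, 3), "; Spearman =", signif(object@spearman, 3),
      if (is.finite(object@permutationP))
        paste("; permutation p =", signif(object@permutationP, 3)) else "",
      "\n")
})

setMethod("show", "RegulonDB", function(object) {
  cat("RegulonDB:", nrow(object@edges), "edges,",
      length(object@index), "TFs (", object@nDuplicates,
      "duplicates dropped )\n")
})

setMethod("show", "ForceCurve", function(object) {
  cat("ForceCurve:", length(object@z), "samples, k =", object@kSpring,
      "N/m, R =", object@RTip * 1e6, "um,", object@direction, "\n")
})

setMethod("show", "HertzFit", function(object) {
  if (length(object@qcFlags)) {
    cat("HertzFit: rejected (", paste(object@qcFlags, collapse = ", "), ")\n")
  } else {
    cat("HertzFit: E =", signif(object@E / 1e3, 4), "kPa, r2 =",
        signif(object@rSquared, 4), ",", object@nPoints, "points\n")
  }
})

setMethod("show", "StiffnessMap", function(object) {
  ok <- !is.na(object@E)
  cat("StiffnessMap:", nrow(object@E), "x", ncol(object@E), "grid,",
      sum(ok), "accepted, median E =",
      signif(stats::median(object@E[ok]) / 1e3, 4), "kPa\n")
})
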