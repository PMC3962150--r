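#' @include AllClasses.R
NULL

#' Accessors for annScreen classes
#'
#' `probeIds()`/`sampleIds()` return the row/column identifiers of an
#' [ExpressionMatrix-class]; `platformLabel()` its platform tag;
#' `exprValues()` the numeric intensity matrix. `probeScores()` returns the
#' score table of a [RankedList-class] and `targetProbe()` its target;
#' `networkNodes()`, `networkEdges()`, `interconnections()` and
#' `networkRuns()` expose the components of an [InteractionNetwork-class].
#'
#' @param x an annScreen object.
#' @return See each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("platformLabel", function(x) standardGeneric("platformLabel"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("probeScores", function(x) standardGeneric("probeScores"))

#' @rdname accessors
#' @export
setGeneric("targetProbe", function(x) standardGeneric("targetProbe"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("interconnections", function(x) standardGeneric("interconnections"))

#' @rdname accessors
#' @export
setGeneric("networkRuns", function(x) standardGeneric("networkRuns"))

# ---------------------------------------------------------------------------
# ExpressionMatrix methods
# ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("probeIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
setMethod("platformLabel", "ExpressionMatrix",
          function(x) metadata(x)$platform)

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix",
          function(x) assay(x, "exprs"))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples [platform: %s]\n",
              nrow(object), ncol(object), platformLabel(object)))
})

# ---------------------------------------------------------------------------
# RankedList methods
# ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("probeScores", "RankedList", function(x) x@scores)

#' @rdname accessors
setMethod("targetProbe", "RankedList", function(x) x@target)

#' @rdname accessors
setMethod("networkRuns", "InteractionNetwork", function(x) x@runs)

setMethod("length", "RankedList", function(x) nrow(x@scores))

setMethod("show", "RankedList", function(object) {
  s <- object@scores
  cat(sprintf("RankedList: %d probes screened against target '%s'\n",
              nrow(s), object@target))
  if (nrow(s)) {
    cat(sprintf("  best : %s (mean test RMS %.4f)\n",
                s$probe_id[1], s$mean_test_rms[1]))
    cat(sprintf("  worst: %s (mean test RMS %.4f)\n",
                s$probe_id[nrow(s)], s$mean_test_rms[nrow(s)]))
  }
  if (nzchar(object@fingerprint))
    cat(sprintf("  config fingerprint: %s\n", object@fingerprint))
})

# ---------------------------------------------------------------------------
# InteractionNetwork methods
# ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("interconnections", "InteractionNetwork", function(x) {
  stats::setNames(x@nodes$interconnections, x@nodes$gene)
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf(
    "InteractionNetwork: %d genes, %d edges (%d stored runs, %s membership)\n",
    nrow(object@nodes), nrow(object@edges), length(object@runs),
    object@membership))
  seed <- object@nodes$gene[object@nodes$role == "seed"]
  if (length(seed)) cat(sprintf("  seed gene: %s\n", seed[1]))
})

setMethod("show", "TrainedNetwork", function(object) {
  cat(sprintf("TrainedNetwork: %d epochs run, best validation at epoch %d\n",
              nrow(object@history), object@bestEpoch))
  if (nrow(object@history))
    cat(sprintf("  best validation RMS: %.5f\n",
                min(object@history$val_rms)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d samples; hub '%s' + %d partners + %d noise probes\n",
    object@nSamples, object@hubId, length(object@partners), object@nNoise))
})

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf(
    "ScreenConfig: %d loops x %d resamples (seed %d, scaleOn=%s)\n",
    object@nLoops, object@nResamplesPerLoop, object@seed, object@scaleOn))
})
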