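#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
NULL

# ---------------------------------------------------------------------------
# ExpressionMatrix
# ---------------------------------------------------------------------------

#' Probe-by-sample expression matrix
#'
#' An `ExpressionMatrix` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one assay `"exprs"` of continuous expression intensities, one row
#' per probe and one column per sample, plus a free-text platform label
#' (e.g. `"A-AFFY-33"`) in its metadata. Probe and sample identifiers must be
#' unique and every value finite; missing values are handled (rejected or
#' imputed) at ingestion time by [readExpressionMatrix()].
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [readExpressionMatrix()], [mergePlatforms()], [filterERPositive()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  v <- tryCatch(assay(object, "exprs"), error = function(e) NULL)
  if (is.null(v)) return("assay 'exprs' is missing")
  msg <- character()
  if (nrow(v) > 0 &&
      (is.null(rownames(v)) || anyNA(rownames(v)) ||
       !all(nzchar(rownames(v)))))
    msg <- c(msg, "probe IDs (rownames) must be present and non-empty")
  else if (anyDuplicated(rownames(v)))
    msg <- c(msg, sprintf("duplicate probe ID '%s'",
                          rownames(v)[anyDuplicated(rownames(v))]))
  if (ncol(v) > 0 &&
      (is.null(colnames(v)) || anyNA(colnames(v)) ||
       !all(nzchar(colnames(v)))))
    msg <- c(msg, "sample IDs (colnames) must be present and non-empty")
  else if (anyDuplicated(colnames(v)))
    msg <- c(msg, sprintf("duplicate sample ID '%s'",
                          colnames(v)[anyDuplicated(colnames(v))]))
  if (!is.numeric(v) || !all(is.finite(v)))
    msg <- c(msg, "expression values must be numeric and finite")
  if (is.null(metadata(object)$platform))
    msg <- c(msg, "platform label missing from metadata")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix of expression intensities, probes in rows
#'   (rownames = probe IDs) and samples in columns (colnames = sample IDs).
#' @param platform free-text platform label.
#' @return A validated [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6, 500, 100), 3, 2,
#'             dimnames = list(paste0("p", 1:3, "_at"), c("s1", "s2")))
#' ExpressionMatrix(m, platform = "demo")
#' @export
ExpressionMatrix <- function(values, platform = "unspecified") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(exprs = values))
  metadata(se)$platform <- as.character(platform)
  new("ExpressionMatrix", se)
}

# ---------------------------------------------------------------------------
# ANN types
# ---------------------------------------------------------------------------

#' Weights of the minimal multilayer perceptron
#'
#' One input layer of `nInputs` nodes (default 1: screening feeds a single
#' probe), `nHidden` sigmoid hidden nodes (default 2, a deliberately
#' parsimonious architecture), and a single sigmoid output node.
#'
#' @slot wIn numeric matrix (`nHidden` x `nInputs`) of input-to-hidden weights.
#' @slot bHidden numeric hidden-node biases (length `nHidden`).
#' @slot wOut numeric hidden-to-output weights (length `nHidden`).
#' @slot bOut numeric output bias (length 1).
#' @seealso [initNetwork()], [annForward()], [trainNetwork()]
#' @export
setClass("NetworkWeights",
         representation(wIn = "matrix", bHidden = "numeric",
                        wOut = "numeric", bOut = "numeric"))

setValidity("NetworkWeights", function(object) {
  H <- nrow(object@wIn)
  msg <- character()
  if (length(object@bHidden) != H || length(object@wOut) != H)
    msg <- c(msg, "bHidden and wOut must have one entry per hidden node")
  if (length(object@bOut) != 1L)
    msg <- c(msg, "bOut must be a single value")
  if (!all(is.finite(object@wIn), is.finite(object@bHidden),
           is.finite(object@wOut), is.finite(object@bOut)))
    msg <- c(msg, "all weights must be finite")
  if (length(msg)) msg else TRUE
})

#' Training hyperparameters for the perceptron
#'
#' Defaults follow the screening method's constants: learning rate 0.1 and
#' momentum 0.5, with early stopping monitored on a validation partition.
#'
#' @slot learningRate positive step size for gradient descent.
#' @slot momentum fraction of the previous weight update carried forward,
#'   in `[0, 1)`.
#' @slot maxEpochs maximum number of passes over the training patterns.
#' @slot patience epochs without validation improvement before stopping.
#' @slot minDelta minimum decrease in validation RMS that counts as an
#'   improvement for the patience counter (default 0: any strict decrease).
#'   The returned weights are always those of the strictly best validation
#'   epoch, whatever `minDelta`.
#' @slot initRange half-width of the uniform weight initialisation interval.
#' @slot seed integer RNG seed for weight initialisation.
#' @export
setClass("TrainConfig",
         representation(learningRate = "numeric", momentum = "numeric",
                        maxEpochs = "integer", patience = "integer",
                        minDelta = "numeric", initRange = "numeric",
                        seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must lie in [0, 1)")
  if (object@maxEpochs < 0L) msg <- c(msg, "maxEpochs must be >= 0")
  if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
  if (object@minDelta < 0) msg <- c(msg, "minDelta must be >= 0")
  if (object@initRange < 0) msg <- c(msg, "initRange must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainConfig-class Constructor.
#' @param learningRate,momentum,maxEpochs,patience,minDelta,initRange,seed
#'   see slots.
#' @export
trainConfig <- function(learningRate = 0.1, momentum = 0.5, maxEpochs = 3000,
                        patience = 100, minDelta = 0, initRange = 0.5,
                        seed = 1L) {
  new("TrainConfig", learningRate = learningRate, momentum = momentum,
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      minDelta = minDelta, initRange = initRange, seed = as.integer(seed))
}

#' A trained perceptron with its training history
#'
#' @slot weights [NetworkWeights-class] from the best validation epoch.
#' @slot finalWeights weights after the last executed epoch.
#' @slot bestEpoch epoch (1-based) at which validation RMS was minimal;
#'   0 when no epoch was run.
#' @slot history data.frame with columns `epoch`, `train_rms`, `val_rms`.
#' @export
setClass("TrainedNetwork",
         representation(weights = "NetworkWeights",
                        finalWeights = "NetworkWeights",
                        bestEpoch = "integer", history = "data.frame"))

setValidity("TrainedNetwork", function(object) {
  h <- object@history
  if (nrow(h) && abs(min(h$val_rms) - h$val_rms[object@bestEpoch]) > 1e-12)
    return("bestEpoch must attain the minimum validation RMS in the history")
  TRUE
})

# ---------------------------------------------------------------------------
# Screening types
# ---------------------------------------------------------------------------

#' Monte Carlo cross-validation split fractions
#'
#' @slot train,test,validation positive fractions summing to 1
#'   (default 0.6 / 0.2 / 0.2).
#' @export
setClass("SplitSpec",
         representation(train = "numeric", test = "numeric",
                        validation = "numeric"))

setValidity("SplitSpec", function(object) {
  f <- c(object@train, object@test, object@validation)
  if (any(f <= 0)) return("all fractions must be positive")
  if (abs(sum(f) - 1) > 1e-8) return("fractions must sum to 1")
  TRUE
})

#' @describeIn SplitSpec-class Constructor.
#' @param train,test,validation split fractions.
#' @export
splitSpec <- function(train = 0.6, test = 0.2, validation = 0.2) {
  new("SplitSpec", train = train, test = test, validation = validation)
}

#' Configuration of a whole-matrix screening run
#'
#' Each candidate probe is scored by `nLoops * nResamplesPerLoop` independently
#' initialised models, each trained on a fresh MCCV split; the ranking
#' statistic is the mean test-partition RMS error. The embedded training
#' profile defaults to shorter epoch caps than [trainConfig()] because a
#' single-input two-hidden-node net converges within tens of epochs and the
#' training is repeated tens of thousands of times per screen.
#'
#' @slot train [TrainConfig-class] used for every model.
#' @slot nLoops number of screening loops (default 5); per-loop mean errors
#'   are reported alongside the overall mean.
#' @slot nResamplesPerLoop models per loop (default 10).
#' @slot split [SplitSpec-class] MCCV fractions.
#' @slot topN default length of the selected head of the ranking (default 100).
#' @slot seed master seed; per-probe substreams are derived from a hash of
#'   (seed, probe ID) so results are independent of screening order.
#' @slot scaleOn `"train"` (fit min-max scaling on the training partition,
#'   no leakage) or `"all"` (fit-on-all compatibility mode).
#' @slot bootstrap if `TRUE`, training patterns are drawn with replacement
#'   from the training partition instead of used once each.
#' @export
setClass("ScreenConfig",
         representation(train = "TrainConfig", nLoops = "integer",
                        nResamplesPerLoop = "integer", split = "SplitSpec",
                        topN = "integer", seed = "integer",
                        scaleOn = "character", bootstrap = "logical"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@nLoops < 1L) msg <- c(msg, "nLoops must be >= 1")
  if (object@nResamplesPerLoop < 1L)
    msg <- c(msg, "nResamplesPerLoop must be >= 1")
  if (object@topN < 1L) msg <- c(msg, "topN must be >= 1")
  if (!object@scaleOn %in% c("train", "all"))
    msg <- c(msg, "scaleOn must be 'train' or 'all'")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScreenConfig-class Constructor.
#' @param train,nLoops,nResamplesPerLoop,split,topN,seed,scaleOn,bootstrap
#'   see slots.
#' @export
screenConfig <- function(train = trainConfig(maxEpochs = 300, patience = 10,
                                             minDelta = 2e-4),
                         nLoops = 5, nResamplesPerLoop = 10,
                         split = splitSpec(), topN = 100, seed = 1L,
                         scaleOn = c("train", "all"), bootstrap = FALSE) {
  new("ScreenConfig", train = train, nLoops = as.integer(nLoops),
      nResamplesPerLoop = as.integer(nResamplesPerLoop), split = split,
      topN = as.integer(topN), seed = as.integer(seed),
      scaleOn = match.arg(scaleOn), bootstrap = bootstrap)
}

#' Ranked screening result
#'
#' All screened probes ordered by ascending mean test RMS error (ties broken
#' lexicographically by probe ID).
#'
#' @slot target the target probe ID the screen predicted.
#' @slot scores data.frame with columns `rank`, `probe_id`, `gene_symbol`,
#'   `mean_test_rms`, `median_train_acc`, `n_models`, `degenerate`.
#' @slot loopMeans numeric matrix (probes x loops) of per-loop mean test RMS,
#'   rows aligned with `scores`.
#' @slot fingerprint short hash of the generating configuration.
#' @export
setClass("RankedList",
         representation(target = "character", scores = "data.frame",
                        loopMeans = "matrix", fingerprint = "character"))

setValidity("RankedList", function(object) {
  s <- object@scores
  need <- c("rank", "probe_id", "mean_test_rms")
  if (!all(need %in% names(s)))
    return("scores must contain rank, probe_id, mean_test_rms")
  if (anyDuplicated(s$probe_id)) return("probe_id entries must be unique")
  if (is.unsorted(s$mean_test_rms))
    return("scores must be ordered by non-decreasing mean_test_rms")
  if (nrow(object@loopMeans) && nrow(object@loopMeans) != nrow(s))
    return("loopMeans rows must align with scores")
  TRUE
})

#' @describeIn RankedList-class Constructor (also used to inject precomputed
#'   rankings, e.g. for auditing network growth).
#' @param target,scores,loopMeans,fingerprint see slots.
#' @export
rankedList <- function(target, scores, loopMeans = NULL, fingerprint = "") {
  if (is.null(loopMeans))
    loopMeans <- matrix(numeric(0), nrow = nrow(scores), ncol = 0)
  new("RankedList", target = target, scores = scores,
      loopMeans = loopMeans, fingerprint = fingerprint)
}

# ---------------------------------------------------------------------------
# Network growth types
# ---------------------------------------------------------------------------

#' Configuration of recursive network growth
#'
#' @slot seedProbe probe ID used as the first screening target.
#' @slot topK genes carried from each ranking to the next layer (default 10).
#' @slot topN ranking-head length defining list membership (default 100).
#' @slot depth number of screening layers (default 2: the seed run plus one
#'   round of panel runs).
#' @slot screen [ScreenConfig-class] applied to every run.
#' @slot membership `"top_n"` (a gene is a member of a run when any of its
#'   probes is in the run's top `topN`) or `"top_k"` (membership restricted to
#'   the run's `topK` gene panel).
#' @export
setClass("GrowthConfig",
         representation(seedProbe = "character", topK = "integer",
                        topN = "integer", depth = "integer",
                        screen = "ScreenConfig", membership = "character"))

setValidity("GrowthConfig", function(object) {
  msg <- character()
  if (object@topK < 0L) msg <- c(msg, "topK must be >= 0")
  if (object@topK > object@topN) msg <- c(msg, "topK must be <= topN")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (!object@membership %in% c("top_n", "top_k"))
    msg <- c(msg, "membership must be 'top_n' or 'top_k'")
  if (length(msg)) msg else TRUE
})

#' @describeIn GrowthConfig-class Constructor.
#' @param seedProbe,topK,topN,depth,screen,membership see slots.
#' @export
growthConfig <- function(seedProbe, topK = 10, topN = 100, depth = 2,
                         screen = screenConfig(),
                         membership = c("top_n", "top_k")) {
  new("GrowthConfig", seedProbe = as.character(seedProbe),
      topK = as.integer(topK), topN = as.integer(topN),
      depth = as.integer(depth), screen = screen,
      membership = match.arg(membership))
}

#' Gene interaction network from recursive screening
#'
#' Nodes are gene symbols tagged by role (`seed`, `panel`); a directed edge
#' records that the target gene of one screening run found the other gene in
#' its ranking head, annotated with the member's best rank in that run. The
#' interconnection count of a gene is the number of runs seeded by *other*
#' panel genes whose ranking head contains any probe of the gene; it is
#' recomputable from the stored rankings.
#'
#' @slot nodes data.frame with columns `gene`, `role`, `interconnections`.
#' @slot edges data.frame with columns `from`, `to`, `member_rank`.
#' @slot runs named list of [RankedList-class], one per screened gene.
#' @slot topN,membership the membership rule the counts were computed under.
#' @export
setClass("InteractionNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        runs = "list", topN = "integer",
                        membership = "character"))

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  if (!all(c("gene", "role", "interconnections") %in% names(object@nodes)))
    msg <- c(msg, "nodes must have gene, role, interconnections columns")
  if (!all(c("from", "to", "member_rank") %in% names(object@edges)))
    msg <- c(msg, "edges must have from, to, member_rank columns")
  if (nrow(object@edges) &&
      any(object@edges$from == object@edges$to))
    msg <- c(msg, "self-edges are not allowed")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Synthetic-data types
# ---------------------------------------------------------------------------

#' Specification of a synthetic hub-partner expression dataset
#'
#' Emulates the statistical shape of a merged two-platform microarray cohort:
#' one designated hub probe, partner probes correlated with the hub at planted
#' strengths, and a background of independent noise probes.
#'
#' @slot nSamples number of samples (>= 10).
#' @slot hubId probe ID of the hub.
#' @slot partners named numeric vector: names are partner probe IDs, values
#'   their population correlation with the hub latent factor, each in (-1, 1).
#' @slot nNoise number of independent background probes.
#' @slot noiseSd standard deviation of measurement noise added to every probe,
#'   in intensity units (after the affine map).
#' @slot intensityOffset,intensityScale affine map from the unit-variance
#'   latent scale to a plausible expression-intensity range.
#' @slot intensityFloor lower clamp mimicking intensity positivity.
#' @slot splitTwoPlatforms if `TRUE`, the probes are partitioned into two
#'   matrices over the same samples (first half / second half of the row
#'   order), as for a two-chip design.
#' @slot erNegativeFraction,erUnknownFraction fractions of samples labelled
#'   ER-negative / ER-unknown in the generated metadata (default 0: all
#'   positive).
#' @slot seed integer RNG seed; identical seeds give bit-identical output.
#' @export
setClass("SyntheticSpec",
         representation(nSamples = "integer", hubId = "character",
                        partners = "numeric", nNoise = "integer",
                        noiseSd = "numeric", intensityOffset = "numeric",
                        intensityScale = "numeric", intensityFloor = "numeric",
                        splitTwoPlatforms = "logical",
                        erNegativeFraction = "numeric",
                        erUnknownFraction = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nSamples < 10L) msg <- c(msg, "nSamples must be >= 10")
  if (length(object@partners) && any(abs(object@partners) >= 1))
    msg <- c(msg, "every partner correlation must satisfy |rho| < 1")
  if (object@nNoise < 0L) msg <- c(msg, "nNoise must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  ids <- c(object@hubId, names(object@partners))
  if (anyDuplicated(ids)) msg <- c(msg, "probe IDs must be unique")
  if (object@erNegativeFraction < 0 || object@erUnknownFraction < 0 ||
      object@erNegativeFraction + object@erUnknownFraction >= 1)
    msg <- c(msg, "ER-negative/unknown fractions must be >= 0 and sum < 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticSpec-class Constructor. Unnamed `partners` are given
#'   IDs `PARTNER_001_at`, ...; noise probes are `NOISE_0001_at`, ....
#' @param nSamples,hubId,partners,nNoise,noiseSd,intensityOffset,intensityScale
#'   see slots.
#' @param intensityFloor,splitTwoPlatforms,erNegativeFraction see slots.
#' @param erUnknownFraction,seed see slots.
#' @export
syntheticSpec <- function(nSamples = 200, hubId = "HUB_0001_at",
                          partners = numeric(0), nNoise = 100,
                          noiseSd = 20, intensityOffset = 500,
                          intensityScale = 120, intensityFloor = 0.1,
                          splitTwoPlatforms = FALSE,
                          erNegativeFraction = 0, erUnknownFraction = 0,
                          seed = 1L) {
  partners <- as.numeric2named(partners)
  new("SyntheticSpec", nSamples = as.integer(nSamples), hubId = hubId,
      partners = partners, nNoise = as.integer(nNoise), noiseSd = noiseSd,
      intensityOffset = intensityOffset, intensityScale = intensityScale,
      intensityFloor = intensityFloor, splitTwoPlatforms = splitTwoPlatforms,
      erNegativeFraction = erNegativeFraction,
      erUnknownFraction = erUnknownFraction, seed = as.integer(seed))
}

# name partner vectors that arrive unnamed
as.numeric2named <- function(partners) {
  v <- unlist(partners)
  nm <- names(v)
  v <- as.numeric(v)
  if (length(v)) {
    if (is.null(nm) || !all(nzchar(nm)))
      nm <- sprintf("PARTNER_%03d_at", seq_along(v))
    names(v) <- nm
  }
  v
}

#' Planted structure of a synthetic dataset
#'
#' @slot hubId the hub probe ID.
#' @slot partners named numeric vector of planted partner correlations.
#' @slot noiseIds IDs of the independent background probes.
#' @export
setClass("SyntheticTruth",
         representation(hubId = "character", partners = "numeric",
                        noiseIds = "character"))
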