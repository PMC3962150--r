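#' @include AllClasses.R AllGenerics.R ann.R
NULL

#' Monte Carlo cross-validation split
#'
#' Draws one random partition of `n` samples into training, test and
#' validation index sets. Test and validation sizes are the nearest integer
#' (half-up) to their fractions of `n`; training takes the remainder, so
#' `n = 211` at 60/20/20 gives 127/42/42.
#'
#' @param n number of samples (>= 5).
#' @param spec a [SplitSpec-class].
#' @return list with integer index vectors `train`, `test`, `validation`;
#'   disjoint and jointly exhaustive.
#' @details Uses R's RNG; seed the session (or wrap in a seeded context) for
#'   reproducible splits. The screening loop itself derives its splits from
#'   the [ScreenConfig-class] master seed instead.
#' @examples
#' set.seed(1)
#' lengths(mccvSplit(211, splitSpec())) # 127, 42, 42
#' @export
mccvSplit <- function(n, spec = splitSpec()) {
  stopifnot(n >= 5)
  nTest <- as.integer(floor(spec@test * n + 0.5))
  nVal <- as.integer(floor(spec@validation * n + 0.5))
  nTrain <- n - nTest - nVal
  if (nTrain < 1 || nTest < 1 || nVal < 1)
    stop(sprintf("MCCV partition empty: n=%d gives train=%d/test=%d/val=%d",
                 n, nTrain, nTest, nVal))
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(nTrain)]),
       test = sort(perm[nTrain + seq_len(nTest)]),
       validation = sort(perm[nTrain + nTest + seq_len(nVal)]))
}

screenFingerprint <- function(cfg, target) {
  cpp_hash_string(paste(
    target, cfg@seed, cfg@nLoops, cfg@nResamplesPerLoop,
    cfg@split@train, cfg@split@test, cfg@split@validation,
    cfg@train@learningRate, cfg@train@momentum, cfg@train@maxEpochs,
    cfg@train@patience, cfg@train@minDelta, cfg@train@initRange,
    cfg@scaleOn, cfg@bootstrap, sep = "|"))
}

# shared driver: run the compiled screening loop for the given candidate rows
screenCore <- function(m, candidates, target, cfg, ann = NULL) {
  X <- exprValues(m)
  if (!target %in% rownames(X)) stop("target probe '", target,
                                     "' not in matrix")
  miss <- setdiff(candidates, rownames(X))
  if (length(miss)) stop("candidate probe '", miss[1], "' not in matrix")
  res <- cpp_screen(X[candidates, , drop = FALSE], X[target, ], candidates,
                    cfg@nLoops, cfg@nResamplesPerLoop,
                    cfg@split@test, cfg@split@validation, 2L,
                    cfg@train@learningRate, cfg@train@momentum,
                    cfg@train@maxEpochs, cfg@train@patience,
                    cfg@train@minDelta, cfg@train@initRange,
                    cfg@scaleOn == "all", cfg@bootstrap,
                    as.double(cfg@seed))
  nModels <- cfg@nLoops * cfg@nResamplesPerLoop
  loop <- rep(seq_len(cfg@nLoops), each = cfg@nResamplesPerLoop)
  loopMeans <- vapply(seq_len(cfg@nLoops), function(l)
    rowMeans(res$rms[, loop == l, drop = FALSE]),
    numeric(length(candidates)))
  if (!is.matrix(loopMeans))
    loopMeans <- matrix(loopMeans, nrow = length(candidates))
  dimnames(loopMeans) <- list(candidates, sprintf("loop%d", seq_len(cfg@nLoops)))
  sym <- if (is.null(ann)) candidates
         else unname(mapProbesToSymbols(candidates, ann))
  scores <- data.frame(
    probe_id = candidates,
    gene_symbol = sym,
    mean_test_rms = rowMeans(res$rms),
    median_train_acc = roundHalfUp(apply(res$acc, 1, stats::median), 1),
    n_models = nModels,
    degenerate = as.logical(res$degenerate),
    stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores, loopMeans = loopMeans)
}

#' Score one candidate probe against a target
#'
#' Trains `nLoops * nResamplesPerLoop` freshly initialised single-input
#' perceptrons on the candidate probe predicting the (min-max scaled) target,
#' each on a fresh MCCV split, and aggregates the test-partition RMS errors.
#' A constant candidate is not an error: it is trained as a constant
#' predictor and flagged `degenerate`.
#'
#' @param m an [ExpressionMatrix-class].
#' @param candidate,target probe IDs present in `m`.
#' @param cfg a [ScreenConfig-class]. The candidate's random substream is
#'   derived from (master seed, candidate ID), so the score is identical
#'   whether the probe is screened alone or within [screenAll()].
#' @return One-row data.frame with `probe_id`, `gene_symbol`,
#'   `mean_test_rms`, `median_train_acc`, `n_models`, `degenerate`, plus the
#'   per-loop mean errors as a `loop_means` attribute.
#' @export
screenProbe <- function(m, candidate, target, cfg = screenConfig()) {
  out <- screenCore(m, candidate, target, cfg)
  structure(out$scores, loop_means = out$loopMeans[1, ])
}

#' Screen every probe of a matrix against a target
#'
#' Runs [screenProbe()] for all probes (including the target itself, whose
#' rank-1 self-hit is the method's internal validation) and returns them
#' ranked by ascending mean test RMS error, ties broken lexicographically by
#' probe ID.
#'
#' @param m an [ExpressionMatrix-class] with at least 2 probes.
#' @param target probe ID of the prediction target.
#' @param cfg a [ScreenConfig-class].
#' @param ann optional probe annotation used to fill the `gene_symbol`
#'   column (see [readProbeAnnotation()]).
#' @return A [RankedList-class].
#' @export
screenAll <- function(m, target, cfg = screenConfig(), ann = NULL) {
  if (nrow(m) < 2) stop("need at least 2 probes to screen")
  out <- screenCore(m, probeIds(m), target, cfg, ann)
  ord <- order(out$scores$mean_test_rms, out$scores$probe_id,
               method = "radix")
  scores <- out$scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  scores <- scores[, c("rank", setdiff(names(scores), "rank"))]
  row.names(scores) <- NULL
  rankedList(target = target, scores = scores,
             loopMeans = out$loopMeans[ord, , drop = FALSE],
             fingerprint = screenFingerprint(cfg, target))
}

#' Select the head of a ranking
#'
#' First `topN` entries of the ranked list, optionally dropping entries at or
#' above an error ceiling (the published analysis keeps the top 100 probes,
#' all below RMS error 0.12).
#'
#' @param r a [RankedList-class].
#' @param topN maximum number of entries (clamped to the list length).
#' @param errorCeiling optional; entries with `mean_test_rms >= errorCeiling`
#'   are dropped.
#' @return A [RankedList-class] prefix (ranks preserved).
#' @export
selectTop <- function(r, topN = 100, errorCeiling = NULL) {
  stopifnot(topN >= 1)
  keep <- seq_len(min(topN, length(r)))
  if (!is.null(errorCeiling))
    keep <- keep[r@scores$mean_test_rms[keep] < errorCeiling]
  rankedList(target = r@target,
             scores = r@scores[keep, , drop = FALSE],
             loopMeans = r@loopMeans[keep, , drop = FALSE],
             fingerprint = r@fingerprint)
}

#' Error-versus-rank table of a ranking
#'
#' The table behind the predictive-error distribution plot: one row per
#' ranked probe, in ranking order (no re-sorting).
#'
#' @param r a [RankedList-class].
#' @return data.frame with columns `rank`, `probe_id`, `mean_test_rms`.
#' @export
errorRankTable <- function(r) {
  r@scores[, c("rank", "probe_id", "mean_test_rms")]
}

#' Write screening outputs as tab-delimited files
#'
#' Writes one file per loop (`loop1.tsv`, ..., each ranked by that loop's
#' mean test error) plus the averaged ranking (`ranking.tsv`, the order of
#' the [RankedList-class] itself), with columns rank, probe_id, gene_symbol,
#' mean_test_rms, median_train_acc, n_models.
#'
#' @param r a [RankedList-class] produced by [screenAll()].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
writeScreenOutputs <- function(r, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- r@scores
  paths <- character(0)
  for (l in seq_len(ncol(r@loopMeans))) {
    lm <- r@loopMeans[, l]
    ord <- order(lm, s$probe_id, method = "radix")
    df <- data.frame(rank = seq_along(ord), probe_id = s$probe_id[ord],
                     gene_symbol = s$gene_symbol[ord],
                     mean_test_rms = unname(lm[ord]),
                     median_train_acc = s$median_train_acc[ord],
                     n_models = s$n_models[ord] %/% ncol(r@loopMeans),
                     stringsAsFactors = FALSE)
    p <- file.path(dir, sprintf("loop%d.tsv", l))
    fwrite(df, p, sep = "\t", quote = FALSE)
    paths <- c(paths, p)
  }
  avg <- s[, c("rank", "probe_id", "gene_symbol", "mean_test_rms",
               "median_train_acc", "n_models")]
  p <- file.path(dir, "ranking.tsv")
  fwrite(avg, p, sep = "\t", quote = FALSE)
  invisible(c(paths, p))
}
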