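#' @include AllClasses.R AllGenerics.R data_io.R
NULL

# run code under a fixed seed without disturbing the caller's RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic hub-partner expression dataset
#'
#' Draws a standard-normal hub latent factor `h` per sample; each partner
#' probe with planted correlation `rho` is `rho * h + sqrt(1 - rho^2) * e`
#' with `e` standard normal, so `rho` is exactly the population correlation
#' with the hub before the intensity map. Noise probes are independent
#' standard normal. All probes are then mapped to intensity units
#' (`offset + scale * z`), measurement noise of sd `noiseSd` is added, and
#' values are clamped at the intensity floor. Identical seeds give
#' bit-identical output.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements
#'   \describe{
#'     \item{matrix}{the [ExpressionMatrix-class] (platform `"synthetic"`),
#'       or, when `spec@splitTwoPlatforms` is `TRUE`, a list of two matrices
#'       `a`/`b` (platforms `"synthetic-A"`/`"synthetic-B"`) partitioning the
#'       probe rows over the same samples, such that
#'       `mergePlatforms(a, b)` reconstructs the single-matrix layout.}
#'     \item{metadata}{data.frame with `sample_id` and `er_status`
#'       (all `positive` unless the spec requests a mixed cohort).}
#'     \item{truth}{a [SyntheticTruth-class] recording hub, partner and
#'       noise identities.}
#'   }
#' @examples
#' spec <- syntheticSpec(nSamples = 50, partners = c(P1_at = 0.8), nNoise = 10)
#' d <- generateSynthetic(spec)
#' d$matrix
#' @export
generateSynthetic <- function(spec) {
  methods::validObject(spec)
  n <- spec@nSamples
  sampleIds <- sprintf("S%04d", seq_len(n))
  noiseIds <- if (spec@nNoise > 0)
    sprintf("NOISE_%04d_at", seq_len(spec@nNoise)) else character(0)
  ids <- c(spec@hubId, names(spec@partners), noiseIds)
  if (anyDuplicated(ids)) stop("probe IDs must be unique")

  withSeed(spec@seed, {
    h <- stats::rnorm(n)
    z <- matrix(NA_real_, length(ids), n, dimnames = list(ids, sampleIds))
    z[1, ] <- h
    for (k in seq_along(spec@partners)) {
      rho <- spec@partners[[k]]
      z[1 + k, ] <- rho * h + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    if (spec@nNoise > 0)
      z[1 + length(spec@partners) + seq_len(spec@nNoise), ] <-
        matrix(stats::rnorm(spec@nNoise * n), spec@nNoise, n)
    vals <- spec@intensityOffset + spec@intensityScale * z
    if (spec@noiseSd > 0)
      vals <- vals + matrix(stats::rnorm(length(ids) * n, sd = spec@noiseSd),
                            length(ids), n)
    vals[vals < spec@intensityFloor] <- spec@intensityFloor

    er <- rep("positive", n)
    nNeg <- floor(spec@erNegativeFraction * n + 0.5)
    nUnk <- floor(spec@erUnknownFraction * n + 0.5)
    if (nNeg + nUnk > 0) {
      flagged <- sample.int(n, nNeg + nUnk)
      er[flagged[seq_len(nNeg)]] <- "negative"
      if (nUnk > 0) er[flagged[nNeg + seq_len(nUnk)]] <- "unknown"
    }

    truth <- methods::new("SyntheticTruth", hubId = spec@hubId,
                          partners = spec@partners, noiseIds = noiseIds)
    metadata <- data.frame(sample_id = sampleIds, er_status = er,
                           stringsAsFactors = FALSE)

    mat <- if (spec@splitTwoPlatforms) {
      half <- ceiling(length(ids) / 2)
      list(a = ExpressionMatrix(vals[seq_len(half), , drop = FALSE],
                                platform = "synthetic-A"),
           b = ExpressionMatrix(vals[-seq_len(half), , drop = FALSE],
                                platform = "synthetic-B"))
    } else {
      ExpressionMatrix(vals, platform = "synthetic")
    }
    list(matrix = mat, metadata = metadata, truth = truth)
  })
}

#' Write a synthetic dataset in the package's exchange formats
#'
#' Writes the expression matrix (or the two platform matrices) with
#' [writeExpressionMatrix()], the metadata as CSV, and a trivial
#' probe-to-symbol annotation (each probe its own symbol, `_at` suffix
#' stripped) usable by the mapping and network stages.
#'
#' @param d result of [generateSynthetic()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSyntheticDataset <- function(d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (is(d$matrix, "ExpressionMatrix")) {
    paths["matrix"] <- file.path(dir, "matrix.tsv")
    writeExpressionMatrix(d$matrix, paths["matrix"])
  } else {
    paths["matrix_a"] <- file.path(dir, "matrix_a.tsv")
    paths["matrix_b"] <- file.path(dir, "matrix_b.tsv")
    writeExpressionMatrix(d$matrix$a, paths["matrix_a"])
    writeExpressionMatrix(d$matrix$b, paths["matrix_b"])
  }
  paths["metadata"] <- file.path(dir, "metadata.csv")
  utils::write.csv(d$metadata, paths["metadata"], row.names = FALSE,
                   quote = FALSE)
  ids <- if (is(d$matrix, "ExpressionMatrix")) probeIds(d$matrix)
         else c(probeIds(d$matrix$a), probeIds(d$matrix$b))
  ann <- data.frame(probe_id = ids, gene_symbol = sub("_at$", "", ids),
                    stringsAsFactors = FALSE)
  paths["annotation"] <- file.path(dir, "annotation.tsv")
  fwrite(ann, paths["annotation"], sep = "\t", quote = FALSE)
  invisible(paths)
}
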