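#' @include AllClasses.R AllGenerics.R data_io.R synthetic.R screen.R network.R
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @import ggplot2
NULL

utils::globalVariables(c("rank", "mean_test_rms"))

pipelineDefaults <- function() {
  list(
    seed = 1L,
    screen = list(n_loops = 5, n_resamples_per_loop = 10, top_n = 100,
                  learning_rate = 0.1, momentum = 0.5, max_epochs = 300,
                  patience = 10, min_delta = 2e-4, init_range = 0.5,
                  scale_on = "train", bootstrap = FALSE,
                  split = list(train = 0.6, test = 0.2, validation = 0.2)),
    growth = list(top_k = 10, top_n = 100, depth = 2, membership = "top_n"),
    report = list(cutoff_rank = 100, error_ceiling = 0.12))
}

mergeConfig <- function(defaults, user) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(user[[k]]) && is.list(defaults[[k]]))
      mergeConfig(defaults[[k]], user[[k]]) else user[[k]]
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' YAML with top-level keys `seed`, `output_dir`, `paths` (elements `matrix`,
#' optional `matrix_b`, optional `metadata`, optional `annotation`),
#' `synthetic` (alternative to `paths`: arguments of [syntheticSpec()] in
#' snake_case plus `n_partners`/`rho_range` shorthand), `screen`, `growth`
#' (requires `seed_probe`), `report`. Omitted screening/growth keys take the
#' package defaults.
#'
#' @param path path to the YAML file.
#' @return Configuration list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  mergeConfig(pipelineDefaults(), read_yaml(path))
}

configToScreenConfig <- function(cfg) {
  s <- cfg$screen
  screenConfig(
    train = trainConfig(learningRate = s$learning_rate,
                        momentum = s$momentum, maxEpochs = s$max_epochs,
                        patience = s$patience, minDelta = s$min_delta,
                        initRange = s$init_range),
    nLoops = s$n_loops, nResamplesPerLoop = s$n_resamples_per_loop,
    split = splitSpec(s$split$train, s$split$test, s$split$validation),
    topN = s$top_n, seed = cfg$seed, scaleOn = s$scale_on,
    bootstrap = isTRUE(s$bootstrap))
}

configToSyntheticSpec <- function(cfg) {
  s <- cfg$synthetic
  partners <- if (!is.null(s$partners)) unlist(s$partners)
  else if (!is.null(s$n_partners)) {
    rng <- if (!is.null(s$rho_range)) as.numeric(unlist(s$rho_range))
           else c(0.5, 0.9)
    stats::setNames(seq(rng[1], rng[2], length.out = s$n_partners),
                    sprintf("PARTNER_%03d_at", seq_len(s$n_partners)))
  } else numeric(0)
  syntheticSpec(
    nSamples = s$n_samples %||% 200,
    hubId = s$hub_id %||% "HUB_0001_at",
    partners = partners,
    nNoise = s$n_noise %||% 100,
    noiseSd = s$noise_sd %||% 20,
    intensityOffset = s$intensity_offset %||% 500,
    intensityScale = s$intensity_scale %||% 120,
    splitTwoPlatforms = isTRUE(s$split_two_platforms),
    erNegativeFraction = s$er_negative_fraction %||% 0,
    erUnknownFraction = s$er_unknown_fraction %||% 0,
    seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full screening and network-growth pipeline
#'
#' Executes ingest (or synthetic generation) -> optional two-platform merge
#' -> ER-positive filter -> whole-matrix screening -> ranking-head selection
#' -> recursive network growth -> cross-run frequency table -> exports, and
#' writes a JSON manifest with the configuration fingerprint, seed and md5
#' checksum of every tabular output. Identical configuration and seed give
#' byte-identical outputs.
#'
#' Outputs written to `output_dir`: `matrix.tsv`/`metadata.csv`/
#' `annotation.tsv` (synthetic mode), `screen/loop*.tsv`,
#' `screen/ranking.tsv`, `error_distribution.tsv`, `network.sif`,
#' `network_edges.tsv`, `network.graphml`, `frequency_table.tsv`,
#' `manifest.json`.
#'
#' @param config configuration list (see [readPipelineConfig()]) or path to
#'   a YAML configuration file.
#' @param outputDir output directory; overrides `config$output_dir`.
#' @return The manifest, invisibly (list with `fingerprint`, `seed`,
#'   `stages`, `checksums`, `versions`).
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  else config <- mergeConfig(pipelineDefaults(), config)
  outDir <- outputDir %||% config$output_dir
  if (is.null(outDir)) stop("output_dir missing from configuration")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sizes <- list()

  ann <- NULL
  if (!is.null(config$synthetic)) {
    d <- stage("simulate", {
      spec <- configToSyntheticSpec(config)
      dd <- generateSynthetic(spec)
      writeSyntheticDataset(dd, outDir)
      dd
    })
    m <- if (is(d$matrix, "ExpressionMatrix")) d$matrix
         else stage("merge", mergePlatforms(d$matrix$a, d$matrix$b))
    meta <- d$metadata
    ann <- data.frame(probe_id = probeIds(m),
                      gene_symbol = sub("_at$", "", probeIds(m)),
                      stringsAsFactors = FALSE)
    seedProbe <- config$growth$seed_probe %||% d$truth@hubId
  } else {
    p <- config$paths
    if (is.null(p$matrix)) stop("pipeline stage 'ingest' failed: no input ",
                                "matrix configured")
    m <- stage("ingest", readExpressionMatrix(p$matrix,
                                              p$platform %||% "A"))
    if (!is.null(p$matrix_b)) {
      b <- stage("ingest", readExpressionMatrix(p$matrix_b,
                                                p$platform_b %||% "B"))
      m <- stage("merge", mergePlatforms(m, b))
    }
    meta <- if (!is.null(p$metadata))
      stage("ingest", readSampleMetadata(p$metadata)) else NULL
    ann <- if (!is.null(p$annotation))
      stage("ingest", readProbeAnnotation(p$annotation)) else NULL
    seedProbe <- config$growth$seed_probe
    if (is.null(seedProbe))
      stop("pipeline stage 'screen' failed: growth$seed_probe missing")
  }
  sizes$matrix <- dim(m)

  if (!is.null(meta)) {
    m <- stage("er_filter", filterERPositive(m, meta))
    sizes$er_filtered <- dim(m)
  }

  scr <- configToScreenConfig(config)
  r1 <- stage("screen", screenAll(m, seedProbe, scr, ann))
  screenDir <- file.path(outDir, "screen")
  writeScreenOutputs(r1, screenDir)

  rep <- config$report
  top <- stage("select_top",
               selectTop(r1, topN = config$growth$top_n,
                         errorCeiling = rep$error_ceiling))
  fwrite(errorRankTable(r1), file.path(outDir, "error_distribution.tsv"),
         sep = "\t", quote = FALSE)

  gcfg <- growthConfig(seedProbe = seedProbe, topK = config$growth$top_k,
                       topN = config$growth$top_n,
                       depth = config$growth$depth, screen = scr,
                       membership = config$growth$membership)
  net <- stage("grow", growNetwork(m, gcfg, ann, layer1 = r1))
  exportNetwork(net, file.path(outDir, "network.sif"), "sif")
  exportNetwork(net, file.path(outDir, "network_edges.tsv"), "tsv")
  exportNetwork(net, file.path(outDir, "network.graphml"), "graphml")
  fwrite(networkNodes(net), file.path(outDir, "network_nodes.tsv"),
         sep = "\t", quote = FALSE)

  freq <- stage("frequency_table",
                frequencyTable(networkRuns(net), ann,
                               topN = config$growth$top_n))
  fwrite(freq, file.path(outDir, "frequency_table.tsv"), sep = "\t",
         quote = FALSE)

  outputs <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  checksums <- as.list(tools::md5sum(sort(outputs)))
  names(checksums) <- substring(names(checksums), nchar(outDir) + 2)
  manifest <- list(
    fingerprint = unclass(cpp_hash_string(paste(
      deparse(config[setdiff(names(config), "output_dir")]),
      collapse = ""))),
    seed = config$seed,
    seed_probe = seedProbe,
    sizes = sizes,
    n_selected = length(top),
    n_edges = nrow(networkEdges(net)),
    checksums = checksums,
    versions = list(
      package = as.character(utils::packageVersion("annScreen")),
      r = as.character(getRversion())))
  write_json(manifest, file.path(outDir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf(
    "pipeline complete: %d probes screened, %d selected, %d network edges",
    length(r1), length(top), nrow(networkEdges(net))))
  invisible(manifest)
}

#' Plot the predictive-error distribution of a ranking
#'
#' Rank-versus-mean-test-RMS curve with a dashed vertical marker at the
#' selection cutoff rank and a horizontal line at the error ceiling; the
#' `zoom` variant restricts the plot to the first `cutoffRank` entries. The
#' plotted order is the ranking order (no re-sorting).
#'
#' @param r a [RankedList-class].
#' @param cutoffRank rank marker (default 100).
#' @param ceiling error-ceiling line (default 0.12).
#' @param zoom if `TRUE`, show only the first `cutoffRank` entries.
#' @param tablePath optional path; the underlying table is written there as
#'   TSV.
#' @return A ggplot object; the underlying table is attached as attribute
#'   `"table"`.
#' @export
plotErrorDistribution <- function(r, cutoffRank = 100, ceiling = 0.12,
                                  zoom = FALSE, tablePath = NULL) {
  tab <- errorRankTable(r)
  if (!is.null(tablePath)) fwrite(tab, tablePath, sep = "\t", quote = FALSE)
  shown <- if (zoom) tab[tab$rank <= cutoffRank, , drop = FALSE] else tab
  p <- ggplot(shown, aes(x = rank, y = mean_test_rms)) +
    geom_line(colour = "steelblue") +
    geom_point(size = 0.4) +
    geom_hline(yintercept = ceiling, colour = "blue", linewidth = 0.3) +
    geom_vline(xintercept = cutoffRank, linetype = "dashed") +
    labs(x = "Rank", y = "Mean test RMS error",
         title = sprintf("Predictive error distribution (target %s)",
                         targetProbe(r))) +
    theme_minimal()
  attr(p, "table") <- tab
  p
}
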