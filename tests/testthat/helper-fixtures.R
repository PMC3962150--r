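# fixtures are built in code; nothing is stored on disk

# small random expression matrix with plausible intensities
randomMatrix <- function(nProbes, nSamples, seed = 1, prefix = "P",
                         platform = "test") {
  set.seed(seed)
  vals <- matrix(rnorm(nProbes * nSamples, 500, 120), nProbes, nSamples,
                 dimnames = list(sprintf("%s%04d_at", prefix, seq_len(nProbes)),
                                 sprintf("S%03d", seq_len(nSamples))))
  ExpressionMatrix(vals, platform = platform)
}

# the study-shaped synthetic design: hub + planted partners + noise probes
hubSpec <- function(seed, nSamples = 200, rhos = seq(0.5, 0.9, length.out = 10),
                    nNoise = 289, noiseSd = 20) {
  syntheticSpec(nSamples = nSamples,
                partners = stats::setNames(rhos, sprintf("PARTNER_%03d_at",
                                                         seq_along(rhos))),
                nNoise = nNoise, noiseSd = noiseSd, seed = seed)
}

# light screening configuration for unit tests
fastScreenConfig <- function(seed = 1, ...) {
  screenConfig(train = trainConfig(maxEpochs = 80, patience = 8,
                                   minDelta = 2e-4),
               nLoops = 2, nResamplesPerLoop = 2, seed = seed, ...)
}

# ranked list with prescribed probe order (for injection into network code)
injectRanking <- function(target, probes, symbols = probes) {
  n <- length(probes)
  rankedList(target = target,
             scores = data.frame(
               rank = seq_len(n), probe_id = probes, gene_symbol = symbols,
               mean_test_rms = seq(0.01, 0.2, length.out = n),
               median_train_acc = 90, n_models = 1, degenerate = FALSE,
               stringsAsFactors = FALSE))
}

# independent brute-force interconnection recount over stored lists
bruteForceCounts <- function(runs, topN) {
  genes <- names(runs)
  vapply(genes, function(g) {
    sum(vapply(setdiff(genes, g), function(other) {
      s <- probeScores(runs[[other]])
      head <- s[seq_len(min(topN, nrow(s))), ]
      g %in% head$gene_symbol
    }, logical(1)))
  }, integer(1))
}
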