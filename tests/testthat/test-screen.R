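test_that("MCCV split sizes follow the 60/20/20 rounding rule", {
  set.seed(1)
  expect_identical(lengths(mccvSplit(211)), c(train = 127L, test = 42L,
                                              validation = 42L))
  expect_identical(unname(lengths(mccvSplit(10))), c(6L, 2L, 2L))
  expect_identical(unname(lengths(mccvSplit(11))), c(7L, 2L, 2L))
  expect_error(mccvSplit(4), "n >= 5")
})

test_that("MCCV splits partition the sample set", {
  set.seed(7)
  for (n in c(5, 9, 23, 50, 211)) {
    s <- mccvSplit(n)
    all_idx <- c(s$train, s$test, s$validation)
    expect_equal(sort(all_idx), seq_len(n))   # exhaustive and disjoint
  }
})

test_that("single-probe scores are deterministic and match whole screens", {
  d <- generateSynthetic(hubSpec(seed = 21, nSamples = 60, nNoise = 10))
  cfg <- fastScreenConfig(seed = 21)
  s1 <- suppressMessages(screenProbe(d$matrix, "PARTNER_003_at",
                                     "HUB_0001_at", cfg))
  s2 <- suppressMessages(screenProbe(d$matrix, "PARTNER_003_at",
                                     "HUB_0001_at", cfg))
  expect_identical(s1, s2)

  r <- suppressMessages(screenAll(d$matrix, "HUB_0001_at", cfg))
  row <- probeScores(r)[probeScores(r)$probe_id == "PARTNER_003_at", ]
  expect_identical(row$mean_test_rms, s1$mean_test_rms)
  expect_identical(row$median_train_acc, s1$median_train_acc)
})

test_that("the target predicts itself best and noise scores at baseline", {
  d <- generateSynthetic(hubSpec(seed = 12, nSamples = 200, nNoise = 25,
                                 noiseSd = 0))
  longCfg <- screenConfig(train = trainConfig(maxEpochs = 300, patience = 50,
                                              minDelta = 1e-4),
                          nResamplesPerLoop = 5, seed = 12)
  self <- suppressMessages(screenProbe(d$matrix, "HUB_0001_at",
                                       "HUB_0001_at", longCfg))
  expect_lt(self$mean_test_rms, 0.02)

  # a pure-noise candidate scores near the constant-predictor baseline
  noise <- suppressMessages(screenProbe(d$matrix, "NOISE_0001_at",
                                        "HUB_0001_at", longCfg))
  y <- exprValues(d$matrix)["HUB_0001_at", ]
  baseline <- sd(0.1 + 0.8 * (y - min(y)) / (max(y) - min(y)))
  expect_lt(abs(noise$mean_test_rms - baseline), 0.05)
  expect_gt(noise$mean_test_rms, self$mean_test_rms)
})

test_that("whole-matrix rankings are complete, ordered and deterministic", {
  d <- generateSynthetic(hubSpec(seed = 31, nSamples = 60, nNoise = 20))
  cfg <- fastScreenConfig(seed = 31)
  r <- suppressMessages(screenAll(d$matrix, "HUB_0001_at", cfg))
  s <- probeScores(r)
  expect_setequal(s$probe_id, probeIds(d$matrix))  # permutation of probes
  expect_false(is.unsorted(s$mean_test_rms))
  expect_identical(s$rank, seq_len(nrow(s)))
  expect_equal(unique(s$n_models), 4L)

  r2 <- suppressMessages(screenAll(d$matrix, "HUB_0001_at", cfg))
  expect_identical(probeScores(r2), s)

  # smallest screening
  two <- ExpressionMatrix(exprValues(d$matrix)[1:2, ])
  expect_length(suppressMessages(screenAll(two, "HUB_0001_at", cfg)), 2L)

  expect_error(suppressMessages(screenAll(d$matrix, "ABSENT_at", cfg)),
               "ABSENT_at")
})

test_that("a constant candidate is flagged degenerate, not an error", {
  d <- generateSynthetic(hubSpec(seed = 5, nSamples = 40, nNoise = 5))
  v <- exprValues(d$matrix)
  v["NOISE_0001_at", ] <- 500
  m <- ExpressionMatrix(v)
  sp <- suppressMessages(screenProbe(m, "NOISE_0001_at", "HUB_0001_at",
                                     fastScreenConfig(seed = 5)))
  expect_true(sp$degenerate)
  expect_true(is.finite(sp$mean_test_rms))
})

test_that("selectTop clamps, filters on the error ceiling, and keeps order", {
  probes <- sprintf("P%03d_at", 1:150)
  r <- injectRanking("P001_at", probes)
  r@scores$mean_test_rms <- seq(0.05, 0.20, length.out = 150)

  expect_length(selectTop(r, topN = 100), 100L)
  expect_length(selectTop(r, topN = 1000), 150L)

  # brute-force recount of the ceiling rule
  ceiling <- 0.12
  expected <- sum(r@scores$mean_test_rms[1:100] < ceiling)
  top <- selectTop(r, topN = 100, errorCeiling = ceiling)
  expect_length(top, expected)
  expect_true(all(probeScores(top)$mean_test_rms < ceiling))
  expect_identical(probeScores(top)$rank, seq_len(expected))

  tab <- errorRankTable(top)
  expect_identical(tab$rank, seq_len(expected))
})

test_that("ANN ranking agrees broadly with the correlation oracle", {
  spec <- syntheticSpec(
    nSamples = 200,
    partners = stats::setNames(seq(0.30, 0.90, length.out = 20),
                               sprintf("PARTNER_%03d_at", 1:20)),
    nNoise = 79, noiseSd = 0, seed = 17)
  d <- generateSynthetic(spec)
  cfg <- screenConfig(nResamplesPerLoop = 5, seed = 17)
  r <- suppressMessages(screenAll(d$matrix, "HUB_0001_at", cfg))
  annTop <- probeScores(r)$probe_id[1:20]

  v <- exprValues(d$matrix)
  rho <- abs(cor(t(v), v["HUB_0001_at", ]))[, 1]
  corTop <- names(sort(rho, decreasing = TRUE))[1:20]
  expect_gte(length(intersect(annTop, corTop)), 15)
})

test_that("screening output files mirror the ranked list", {
  d <- generateSynthetic(hubSpec(seed = 9, nSamples = 50, nNoise = 10))
  cfg <- fastScreenConfig(seed = 9)
  r <- suppressMessages(screenAll(d$matrix, "HUB_0001_at", cfg))
  dir <- withr::local_tempdir()
  paths <- writeScreenOutputs(r, dir)
  expect_length(paths, cfg@nLoops + 1L)

  avg <- read.delim(file.path(dir, "ranking.tsv"))
  expect_identical(avg$probe_id, probeScores(r)$probe_id)
  expect_equal(avg$mean_test_rms, probeScores(r)$mean_test_rms,
               tolerance = 1e-9)

  loop1 <- read.delim(file.path(dir, "loop1.tsv"))
  expect_setequal(loop1$probe_id, probeScores(r)$probe_id)
  expect_false(is.unsorted(loop1$mean_test_rms))
})
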