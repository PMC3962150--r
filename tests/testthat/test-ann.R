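test_that("sigmoid matches its closed form and saturates safely", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 0.7310585786, tolerance = 1e-9)
  expect_equal(sigmoid(-1), 1 - sigmoid(1), tolerance = 1e-12)
  expect_no_warning({
    hi <- sigmoid(1000)
    lo <- sigmoid(-1000)
  })
  expect_true(hi > 0 && hi <= 1)
  expect_true(lo >= 0 && lo < 1)
})

test_that("weight initialisation is seeded, bounded and centred", {
  cfg <- trainConfig(seed = 42)
  expect_identical(initNetwork(1, 2, cfg), initNetwork(1, 2, cfg))

  zero <- initNetwork(1, 2, trainConfig(initRange = 0))
  expect_true(all(c(zero@wIn, zero@bHidden, zero@wOut, zero@bOut) == 0))

  big <- initNetwork(2, 2500, trainConfig(seed = 1))  # > 10,000 draws
  draws <- c(big@wIn, big@bHidden, big@wOut, big@bOut)
  expect_true(all(abs(draws) <= 0.5))
  expect_lt(abs(mean(draws)), 0.02)
})

test_that("forward pass matches independent hand computation", {
  # all-zero network outputs 0.5 for any input
  zero <- networkWeights(c(0, 0), c(0, 0), c(0, 0), 0)
  expect_identical(annForward(zero, 0.3), 0.5)
  expect_identical(annForward(zero, -5), 0.5)

  # pencil-and-paper 1-2-1 case
  net <- networkWeights(c(1, -1), c(0, 0), c(1, 1), 0)
  hand <- 1 / (1 + exp(-(1 / (1 + exp(-0.5)) + 1 / (1 + exp(0.5)))))
  expect_equal(annForward(net, 0.5), hand, tolerance = 1e-12)

  # asymmetric case, still by explicit arithmetic
  net2 <- networkWeights(c(0.3, -0.7), c(0.1, -0.2), c(0.8, 0.5), -0.1)
  h1 <- 1 / (1 + exp(-(0.3 * 0.4 + 0.1)))
  h2 <- 1 / (1 + exp(-(-0.7 * 0.4 - 0.2)))
  expect_equal(annForward(net2, 0.4),
               1 / (1 + exp(-(0.8 * h1 + 0.5 * h2 - 0.1))),
               tolerance = 1e-12)

  expect_error(annForward(net, c(1, 2)), "expects 1")

  # output strictly inside (0,1) for arbitrary nets
  set.seed(1)
  for (i in 1:20) {
    n <- networkWeights(matrix(rnorm(6, sd = 3), 2, 3), rnorm(2, sd = 3),
                        rnorm(2, sd = 3), rnorm(1, sd = 3))
    o <- annForward(n, rnorm(3, sd = 5))
    expect_true(o > 0 && o < 1)
  }
})

test_that("backprop gradient agrees with central finite differences", {
  relErr <- function(seed) {
    set.seed(seed)
    I <- sample(1:3, 1); H <- sample(1:3, 1)
    net <- networkWeights(matrix(runif(H * I, -1, 1), H, I),
                          runif(H, -1, 1), runif(H, -1, 1), runif(1, -1, 1))
    x <- runif(I); y <- runif(1, 0.1, 0.9)
    g <- annGradient(net, x, y)
    gv <- c(g$wIn, g$bHidden, g$wOut, g$bOut)
    w0 <- c(net@wIn, net@bHidden, net@wOut, net@bOut)
    loss <- function(w) {
      n2 <- networkWeights(matrix(w[1:(H * I)], H, I), w[H * I + 1:H],
                           w[H * I + H + 1:H], w[H * I + 2 * H + 1])
      0.5 * (annForward(n2, x) - y)^2   # independent R forward pass
    }
    h <- 1e-5
    fd <- vapply(seq_along(w0), function(i) {
      wp <- w0; wm <- w0
      wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
      (loss(wp) - loss(wm)) / (2 * h)
    }, numeric(1))
    max(abs(gv - fd)) / max(abs(fd))
  }
  expect_lt(max(vapply(1:25, relErr, numeric(1))), 1e-6)
})

test_that("training honours epoch limits and early-stopping bookkeeping", {
  set.seed(9)
  x <- runif(200)
  ys <- 0.1 + 0.8 * x
  tr <- 1:120; va <- 121:160
  net <- initNetwork(1, 2, trainConfig(seed = 2))

  # no-op training
  fit0 <- trainNetwork(net, x[tr], ys[tr], x[va], ys[va],
                       trainConfig(maxEpochs = 0))
  expect_identical(fit0@weights, net)
  expect_equal(nrow(fit0@history), 0L)

  # learnability on a noiseless monotone target
  cfg <- trainConfig(maxEpochs = 500, patience = 500, seed = 2)
  fit <- trainNetwork(net, x[tr], ys[tr], x[va], ys[va], cfg)
  expect_lt(min(fit@history$val_rms), 0.05)

  # returned weights attain the minimum recorded validation RMS
  expect_equal(fit@history$val_rms[fit@bestEpoch], min(fit@history$val_rms))
  pred <- annForward(fit@weights, matrix(x[va], ncol = 1))
  expect_equal(rmsError(pred, ys[va]), min(fit@history$val_rms),
               tolerance = 1e-12)

  # determinism
  fit2 <- trainNetwork(net, x[tr], ys[tr], x[va], ys[va], cfg)
  expect_identical(fit@weights, fit2@weights)
  expect_identical(fit@history, fit2@history)

  expect_error(trainNetwork(net, numeric(0), numeric(0), x[va], ys[va], cfg),
               "empty training set")
  expect_error(trainNetwork(net, x[tr], ys[tr] + 1, x[va], ys[va], cfg),
               "\\[0, 1\\]")
})

test_that("training histories export as tab-delimited epoch logs", {
  set.seed(3)
  x <- runif(40); ys <- 0.1 + 0.8 * x
  fit <- trainNetwork(initNetwork(1, 2, trainConfig(seed = 1)),
                      x[1:30], ys[1:30], x[31:40], ys[31:40],
                      trainConfig(maxEpochs = 20, patience = 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrainingHistory(fit, path)
  log <- read.delim(path)
  expect_identical(names(log), c("epoch", "train_rms", "val_rms"))
  expect_identical(nrow(log), nrow(fit@history))
  expect_equal(log$val_rms, fit@history$val_rms, tolerance = 1e-9)
})

test_that("zero momentum reduces to plain per-pattern gradient descent", {
  # independent plain-GD reference, coded directly from the update equations
  plainGD <- function(net, x, ys, lr, epochs) {
    wIn <- net@wIn; bH <- net@bHidden; wO <- net@wOut; bO <- net@bOut
    for (e in seq_len(epochs)) for (p in seq_along(x)) {
      a <- 1 / (1 + exp(-(wIn[, 1] * x[p] + bH)))
      o <- 1 / (1 + exp(-(sum(wO * a) + bO)))
      dO <- (o - ys[p]) * o * (1 - o)
      dH <- dO * wO * a * (1 - a)
      wIn[, 1] <- wIn[, 1] - lr * dH * x[p]; bH <- bH - lr * dH
      wO <- wO - lr * dO * a; bO <- bO - lr * dO
    }
    networkWeights(wIn, bH, wO, bO)
  }
  set.seed(4)
  x <- runif(30); ys <- 0.1 + 0.8 * x
  net <- initNetwork(1, 2, trainConfig(seed = 8))
  fit <- trainNetwork(net, x, ys, x, ys,
                      trainConfig(momentum = 0, maxEpochs = 2, patience = 10))
  expect_equal(fit@finalWeights, plainGD(net, x, ys, 0.1, 2),
               tolerance = 1e-12)
})

test_that("error metrics match hand arithmetic and validate inputs", {
  expect_identical(rmsError(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_identical(rmsError(c(0.5, 0.5), c(0, 1)), 0.5)
  expect_error(rmsError(1, c(1, 2)), "lengths differ")
  set.seed(2)
  for (i in 1:10) {
    p <- runif(7); t <- runif(7)
    expect_true(rmsError(p, t) >= 0 && rmsError(p, t) <= 1)
  }

  expect_identical(classificationAccuracy(c(0.9, 0.1), c(1, 0)), 100)
  expect_identical(classificationAccuracy(c(0.9, 0.2, 0.6, 0.7),
                                          c(1, 0, 0, 1)), 75)
  expect_identical(classificationAccuracy(0.5, 1), 100)  # tie -> class 1
  expect_identical(classificationAccuracy(c(1/3, 2/3, 2/3), c(0, 1, 0)),
                   66.7)
  expect_error(classificationAccuracy(1, c(1, 0)), "lengths differ")
  expect_error(classificationAccuracy(c(0.1, 0.2), c(1, 2)), "binary")
})
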