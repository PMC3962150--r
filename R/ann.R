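#' @include AllClasses.R AllGenerics.R
#' @useDynLib annScreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Logistic sigmoid transfer function
#'
#' `1 / (1 + exp(-x))`, numerically safe for large `|x|` (saturates to 0/1
#' without overflow).
#'
#' @param x numeric vector.
#' @return values in `(0, 1)` (attaining the bounds only in floating-point
#'   saturation).
#' @examples
#' sigmoid(0)    # 0.5
#' sigmoid(1000) # 1, no overflow
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct network weights explicitly
#'
#' @param wIn numeric matrix (`nHidden` x `nInputs`) of input-to-hidden
#'   weights; a plain vector is taken as a one-input column.
#' @param bHidden hidden biases (length `nHidden`).
#' @param wOut hidden-to-output weights (length `nHidden`).
#' @param bOut output bias (scalar).
#' @return A [NetworkWeights-class].
#' @export
networkWeights <- function(wIn, bHidden, wOut, bOut) {
  if (!is.matrix(wIn)) wIn <- matrix(wIn, ncol = 1)
  storage.mode(wIn) <- "double"
  new("NetworkWeights", wIn = wIn, bHidden = as.numeric(bHidden),
      wOut = as.numeric(wOut), bOut = as.numeric(bOut))
}

#' Initialise a network with uniform random weights
#'
#' Weights and biases are drawn independently and uniformly from
#' `[-initRange, initRange]` under the configuration's seed (draw order:
#' input weights, hidden biases, output weights, output bias), so identical
#' seeds give identical networks.
#'
#' @param nInputs,nHidden layer sizes (defaults 1 and 2, the screening
#'   architecture).
#' @param cfg a [TrainConfig-class] supplying `initRange` and `seed`.
#' @return A [NetworkWeights-class].
#' @export
initNetwork <- function(nInputs = 1, nHidden = 2, cfg = trainConfig()) {
  stopifnot(nInputs >= 1, nHidden >= 1)
  withSeed(cfg@seed, {
    r <- cfg@initRange
    networkWeights(
      wIn = matrix(stats::runif(nHidden * nInputs, -r, r), nHidden, nInputs),
      bHidden = stats::runif(nHidden, -r, r),
      wOut = stats::runif(nHidden, -r, r),
      bOut = stats::runif(1, -r, r))
  })
}

#' Forward pass of the perceptron
#'
#' Hidden activations are `sigmoid(wIn %*% x + bHidden)`; the output is
#' `sigmoid(sum(wOut * hidden) + bOut)`. This R implementation is
#' deliberately independent of the compiled training path and serves as its
#' reference.
#'
#' @param net a [NetworkWeights-class].
#' @param x input vector of length `nInputs`, or a pattern matrix with
#'   `nInputs` columns (one prediction per row).
#' @return Prediction(s) in `(0, 1)`.
#' @export
annForward <- function(net, x) {
  I <- ncol(net@wIn)
  if (is.matrix(x)) {
    if (ncol(x) != I)
      stop("input has ", ncol(x), " columns but the network expects ", I)
    return(apply(x, 1, function(r) annForward(net, r)))
  }
  if (length(x) != I)
    stop("input has length ", length(x), " but the network expects ", I)
  hidden <- sigmoid(as.numeric(net@wIn %*% x) + net@bHidden)
  sigmoid(sum(net@wOut * hidden) + net@bOut)
}

#' Backpropagation gradient for one pattern
#'
#' Gradient of the squared error `E = 0.5 * (output - y)^2` with respect to
#' every weight and bias, computed by the compiled backpropagation pass (the
#' same code path the training loop uses).
#'
#' @param net a [NetworkWeights-class].
#' @param x input vector.
#' @param y target value.
#' @return list with components `wIn`, `bHidden`, `wOut`, `bOut` shaped like
#'   the corresponding slots.
#' @export
annGradient <- function(net, x, y) {
  if (length(x) != ncol(net@wIn))
    stop("input has length ", length(x), " but the network expects ",
         ncol(net@wIn))
  cpp_gradient(net@wIn, net@bHidden, net@wOut, net@bOut,
               as.numeric(x), as.numeric(y))
}

#' Train the perceptron with online backpropagation and momentum
#'
#' Per-epoch, per-pattern gradient descent in a fixed pattern order:
#' `delta_w(t) = -lr * dE/dw + momentum * delta_w(t-1)` on squared error.
#' After each epoch the validation RMS is evaluated; training stops at
#' `maxEpochs` or once validation RMS has not improved for `patience`
#' consecutive epochs, and the weights from the best validation epoch are
#' returned.
#'
#' @param net initial [NetworkWeights-class].
#' @param trainX,trainY training patterns (vector or matrix with one row per
#'   pattern) and targets scaled to `[0, 1]`.
#' @param valX,valY validation patterns and targets.
#' @param cfg a [TrainConfig-class].
#' @return A [TrainedNetwork-class]; with `maxEpochs = 0` the weights are
#'   unchanged and the history is empty.
#' @export
trainNetwork <- function(net, trainX, trainY, valX, valY,
                         cfg = trainConfig()) {
  toPatterns <- function(x) {
    if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  }
  trainX <- toPatterns(trainX); valX <- toPatterns(valX)
  if (nrow(trainX) == 0) stop("empty training set")
  if (nrow(trainX) != length(trainY) || nrow(valX) != length(valY))
    stop("pattern/target length mismatch")
  if (any(trainY < 0 | trainY > 1) || any(valY < 0 | valY > 1))
    stop("targets must be scaled to [0, 1]")
  if (cfg@maxEpochs == 0L)
    return(new("TrainedNetwork", weights = net, finalWeights = net,
               bestEpoch = 0L,
               history = data.frame(epoch = integer(), train_rms = numeric(),
                                    val_rms = numeric())))
  fit <- cpp_train(trainX, as.numeric(trainY), valX, as.numeric(valY),
                   net@wIn, net@bHidden, net@wOut, net@bOut,
                   cfg@learningRate, cfg@momentum, cfg@maxEpochs,
                   cfg@patience, cfg@minDelta)
  asW <- function(w) networkWeights(w$wIn, w$bHidden, w$wOut, w$bOut)
  new("TrainedNetwork",
      weights = asW(fit$best), finalWeights = asW(fit$final),
      bestEpoch = as.integer(fit$best_epoch),
      history = data.frame(epoch = seq_along(fit$val_rms),
                           train_rms = fit$train_rms,
                           val_rms = fit$val_rms))
}

#' Export a training history as a tab-delimited epoch log
#'
#' One row per epoch with the training and validation RMS recorded during
#' [trainNetwork()].
#'
#' @param fit a [TrainedNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrainingHistory <- function(fit, path) {
  fwrite(fit@history, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Root-mean-squared error
#'
#' @param pred,target numeric vectors of equal length.
#' @return `sqrt(mean((pred - target)^2))`.
#' @examples
#' rmsError(c(0.5, 0.5), c(0, 1)) # 0.5
#' @export
rmsError <- function(pred, target) {
  if (length(pred) != length(target))
    stop("pred and target lengths differ (", length(pred), " vs ",
         length(target), ")")
  if (length(pred) == 0) stop("empty input")
  sqrt(mean((pred - target)^2))
}

#' Classification accuracy of thresholded predictions
#'
#' Percentage of cases where `pred >= threshold` agrees with the binary
#' target (a prediction exactly at the threshold counts as class 1), rounded
#' half-up to one decimal.
#'
#' @param pred numeric predictions.
#' @param target binary targets in `{0, 1}`.
#' @param threshold decision threshold (default 0.5).
#' @return Percentage in `[0, 100]` with one decimal.
#' @examples
#' classificationAccuracy(c(0.9, 0.2, 0.6, 0.7), c(1, 0, 0, 1)) # 75.0
#' @export
classificationAccuracy <- function(pred, target, threshold = 0.5) {
  if (length(pred) != length(target))
    stop("pred and target lengths differ (", length(pred), " vs ",
         length(target), ")")
  if (!all(target %in% c(0, 1))) stop("target must be binary 0/1")
  roundHalfUp(100 * mean((pred >= threshold) == (target == 1)), 1)
}
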