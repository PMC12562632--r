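.cppCfg <- function(graph) {
  c(graph@config, list(architecture = graph@architecture))
}

#' Build the multiscale CNN regressor
#'
#' Three parallel convolution branches at kernel scales 3/5/7 whose
#' (channels x positions) maps are combined by learnable per-channel fusion
#' weights w1, w2, w3 (initialized to 1/3, unconstrained), flattened, and
#' passed through a 128-unit ReLU layer and a linear output. For a 421-band
#' input every branch emits 128 x 53 and the flattened fused dimension is
#' 6784.
#'
#' @param cfg an \code{\link{mscnnConfig}}
#' @return an unfitted \linkS4class{PredictorGraph}
#' @export
buildMscnn <- function(cfg = mscnnConfig()) {
  stopifnot(inherits(cfg, "MSCNNConfig"))
  new("PredictorGraph", architecture = "mscnn", config = unclass(cfg))
}

#' Build the multiscale CNN-LSTM regressor
#'
#' Identical multiscale trunk to \code{\link{buildMscnn}}; the 128-unit
#' fused representation is treated as a length-1 sequence and passed through
#' a single-layer LSTM (input 128, hidden 128) whose final hidden state
#' feeds the linear output.
#'
#' @param cfg an \code{\link{mscnnConfig}}
#' @param hidden LSTM hidden dimension (default 128)
#' @return an unfitted \linkS4class{PredictorGraph}
#' @export
buildMscnnLstm <- function(cfg = mscnnConfig(), hidden = 128L) {
  stopifnot(inherits(cfg, "MSCNNConfig"))
  cfg$lstmHidden <- as.integer(hidden)
  new("PredictorGraph", architecture = "mscnn_lstm", config = unclass(cfg))
}

#' Build the 1-D ResNet18 regressor
#'
#' Stem Conv(1->64, k7, s2, p3) + batch-norm + ReLU + max-pool(k3, s2, p1),
#' then four residual groups (channels 64/128/256/512, two blocks each,
#' 3-kernels, 1-kernel projection on channel/stride change), global average
#' pooling to 512 features, and a linear output.
#'
#' @param inputLength number of spectral bands (>= 32)
#' @return an unfitted \linkS4class{PredictorGraph}
#' @export
buildResnet18 <- function(inputLength = 421L) {
  if (inputLength < 32L)
    stop("geometry error: input too short for the downsampling chain")
  L <- conv1dOutputLength(inputLength, 7L, 2L, 3L)   # stem
  L <- conv1dOutputLength(L, 3L, 2L, 1L)             # max pool
  lens <- integer(4)
  for (g in 1:4) {
    if (g > 1) L <- conv1dOutputLength(L, 3L, 2L, 1L)
    lens[g] <- L
  }
  new("PredictorGraph", architecture = "resnet18_1d",
      config = list(inputLength = as.integer(inputLength),
                    groupChannels = c(64L, 128L, 256L, 512L),
                    blocksPerGroup = 2L, groupLengths = lens,
                    featureDim = 512L))
}

#' Initialize a predictor graph
#'
#' Draws all weights with the seeded uniform fan-in scheme
#' (U(-1/sqrt(fan_in), 1/sqrt(fan_in))), sets batch-norm scales to 1 and
#' fusion weights to 1/3, and resets running statistics.
#'
#' @param graph a \linkS4class{PredictorGraph}
#' @param seed integer seed
#' @return the graph with populated parameter store
#' @export
initializeGraph <- function(graph, seed = 1L) {
  stopifnot(is(graph, "PredictorGraph"))
  r <- cpp_nn_init(graph@architecture, .cppCfg(graph), as.integer(seed))
  graph@params <- r$params
  graph@state <- r$state
  graph@fitted <- FALSE
  graph
}

#' Number of trainable parameters
#'
#' @param graph an initialized \linkS4class{PredictorGraph}
#' @return total count of trainable parameter elements
#' @export
parameterCount <- function(graph) {
  if (!length(graph@params)) graph <- initializeGraph(graph)
  sum(vapply(graph@params, length, numeric(1)))
}

#' Raw forward pass
#'
#' Runs the network on an already-standardized band matrix without applying
#' the stored standardization; intended for architecture-level checks
#' against layer-by-layer recomputation. \code{mode = "train"} uses batch
#' statistics in the normalization layers, \code{"inference"} the running
#' statistics.
#'
#' @param graph an initialized or fitted \linkS4class{PredictorGraph}
#' @param X N x B matrix
#' @param mode "inference" (default) or "train"
#' @return numeric predictions, length N
#' @export
forwardPass <- function(graph, X, mode = c("inference", "train")) {
  mode <- match.arg(mode)
  if (!length(graph@params))
    stop("contract error: graph is not initialized")
  X <- as.matrix(X)
  if (ncol(X) != graph@config$inputLength)
    stop("contract error: batch width must equal the input length")
  as.numeric(cpp_nn_forward(graph@architecture, .cppCfg(graph),
                            graph@params, graph@state, X,
                            mode == "train"))
}

#' Train a spectral deep regressor
#'
#' Adam on mean squared error over seeded mini-batch epochs. Bands are
#' standardized (zero mean, unit SD) with calibration-set statistics stored
#' in the model and re-applied at prediction time; the target is optionally
#' z-scored during optimization and always back-transformed. With early
#' stopping enabled a validation fraction is held out internally, the
#' validation loss is evaluated every epoch, and the best weights are
#' restored. Training is deterministic given the seed on a single thread.
#'
#' @param graph a \linkS4class{PredictorGraph} from one of the builders
#' @param train \linkS4class{SpectrumTable} or N x B matrix of calibration
#'   spectra
#' @param target "FI", "SSC" or "FSR" (table input) or a numeric vector
#' @param cfg a \code{\link{trainConfig}}
#' @return the fitted graph; \code{@history$train} (and \code{$val}) hold
#'   per-epoch losses
#' @export
trainRegressor <- function(graph, train, target, cfg = trainConfig()) {
  stopifnot(is(graph, "PredictorGraph"), inherits(cfg, "TrainConfig"))
  d <- .resolveXY(train, target)
  if (!nrow(d$X)) stop("contract error: empty training set")
  if (ncol(d$X) != graph@config$inputLength)
    stop("contract error: band count must equal the input length")
  def <- .archDefaults(graph@architecture)
  epochs <- if (is.null(cfg$maxIterations)) def$epochs else as.integer(cfg$maxIterations)
  es <- if (is.null(cfg$earlyStopping)) def$earlyStopping else cfg$earlyStopping
  es <- modifyList(list(enabled = FALSE, patience = 50L, valFraction = 0.1), es)

  xm <- colMeans(d$X)
  xs <- apply(d$X, 2, stats::sd); xs[xs == 0] <- 1
  Xs <- .stdApply(d$X, list(center = xm, scale = xs))
  if (cfg$standardizeY) {
    ym <- mean(d$y); ys <- stats::sd(d$y); if (is.na(ys) || ys == 0) ys <- 1
  } else { ym <- 0; ys <- 1 }

  if (!length(graph@params))
    graph <- initializeGraph(graph, seed = cfg$seed)

  r <- cpp_nn_train(graph@architecture, .cppCfg(graph),
                    graph@params, graph@state, Xs, (d$y - ym) / ys,
                    list(seed = cfg$seed, epochs = epochs,
                         batchSize = cfg$batchSize, lr = cfg$learningRate,
                         earlyStopping = isTRUE(es$enabled),
                         patience = as.integer(es$patience),
                         valFraction = es$valFraction))
  if (!all(is.finite(r$history$train)))
    stop("divergence error: NaN loss at iteration ",
         which(!is.finite(r$history$train))[1])
  graph@params <- r$params
  graph@state <- r$state
  graph@standardization <- list(xCenter = xm, xScale = xs,
                                yCenter = ym, yScale = ys)
  graph@history <- r$history
  graph@fitted <- TRUE
  graph
}

#' Predict quality values from spectra
#'
#' Applies the stored band standardization, runs the network in inference
#' mode, and returns predictions in original target units. Refuses unfitted
#' graphs. Predictions are pointwise: batch composition does not affect the
#' values.
#'
#' @param object a fitted \linkS4class{PredictorGraph}
#' @param newdata \linkS4class{SpectrumTable} or N x B matrix
#' @param ... unused
#' @return numeric predictions, length N
#' @export
setMethod("predict", "PredictorGraph", function(object, newdata, ...) {
  if (!object@fitted) stop("contract error: predict refuses unfitted graphs")
  X <- if (is(newdata, "SpectrumTable")) spectra(newdata) else as.matrix(newdata)
  if (ncol(X) != object@config$inputLength)
    stop("contract error: band count mismatch")
  s <- object@standardization
  Xs <- .stdApply(X, list(center = s$xCenter, scale = s$xScale))
  forwardPass(object, Xs, mode = "inference") * s$yScale + s$yCenter
})
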