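#' Output length of a 1-D convolution
#'
#' Standard convolution arithmetic,
#' \code{floor((L + 2*padding - kernel)/stride) + 1}.
#'
#' @param L input length (positive)
#' @param kernel,stride positive integers
#' @param padding non-negative integer
#' @return output length (>= 1, else a geometry error is raised)
#' @export
conv1dOutputLength <- function(L, kernel, stride = 1L, padding = 0L) {
  if (L < 1 || kernel < 1 || stride < 1 || padding < 0)
    stop("contract error: arguments must be positive (padding >= 0)")
  out <- floor((L + 2 * padding - kernel) / stride) + 1
  if (out < 1) stop("geometry error: convolution output length < 1")
  as.integer(out)
}

#' Multiscale CNN configuration
#'
#' Geometry of the three parallel branches: small (3-kernels, channels
#' 1->16->128, padding 1), medium (5-kernels, 1->64->128, padding 2) and
#' large (7-kernels, 1->128->128, padding 3), every convolution with stride
#' 2, each branch closed by batch-norm + ReLU stages and 2x1 max pooling.
#' All branches must emit identical (channels x length) maps so the
#' learnable per-channel fusion is well defined; this is checked here.
#'
#' @param inputLength number of spectral bands (default 421)
#' @param kernels,channels1,paddings per-branch first-layer geometry
#' @param outChannels common second-layer channel count (default 128)
#' @param stride convolution stride (default 2)
#' @param poolKernel,poolStride max-pooling geometry (default 2, 2)
#' @param fcHidden fused fully connected width (default 128)
#' @param lstmHidden LSTM hidden size for the LSTM-headed variant
#' @return an \code{MSCNNConfig} list with derived lengths and flatten size
#' @export
mscnnConfig <- function(inputLength = 421L, kernels = c(3L, 5L, 7L),
                        channels1 = c(16L, 64L, 128L), outChannels = 128L,
                        paddings = c(1L, 2L, 3L), stride = 2L,
                        poolKernel = 2L, poolStride = 2L,
                        fcHidden = 128L, lstmHidden = 128L) {
  stopifnot(length(kernels) == 3L, length(channels1) == 3L,
            length(paddings) == 3L)
  L1 <- mapply(conv1dOutputLength, L = inputLength, kernel = kernels,
               stride = stride, padding = paddings)
  L2 <- mapply(conv1dOutputLength, L = L1, kernel = kernels,
               stride = stride, padding = paddings)
  Lp <- vapply(L2, conv1dOutputLength, integer(1),
               kernel = poolKernel, stride = poolStride, padding = 0L)
  if (length(unique(Lp)) != 1L || length(unique(L1)) != 1L ||
      length(unique(L2)) != 1L)
    stop("geometry error: branches emit mismatched map shapes (",
         paste(Lp, collapse = "/"), ")")
  structure(list(inputLength = as.integer(inputLength),
                 kernels = as.integer(kernels),
                 channels1 = as.integer(channels1),
                 outChannels = as.integer(outChannels),
                 paddings = as.integer(paddings), stride = as.integer(stride),
                 poolKernel = as.integer(poolKernel),
                 poolStride = as.integer(poolStride),
                 fcHidden = as.integer(fcHidden),
                 lstmHidden = as.integer(lstmHidden),
                 branchLengths = c(conv1 = L1[1], conv2 = L2[1], pool = Lp[1]),
                 flatDim = as.integer(outChannels * Lp[1])),
            class = "MSCNNConfig")
}

#' Training configuration for the spectral deep models
#'
#' Defaults follow the study protocol: Adam at learning rate 1e-4,
#' mean-squared-error loss, batch size 32. "Iterations" are epochs over the
#' calibration set with seeded without-replacement mini-batch shuffling.
#' Per-architecture epoch defaults (applied when \code{maxIterations} is
#' NULL): 500 with early stopping for ResNet18-1D, 1000 for MSCNN and
#' MSCNN-LSTM. Early stopping holds out \code{valFraction} of the training
#' samples, evaluates every epoch, and restores the best weights.
#'
#' @param learningRate Adam step size
#' @param batchSize mini-batch size
#' @param maxIterations epochs; NULL for the per-architecture default
#' @param earlyStopping list(enabled, patience, valFraction); NULL for the
#'   per-architecture default (enabled only for ResNet18-1D)
#' @param seed integer controlling initialization and shuffling
#' @param standardizeY z-score the target during optimization (predictions
#'   are always returned in original units)
#' @return a \code{TrainConfig} list
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 32L,
                        maxIterations = NULL, earlyStopping = NULL,
                        seed = 1L, standardizeY = TRUE) {
  if (learningRate < 0 || batchSize < 1L)
    stop("contract error: hyperparameters must be positive")
  if (!is.null(earlyStopping)) {
    es <- modifyList(list(enabled = TRUE, patience = 50L, valFraction = 0.1),
                     earlyStopping)
    if (es$valFraction <= 0 || es$valFraction > 0.5)
      stop("contract error: valFraction must be in (0, 0.5]")
    earlyStopping <- es
  }
  structure(list(optimizer = "adam", learningRate = learningRate,
                 loss = "mse", batchSize = as.integer(batchSize),
                 maxIterations = maxIterations, earlyStopping = earlyStopping,
                 seed = as.integer(seed), standardizeY = isTRUE(standardizeY),
                 batchNorm = list(momentum = 0.1, eps = 1e-5)),
            class = "TrainConfig")
}

.archDefaults <- function(architecture) {
  switch(architecture,
    resnet18_1d = list(epochs = 500L,
                       earlyStopping = list(enabled = TRUE, patience = 50L,
                                            valFraction = 0.1)),
    mscnn = list(epochs = 1000L, earlyStopping = list(enabled = FALSE)),
    mscnn_lstm = list(epochs = 1000L, earlyStopping = list(enabled = FALSE)))
}
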