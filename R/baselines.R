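## Classical chemometric baselines. Scale-sensitive methods (SVR, SVM, LDA)
## standardize bands from the training data; PLS and PCR are centered only.
## Every fitted model carries its preprocessing so prediction is leakage-free
## by construction.

.resolveXY <- function(train, target) {
  if (is(train, "SpectrumTable"))
    list(X = spectra(train), y = .targetVector(train, target))
  else
    list(X = as.matrix(train), y = as.numeric(target))
}

.resolveXL <- function(train, labels) {
  if (is(train, "SpectrumTable")) {
    X <- spectra(train)
    if (is.null(labels)) labels <- stages(train)
  } else X <- as.matrix(train)
  if (is.null(labels)) stop("contract error: no class labels")
  list(X = X, g = factor(labels))
}

.bandNames <- function(X) {
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  X
}

.stdFit <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  list(center = colMeans(X), scale = s)
}

.stdApply <- function(X, st) sweep(sweep(X, 2, st$center), 2, st$scale, "/")

.newBaseline <- function(method, fit, hyper, preprocess = NULL, extras = list()) {
  structure(c(list(method = method, fit = fit, hyper = hyper,
                   preprocess = preprocess), extras),
            class = "BaselineModel")
}

#' @export
print.BaselineModel <- function(x, ...) {
  cat(sprintf("BaselineModel <%s> (%s)\n", x$method,
              paste(sprintf("%s=%s", names(x$hyper), unlist(x$hyper)),
                    collapse = ", ")))
  invisible(x)
}

#' Partial least squares regression
#'
#' Linear predictor in band space built from latent variables that maximize
#' the spectral/response covariance. Bands are centered (not scaled).
#'
#' @param train \linkS4class{SpectrumTable} or N x B matrix
#' @param target target column name (table input) or numeric response vector
#' @param nLatent number of latent variables (default 10)
#' @param autoLv choose the latent-variable count by internal seeded 5-fold
#'   cross-validation on the training set (1..\code{maxLatent}, minimum
#'   RMSECV); overrides \code{nLatent}
#' @param maxLatent largest count tried when \code{autoLv = TRUE}
#' @param cvSeed fold seed for the internal selection
#' @return a \code{BaselineModel}; use \code{predict()} on new spectra
#' @export
fitPlsr <- function(train, target, nLatent = 10L, autoLv = FALSE,
                    maxLatent = 20L, cvSeed = 2L) {
  d <- .resolveXY(train, target)
  lvCap <- min(nrow(d$X) - 2L, ncol(d$X))
  if (autoLv) {
    maxLatent <- min(as.integer(maxLatent), lvCap)
    sch <- foldScheme(nrow(d$X), k = 5L, seed = cvSeed)
    press <- numeric(maxLatent)
    for (f in seq_len(sch$k)) {
      te <- sch$folds[[f]]
      Xtr <- .bandNames(d$X[-te, , drop = FALSE])
      m <- mixOmics::pls(Xtr, d$y[-te], ncomp = maxLatent, scale = FALSE,
                         mode = "regression")
      p <- predict(m, .bandNames(d$X[te, , drop = FALSE]))$predict[, 1, ]
      press <- press + colSums((p - d$y[te])^2)
    }
    nLatent <- which.min(press)
  }
  nLatent <- as.integer(nLatent)
  if (nLatent < 1L || nLatent > min(nrow(d$X) - 1L, ncol(d$X)))
    stop("contract error: nLatent out of range")
  X <- .bandNames(d$X)
  fit <- mixOmics::pls(X, d$y, ncomp = nLatent, scale = FALSE,
                       mode = "regression")
  .newBaseline("plsr", fit, list(nLatent = nLatent, autoLv = autoLv))
}

#' Support vector regression with RBF kernel
#'
#' Bands are standardized with training statistics before the kernel is
#' applied. Default hyperparameters: penalty \code{C = 90}, RBF
#' \code{gamma = 1}.
#'
#' @inheritParams fitPlsr
#' @param C penalty coefficient
#' @param gamma RBF kernel parameter
#' @return a \code{BaselineModel}
#' @export
fitSvr <- function(train, target, C = 90, gamma = 1) {
  d <- .resolveXY(train, target)
  if (nrow(d$X) < 2L) stop("contract error: need >= 2 training samples")
  st <- .stdFit(d$X)
  fit <- e1071::svm(.stdApply(d$X, st), d$y, type = "eps-regression",
                    kernel = "radial", cost = C, gamma = gamma, scale = FALSE,
                    fitted = FALSE)
  .newBaseline("svr", fit, list(C = C, gamma = gamma), preprocess = st)
}

## deterministic PC sign convention: largest-|loading| element positive
.fixSigns <- function(rotation) {
  flip <- apply(rotation, 2, function(v) sign(v[which.max(abs(v))]))
  sweep(rotation, 2, flip, "*")
}

#' Principal component regression
#'
#' Least squares on the leading principal-component scores of the centered
#' band matrix. Component signs are fixed (largest-magnitude loading
#' positive) so refits are bitwise reproducible.
#'
#' @inheritParams fitPlsr
#' @param nComponents number of principal components (default 10)
#' @return a \code{BaselineModel}
#' @export
fitPcr <- function(train, target, nComponents = 10L) {
  d <- .resolveXY(train, target)
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > min(nrow(d$X) - 1L, ncol(d$X)))
    stop("contract error: nComponents out of range")
  pc <- stats::prcomp(d$X, center = TRUE, scale. = FALSE)
  rot <- .fixSigns(pc$rotation[, seq_len(nComponents), drop = FALSE])
  sc <- sweep(d$X, 2, pc$center) %*% rot
  lmfit <- stats::lm.fit(cbind(1, sc), d$y)
  .newBaseline("pcr", list(center = pc$center, rotation = rot,
                           coef = lmfit$coefficients),
               list(nComponents = nComponents))
}

#' PLS discriminant analysis
#'
#' One-hot-encoded PLS projection of the spectra into a latent space that
#' maximizes class separation, with a Mahalanobis nearest-centroid decision
#' on the latent variates (the stable multi-class decision rule for ordered
#' classes, where argmax on raw indicator predictions is biased against
#' middle classes).
#'
#' @param train \linkS4class{SpectrumTable} or N x B matrix
#' @param labels class labels; taken from \code{stages(train)} when omitted
#' @param nLatent number of latent variables (default 10)
#' @param standardize z-score bands with training statistics first
#'   (default FALSE: PLS is centered only)
#' @return a \code{BaselineModel}
#' @export
fitPlsda <- function(train, labels = NULL, nLatent = 10L, standardize = FALSE) {
  d <- .resolveXL(train, labels)
  if (nlevels(d$g) < 2L) stop("contract error: need >= 2 classes")
  nLatent <- as.integer(min(nLatent, nrow(d$X) - 1L, ncol(d$X)))
  st <- if (standardize) .stdFit(d$X) else NULL
  X <- .bandNames(if (standardize) .stdApply(d$X, st) else d$X)
  fit <- mixOmics::plsda(X, d$g, ncomp = nLatent, scale = FALSE)
  .newBaseline("plsda", fit, list(nLatent = nLatent, standardize = standardize),
               preprocess = st, extras = list(levels = levels(d$g)))
}

#' SVM maturity classifier (RBF kernel)
#'
#' Bands standardized with training statistics; \code{gamma = "scale"} uses
#' \code{1 / (B * var(X))} computed on the standardized training matrix.
#'
#' @inheritParams fitPlsda
#' @param C penalty parameter (default 10)
#' @param gamma RBF parameter or \code{"scale"}
#' @return a \code{BaselineModel}
#' @export
fitSvmClassifier <- function(train, labels = NULL, C = 10, gamma = "scale") {
  d <- .resolveXL(train, labels)
  if (nlevels(d$g) < 2L) stop("contract error: need >= 2 classes")
  st <- .stdFit(d$X)
  Xs <- .stdApply(d$X, st)
  if (identical(gamma, "scale"))
    gamma <- 1 / (ncol(Xs) * stats::var(as.vector(Xs)))
  fit <- e1071::svm(Xs, d$g, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  .newBaseline("svm", fit, list(C = C, gamma = gamma), preprocess = st,
               extras = list(levels = levels(d$g)))
}

#' Linear discriminant analysis with recursive feature elimination
#'
#' Iteratively refits LDA on standardized bands, dropping the 10% (by
#' default) of remaining bands with the smallest aggregate absolute
#' discriminant coefficient, until \code{nFeatures} remain. With
#' \code{nFeatures = B} this is plain LDA.
#'
#' @inheritParams fitPlsda
#' @param nFeatures number of bands to keep (default: all, i.e. no
#'   elimination); must be >= number of classes - 1
#' @param step fraction of remaining bands dropped per iteration
#' @return a \code{BaselineModel}; \code{$selected} holds the kept band indices
#' @export
fitLdaRfe <- function(train, labels = NULL, nFeatures = NULL, step = 0.1) {
  d <- .resolveXL(train, labels)
  B <- ncol(d$X)
  if (is.null(nFeatures)) nFeatures <- B
  if (nFeatures < nlevels(d$g) - 1L)
    stop("contract error: nFeatures must be >= n_classes - 1")
  if (nFeatures > B) stop("contract error: nFeatures exceeds band count")
  st <- .stdFit(d$X)
  Xs <- .stdApply(d$X, st)
  keep <- seq_len(B)
  repeat {
    fit <- suppressWarnings(MASS::lda(Xs[, keep, drop = FALSE], grouping = d$g))
    if (length(keep) <= nFeatures) break
    imp <- rowSums(abs(fit$scaling))
    nDrop <- min(max(1L, floor(step * length(keep))), length(keep) - nFeatures)
    keep <- keep[order(imp, decreasing = TRUE)[seq_len(length(keep) - nDrop)]]
    keep <- sort(keep)
  }
  .newBaseline("lda_rfe", fit, list(nFeatures = nFeatures, step = step),
               preprocess = st,
               extras = list(selected = keep, levels = levels(d$g)))
}

#' Predict from a fitted baseline model
#'
#' @param object a \code{BaselineModel}
#' @param newdata \linkS4class{SpectrumTable} or N x B matrix
#' @param ... unused
#' @return numeric predictions (regression) or a factor (classification)
#' @method predict BaselineModel
#' @export
predict.BaselineModel <- function(object, newdata, ...) {
  X <- if (is(newdata, "SpectrumTable")) spectra(newdata) else as.matrix(newdata)
  switch(object$method,
    plsr = {
      p <- predict(object$fit, .bandNames(X))
      as.numeric(p$predict[, 1, object$hyper$nLatent])
    },
    svr = {
      if (object$fit$tot.nSV == 0)          # constant target: all in the tube
        rep(-object$fit$rho, nrow(X))
      else as.numeric(predict(object$fit, .stdApply(X, object$preprocess)))
    },
    pcr = {
      sc <- sweep(X, 2, object$fit$center) %*% object$fit$rotation
      as.numeric(cbind(1, sc) %*% object$fit$coef)
    },
    plsda = {
      Xs <- if (!is.null(object$preprocess)) .stdApply(X, object$preprocess) else X
      cl <- predict(object$fit,
                    .bandNames(Xs))$class$mahalanobis.dist[, object$hyper$nLatent]
      factor(as.character(cl), levels = object$levels)
    },
    svm = {
      p <- predict(object$fit, .stdApply(X, object$preprocess))
      factor(as.character(p), levels = object$levels)
    },
    lda_rfe = {
      Xs <- .stdApply(X, object$preprocess)[, object$selected, drop = FALSE]
      cl <- predict(object$fit, Xs)$class
      factor(as.character(cl), levels = object$levels)
    },
    stop("unknown baseline method: ", object$method))
}

#' Baseline model specification
#'
#' Bundles a method id and its hyperparameters for use with
#' \code{\link{crossvalClassify}} and the command-line tools.
#'
#' @param method one of "plsr", "svr", "pcr", "plsda", "svm", "lda_rfe"
#' @param ... hyperparameters forwarded to the corresponding \code{fit*}
#' @return a \code{BaselineSpec}
#' @export
baselineSpec <- function(method = c("plsda", "svm", "lda_rfe", "plsr", "svr", "pcr"),
                         ...) {
  method <- match.arg(method)
  structure(list(method = method, hyper = list(...)), class = "BaselineSpec")
}

.fitBaseline <- function(spec, train, y) {
  f <- switch(spec$method,
    plsr = fitPlsr, svr = fitSvr, pcr = fitPcr,
    plsda = fitPlsda, svm = fitSvmClassifier, lda_rfe = fitLdaRfe)
  do.call(f, c(list(train, y), spec$hyper))
}
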