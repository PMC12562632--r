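#' Firmness-soluble-solids ratio
#'
#' The composite maturity index \code{FSR = FI / SSC}: firmness (N) over
#' soluble solid content (percent). Vectorized.
#'
#' @param FI firmness in newtons
#' @param SSC soluble solid content in percent, strictly positive
#' @return dimensionless ratio
#' @export
fsr <- function(FI, SSC) {
  if (any(SSC <= 0)) stop("contract error: SSC must be > 0")
  FI / SSC
}

## round half away from zero at `digits` decimals (presentation convention)
roundHalfAway <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent change between two values
#'
#' \code{100 * (after - before) / before}, sign preserved, rounded half away
#' from zero at \code{digits} decimals (the convention used when reporting
#' stage-to-stage changes of quality indices).
#'
#' @param before,after scalar values, \code{before != 0}
#' @param digits decimals kept (default 1)
#' @return signed percent change
#' @export
percentChange <- function(before, after, digits = 1L) {
  if (before == 0) stop("contract error: before must be nonzero")
  roundHalfAway(100 * (after - before) / before, digits)
}

#' Regression metrics: R2, RMSE, RPD
#'
#' \code{RMSE = sqrt(mean((yRef - yPred)^2))};
#' \code{R2 = 1 - SSres/SStot} about the reference mean; and
#' \code{RPD = SD(yRef) / RMSE}. By default the RPD standard deviation uses
#' the population convention (divide by n), which makes the identity
#' \code{RPD = 1 / sqrt(1 - R2)} exact; the sample convention (n-1) is
#' available by flag.
#'
#' @param yRef reference values (length >= 2, nonzero variance)
#' @param yPred predicted values, same length
#' @param setId \code{"prediction"} or \code{"calibration"}
#' @param rpdConvention \code{"population"} (default) or \code{"sample"}
#' @return a \code{RegressionReport} list: setId, n, R2, RMSE, RPD, overflow
#' @export
regressionReport <- function(yRef, yPred,
                             setId = c("prediction", "calibration"),
                             rpdConvention = c("population", "sample")) {
  setId <- match.arg(setId)
  rpdConvention <- match.arg(rpdConvention)
  yRef <- as.numeric(yRef); yPred <- as.numeric(yPred)
  n <- length(yRef)
  if (n < 2L || length(yPred) != n)
    stop("contract error: need equal lengths >= 2")
  sst <- sum((yRef - mean(yRef))^2)
  if (sst == 0) stop("contract error: zero reference variance")
  ssr <- sum((yRef - yPred)^2)
  rmse <- sqrt(ssr / n)
  r2 <- 1 - ssr / sst
  sdref <- if (rpdConvention == "population") sqrt(sst / n) else sqrt(sst / (n - 1))
  overflow <- rmse == 0
  structure(list(setId = setId, n = n, R2 = r2, RMSE = rmse,
                 RPD = if (overflow) Inf else sdref / rmse,
                 overflow = overflow, rpdConvention = rpdConvention),
            class = "RegressionReport")
}

#' @export
print.RegressionReport <- function(x, ...) {
  cat(sprintf("%s set (n=%d): R2 = %.4f, RMSE = %.4f, RPD = %s\n",
              x$setId, x$n, x$R2, x$RMSE,
              if (x$overflow) "Inf (perfect prediction)" else sprintf("%.4f", x$RPD)))
  invisible(x)
}

#' Per-stage summary of quality indices
#'
#' Minimum, maximum, mean and sample standard deviation (n-1) of FI, SSC and
#' FSR within each maturity stage, ordered P1 to P5. With a single record in
#' a stage the SD is reported as NA.
#'
#' @param records data.frame with columns FI, SSC, FSR and stage, or a
#'   \linkS4class{SpectrumTable} carrying those annotations
#' @return data.frame with columns stage, index, min, max, mean, sd
#' @export
stageSummary <- function(records) {
  if (is(records, "SpectrumTable")) records <- qualityData(records)
  records <- as.data.frame(records)
  need <- c("FI", "SSC", "FSR", "stage")
  if (!all(need %in% names(records)))
    stop("contract error: records need columns ", paste(need, collapse = ", "))
  if (anyNA(records$stage) || any(records$stage == ""))
    stop("contract error: every record must carry a stage label")
  lv <- .stageLevels(records$stage)
  out <- do.call(rbind, lapply(lv, function(s) {
    r <- records[records$stage == s, ]
    do.call(rbind, lapply(c("FI", "SSC", "FSR"), function(idx) {
      v <- r[[idx]]
      data.frame(stage = s, index = idx, min = min(v), max = max(v),
                 mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Stratified k-fold scheme
#'
#' Disjoint folds covering all samples; with \code{stratified = TRUE} each
#' class is dealt round-robin after a seeded shuffle, so per-stratum fold
#' sizes differ by at most one.
#'
#' @param labels class labels (length n) or an integer sample count for
#'   unstratified folding
#' @param k number of folds
#' @param stratified balance classes across folds (default TRUE)
#' @param seed integer seed
#' @return a \code{FoldScheme} list with \code{$folds}
#' @export
foldScheme <- function(labels, k = 5L, stratified = TRUE, seed = 2L) {
  if (length(labels) == 1L && is.numeric(labels)) {
    n <- as.integer(labels); labels <- rep("all", n); stratified <- FALSE
  }
  n <- length(labels)
  if (k < 2L || k > n) stop("contract error: k out of range")
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  folds <- vector("list", k)
  groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
  for (g in groups) {
    g <- g[sample(length(g))]
    for (i in seq_along(g)) {
      f <- ((i - 1L) %% k) + 1L
      folds[[f]] <- c(folds[[f]], g[i])
    }
  }
  structure(list(folds = lapply(folds, sort), k = k,
                 stratified = stratified, seed = seed),
            class = "FoldScheme")
}

#' Classification metrics from truth/prediction pairs
#'
#' Confusion matrix (rows: reference, columns: predicted) with accuracy and
#' macro-averaged precision, recall and F1, all in percent. Classes never
#' predicted contribute zero precision (and zero F1) to the macro average.
#'
#' @param truth reference labels
#' @param pred predicted labels
#' @param levels optional class order
#' @param perFold optional per-fold accuracy breakdown to carry along
#' @return a \code{ClassificationReport} list
#' @export
classificationReport <- function(truth, pred, levels = NULL, perFold = NULL) {
  if (is.null(levels)) levels <- .stageLevels(as.character(truth))
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  cm <- table(reference = truth, predicted = pred)
  n <- sum(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(confusion = cm,
                 accuracy = 100 * sum(tp) / n,
                 precision = 100 * mean(prec),
                 recall = 100 * mean(rec),
                 f1 = 100 * mean(f1),
                 n = n, perFold = perFold),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, macro precision %.2f%%, recall %.2f%%, F1 %.2f%% (n=%d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$n))
  print(x$confusion)
  invisible(x)
}

#' Leakage-free k-fold cross-validated classification
#'
#' The complete modeling pipeline -- band standardization, latent-variable
#' projection, RFE band selection -- is refitted from scratch on each fold's
#' training portion only (this is guaranteed by construction: all
#' preprocessing lives inside the \code{fit*} functions and sees only the
#' rows passed to it). Metrics are computed from predictions aggregated
#' across folds.
#'
#' @param spec a \code{\link{baselineSpec}} for a classification method
#' @param table \linkS4class{SpectrumTable} or N x B matrix
#' @param labels class labels; default \code{stages(table)}
#' @param scheme a \code{\link{foldScheme}}; default stratified 5-fold, seed 2
#' @return a \code{ClassificationReport} with per-fold accuracies
#' @export
crossvalClassify <- function(spec, table, labels = NULL, scheme = NULL) {
  stopifnot(inherits(spec, "BaselineSpec"))
  d <- .resolveXL(table, labels)
  if (is.null(scheme)) scheme <- foldScheme(as.character(d$g), k = 5L)
  n <- nrow(d$X)
  pred <- rep(NA_character_, n)
  perFold <- data.frame(fold = seq_len(scheme$k), accuracy = NA_real_)
  for (f in seq_len(scheme$k)) {
    testIdx <- scheme$folds[[f]]
    trainIdx <- setdiff(seq_len(n), testIdx)
    gTrain <- droplevels(d$g[trainIdx])
    if (nlevels(gTrain) < nlevels(droplevels(d$g)))
      stop("stratification error: class absent from training fold ", f)
    fit <- .fitBaseline(spec, d$X[trainIdx, , drop = FALSE], gTrain)
    p <- as.character(predict(fit, d$X[testIdx, , drop = FALSE]))
    pred[testIdx] <- p
    perFold$accuracy[f] <- 100 * mean(p == as.character(d$g[testIdx]))
  }
  classificationReport(as.character(d$g), pred,
                       levels = .stageLevels(as.character(d$g)),
                       perFold = perFold)
}
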