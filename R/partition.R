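#' Joint X-y distance matrix for SPXY partitioning
#'
#' Normalized sum of the Euclidean spectral distance and the absolute
#' response distance,
#' \code{d(i,j) = dX(i,j)/max(dX) + dy(i,j)/max(dy)},
#' so both blocks contribute on equal footing. Entries lie in [0, 2] with a
#' zero diagonal.
#'
#' @param X N x B matrix of predictors (spectra)
#' @param y length-N response vector
#' @return N x N symmetric matrix
#' @export
spxyJointDistance <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop("contract error: need at least 2 samples")
  if (length(y) != n) stop("contract error: length(y) != nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("contract error: non-finite entries")
  dX <- unname(as.matrix(stats::dist(X)))
  dy <- abs(outer(y, y, "-"))
  if (max(dX) == 0) stop("degenerate-distance error: all X rows identical")
  if (max(dy) == 0) stop("degenerate-distance error: all y values identical")
  dX / max(dX) + dy / max(dy)
}

#' Kennard-Stone max-min selection on a distance matrix
#'
#' Seeds the selection with the pair at maximum distance, then repeatedly
#' adds the candidate whose minimum distance to the already-selected set is
#' largest. Ties are broken by the lowest index; the procedure is fully
#' deterministic.
#'
#' @param D N x N symmetric distance matrix (e.g. \code{\link{spxyJointDistance}})
#' @param nCal number of samples to select, \code{2 <= nCal <= N}
#' @return ordered integer vector of selected indices
#' @export
spxySelect <- function(D, nCal) {
  D <- unname(as.matrix(D))
  n <- nrow(D)
  if (nCal < 2L) stop("contract error: nCal must be >= 2")
  if (nCal > n) stop("contract error: nCal exceeds sample count")
  hit <- which(D == max(D), arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- as.integer(hit[1, ])
  if (nCal > 2L) {
    minD <- pmin(D[, sel[1]], D[, sel[2]])
    minD[sel] <- -Inf
    for (step in seq_len(nCal - 2L)) {
      nxt <- as.integer(which.max(minD))   # ties: lowest index
      sel <- c(sel, nxt)
      minD <- pmin(minD, D[, nxt])
      minD[nxt] <- -Inf
    }
  }
  sel
}

## stage-ordered stratum levels: P1..P5 first, anything else after, sorted
.stageLevels <- function(st) {
  u <- unique(st)
  c(intersect(MATURITY_STAGES, u), sort(setdiff(u, MATURITY_STAGES)))
}

#' Stratified SPXY calibration/prediction split
#'
#' Runs SPXY (Kennard-Stone max-min selection on the joint X-y distance)
#' independently within each maturity stage, so both sets represent every
#' stage in the requested ratio. Within each stratum the sample order is
#' first shuffled with the given seed (this resolves ties between duplicated
#' points); the selection itself is deterministic. Per-stratum calibration
#' counts are \code{round(n_s * cal/(cal+pred))} (half-to-even), with the
#' last stratum adjusted so the global totals match the rounded global
#' ratio exactly.
#'
#' @param table a \linkS4class{SpectrumTable} with stage labels
#' @param ratio integer pair \code{c(cal, pred)}, e.g. \code{c(4, 1)}
#' @param target response column driving the y-distance ("FI", "SSC" or
#'   "FSR"); ignored for \code{method = "random"}
#' @param seed integer seed for the pre-selection shuffle (default 2)
#' @param method \code{"spxy"} (default) or a \code{"random"} convenience split
#' @return a \linkS4class{SplitAssignment}
#' @export
stratifiedSpxySplit <- function(table, ratio = c(4, 1), target = "FI",
                                seed = 2L, method = c("spxy", "random")) {
  method <- match.arg(method)
  stopifnot(is(table, "SpectrumTable"))
  if (length(ratio) != 2L || any(ratio < 0) || sum(ratio) <= 0 ||
      any(ratio != round(ratio)) || ratio[1] <= 0)
    stop("contract error: ratio must be positive integers c(cal, pred)")
  st <- stages(table)
  if (is.null(st)) stop("contract error: table has no stage labels")
  frac <- ratio[1] / sum(ratio)
  n <- ncol(table)
  lv <- .stageLevels(st)
  sizes <- vapply(lv, function(s) sum(st == s), integer(1))
  if (any(sizes < 2L)) stop("contract error: every stratum needs >= 2 samples")
  nCal <- round(sizes * frac)
  nCal[length(nCal)] <- round(n * frac) - sum(nCal[-length(nCal)])
  if (any(nCal < 0 | nCal > sizes))
    stop("contract error: infeasible per-stratum calibration counts")

  X <- spectra(table)
  y <- if (method == "spxy") .targetVector(table, target) else NULL

  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)

  cal <- integer(0); pred <- integer(0)
  per <- data.frame(stage = lv, nCal = as.integer(nCal),
                    nPred = as.integer(sizes - nCal))
  for (i in seq_along(lv)) {
    idx <- which(st == lv[i])
    perm <- sample(length(idx))
    k <- nCal[i]
    if (k == length(idx)) {
      pick <- seq_along(idx)            # exhaustion: all calibration
    } else if (k == 0L) {
      pick <- integer(0)
    } else if (method == "random") {
      pick <- seq_len(k)                # first k of the shuffled order
    } else if (k == 1L) {
      D <- spxyJointDistance(X[idx[perm], , drop = FALSE], y[idx[perm]])
      pick <- spxySelect(D, 2L)[1]
    } else {
      D <- spxyJointDistance(X[idx[perm], , drop = FALSE], y[idx[perm]])
      pick <- spxySelect(D, k)
    }
    calG <- idx[perm[pick]]
    cal <- c(cal, calG)
    pred <- c(pred, sort(setdiff(idx, calG)))
  }
  new("SplitAssignment", calibration = as.integer(cal),
      prediction = as.integer(pred), perStratum = per,
      config = list(ratio = ratio, target = target, seed = seed,
                    method = method))
}
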