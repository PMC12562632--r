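#' Pixel-wise quality prediction over a cube region
#'
#' Passes each in-region pixel spectrum through a fitted model (deep
#' \linkS4class{PredictorGraph} or classical \code{BaselineModel}), applying
#' the model's stored standardization, and assembles the predictions into a
#' spatial map in target units. The cube must already be calibrated and
#' band-truncated to the model's expected input bands. Prediction is
#' batched in row-major chunks; the values are independent of the chunking.
#'
#' @param cube calibrated, truncated \linkS4class{Hypercube}
#' @param model fitted regressor with a \code{predict} method over N x B
#'   matrices
#' @param region either \code{c(row0, col0, height, width)} (0-based
#'   corner) or a logical rows x cols mask; NULL uses the whole image
#' @param target label stored with the map (e.g. "FI")
#' @param chunkSize pixels per prediction batch
#' @return a \code{PredictionMap}: list with \code{values} (matrix, NA
#'   outside the region), \code{region}, \code{target}
#' @export
pixelwisePredict <- function(cube, model, region = NULL, target = "",
                             chunkSize = 4096L) {
  stopifnot(is(cube, "Hypercube"))
  d <- dim(cube@data)
  expected <- if (is(model, "PredictorGraph")) model@config$inputLength
              else NA_integer_
  if (!is.na(expected) && d[3] != expected)
    stop("contract error: cube has ", d[3], " bands but the model expects ",
         expected)
  if (is.null(region)) {
    mask <- matrix(TRUE, d[1], d[2])
    offs <- c(0L, 0L); outDim <- d[1:2]
  } else if (is.matrix(region) && is.logical(region)) {
    if (!identical(dim(region), d[1:2]))
      stop("contract error: mask shape mismatch")
    mask <- region; offs <- c(0L, 0L); outDim <- d[1:2]
  } else {
    r0 <- region[1]; c0 <- region[2]; h <- region[3]; w <- region[4]
    if (r0 < 0 || c0 < 0 || r0 + h > d[1] || c0 + w > d[2])
      stop("contract error: region exceeds cube bounds")
    mask <- matrix(FALSE, d[1], d[2])
    mask[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- TRUE
    offs <- c(r0, c0); outDim <- c(h, w)
  }
  pix <- which(as.vector(mask))
  X <- matrix(cube@data, nrow = d[1] * d[2])[pix, , drop = FALSE]
  pred <- numeric(length(pix))
  for (from in seq(1, length(pix), by = chunkSize)) {
    to <- min(from + chunkSize - 1L, length(pix))
    pred[from:to] <- as.numeric(predict(model, X[from:to, , drop = FALSE]))
  }
  full <- matrix(NA_real_, d[1], d[2])
  full[pix] <- pred
  values <- full[(offs[1] + 1):(offs[1] + outDim[1]),
                 (offs[2] + 1):(offs[2] + outDim[2]), drop = FALSE]
  structure(list(values = values, region = region, target = target),
            class = "PredictionMap")
}

#' @export
print.PredictionMap <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("PredictionMap%s: %d x %d px, %d defined, range %.3f-%.3f\n",
              if (nzchar(x$target)) paste0(" <", x$target, ">") else "",
              nrow(x$values), ncol(x$values), length(v),
              min(v), max(v)))
  invisible(x)
}

.palettes <- list(
  blueRed = c("#0000CC", "#00B2FF", "#00E599", "#FFE500", "#FF7F00", "#CC0000"))

#' Render a prediction map as a color-mapped PNG
#'
#' Values are clipped to the color scale, mapped through a continuous
#' blue-to-red palette (low = blue, high = red), and written with a
#' vertical colorbar on the right. Undefined pixels render white. Output
#' bytes are deterministic for fixed inputs.
#'
#' @param map a \code{PredictionMap} (or bare numeric matrix)
#' @param file output PNG path
#' @param colorScale \code{c(lo, hi)} in target units; default the
#'   1st-99th percentile of the defined values
#' @param palette palette id (currently \code{"blueRed"})
#' @param colorbarWidth width of the colorbar strip in pixels (0: none)
#' @return invisibly, a list with the file path and the scale used
#' @export
renderMap <- function(map, file, colorScale = NULL, palette = "blueRed",
                      colorbarWidth = 10L) {
  v <- if (inherits(map, "PredictionMap")) map$values else as.matrix(map)
  fin <- v[is.finite(v)]
  if (!length(fin)) stop("contract error: map has no defined values")
  if (is.null(colorScale))
    colorScale <- as.numeric(quantile(fin, c(0.01, 0.99)))
  if (!(colorScale[1] < colorScale[2]))
    stop("contract error: degenerate color scale")
  ramp <- grDevices::colorRamp(.palettes[[palette]])
  t01 <- (pmin(pmax(v, colorScale[1]), colorScale[2]) - colorScale[1]) /
    diff(colorScale)
  flat <- as.vector(t01)
  rgbv <- matrix(1, length(flat), 3)            # NA pixels -> white
  ok <- is.finite(flat)
  rgbv[ok, ] <- ramp(flat[ok]) / 255
  img <- array(rgbv, dim = c(nrow(v), ncol(v), 3))
  if (colorbarWidth > 0) {
    barT <- seq(1, 0, length.out = nrow(v))
    bar <- ramp(barT) / 255
    strip <- array(1, dim = c(nrow(v), colorbarWidth + 2L, 3))
    for (ch in 1:3)
      strip[, 3:(colorbarWidth + 2L), ch] <- matrix(bar[, ch], nrow(v),
                                                    colorbarWidth)
    img2 <- array(1, dim = c(nrow(v), ncol(v) + colorbarWidth + 2L, 3))
    img2[, seq_len(ncol(v)), ] <- img
    img2[, ncol(v) + seq_len(colorbarWidth + 2L), ] <- strip
    img <- img2
  }
  png::writePNG(img, file)
  invisible(list(file = file, scale = colorScale, palette = palette))
}
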