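#' White/dark reflectance calibration
#'
#' Converts raw digital numbers to relative reflectance,
#' \code{R = (RO - RD) / (RW - RD)}, elementwise over the cube. Elements
#' where the white and dark references coincide (dead pixels: zero dynamic
#' range) are set to \code{fill} and flagged in the output metadata rather
#' than raising, so whole-cube calibration survives isolated dead pixels.
#'
#' @param raw original \linkS4class{Hypercube} (digital numbers)
#' @param cal a \linkS4class{CalibrationPair}
#' @param fill value assigned where \code{RW == RD} (default 0)
#' @return calibrated \linkS4class{Hypercube}; metadata gains
#'   \code{n_invalid} and, when nonzero, \code{invalid_index} (linear indices)
#' @export
reflectanceCorrect <- function(raw, cal, fill = 0) {
  stopifnot(is(raw, "Hypercube"), is(cal, "CalibrationPair"))
  if (!identical(dim(raw@data), dim(cal@white@data)))
    stop("contract error: raw and calibration cubes must share shape")
  if (!isTRUE(all.equal(raw@wavelengths, cal@white@wavelengths)))
    stop("contract error: raw and calibration cubes must share wavelengths")
  denom <- cal@white@data - cal@dark@data
  bad <- denom == 0
  if (all(bad))
    stop("calibration error: white and dark references are identical everywhere")
  out <- (raw@data - cal@dark@data) / denom
  meta <- raw@metadata
  meta$n_invalid <- sum(bad)
  if (any(bad)) {
    out[bad] <- fill
    meta$invalid_index <- which(bad)
  }
  Hypercube(out, raw@wavelengths, metadata = meta)
}

#' Elliptical region-of-interest mask
#'
#' Boolean mask over a rows x cols grid, true inside (or on) the axis-aligned
#' ellipse of the given \linkS4class{ROISpec}. Pixel coordinates are 0-based;
#' a pixel belongs to the ROI when its center satisfies
#' \code{((r-cr)/ar)^2 + ((c-cc)/ac)^2 <= 1}, where \code{ar}/\code{ac} are
#' the semi-axes along rows/columns given the orientation.
#'
#' @param shape integer vector \code{c(rows, cols)}
#' @param roi a \linkS4class{ROISpec}
#' @return logical rows x cols matrix
#' @export
ellipticalRoiMask <- function(shape, roi) {
  stopifnot(is(roi, "ROISpec"), length(shape) == 2L)
  rows <- shape[1]; cols <- shape[2]
  ar <- if (roi@orientation == "row") roi@semiMajor else roi@semiMinor
  ac <- if (roi@orientation == "row") roi@semiMinor else roi@semiMajor
  if (roi@centerRow - ar < 0 || roi@centerRow + ar > rows - 1 ||
      roi@centerCol - ac < 0 || roi@centerCol + ac > cols - 1)
    stop("contract error: ellipse exceeds image bounds")
  r <- (seq_len(rows) - 1 - roi@centerRow) / ar
  c_ <- (seq_len(cols) - 1 - roi@centerCol) / ac
  outer(r^2, c_^2, "+") <= 1
}

#' Mean spectrum over a pixel mask
#'
#' Per-band arithmetic mean of the cube over the pixels where \code{mask} is
#' true.
#'
#' @param cube a \linkS4class{Hypercube}
#' @param mask logical rows x cols matrix
#' @return numeric vector of length \code{bands}, named by wavelength
#' @export
meanRoiSpectrum <- function(cube, mask) {
  stopifnot(is(cube, "Hypercube"))
  d <- dim(cube@data)
  if (!identical(dim(mask), d[1:2]))
    stop("contract error: mask shape must equal the cube's spatial shape")
  if (!any(mask)) stop("contract error: empty mask")
  m <- matrix(cube@data, nrow = d[1] * d[2])[as.vector(mask), , drop = FALSE]
  out <- colMeans(m)
  names(out) <- sprintf("%.10g", cube@wavelengths)
  out
}

.bandWindow <- function(wl, loNm, hiNm) {
  if (!(loNm < hiNm)) stop("contract error: loNm must be < hiNm")
  keep <- which(wl >= loNm & wl <= hiNm)
  if (!length(keep))
    stop("contract error: no bands inside [", loNm, ", ", hiNm, "] nm")
  keep
}

#' @rdname truncateBands
#' @export
setMethod("truncateBands", "SpectrumTable", function(x, loNm, hiNm) {
  keep <- .bandWindow(wavelengths(x), loNm, hiNm)
  x[keep, ]
})

#' @rdname truncateBands
#' @export
setMethod("truncateBands", "Hypercube", function(x, loNm, hiNm) {
  keep <- .bandWindow(x@wavelengths, loNm, hiNm)
  Hypercube(x@data[, , keep, drop = FALSE], x@wavelengths[keep], x@metadata)
})
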