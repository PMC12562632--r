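#' Hyperspectral cube
#'
#' A rows x cols x bands reflectance (or raw digital-number) array with its
#' band-center wavelengths in nm and free-form metadata. Produced by
#' line-scanning NIR hyperspectral cameras; here read from ENVI-style
#' header/binary pairs or generated synthetically.
#'
#' @slot data numeric 3-D array, rows x cols x bands, finite
#' @slot wavelengths strictly increasing numeric vector, one entry per band, nm
#' @slot metadata named list of free-form entries
#' @export
setClass("Hypercube",
  representation(data = "array", wavelengths = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("Hypercube", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3-D array (rows x cols x bands)")
  if (dim(d)[3] != length(object@wavelengths))
    return("length(wavelengths) must equal the band dimension of data")
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (!all(is.finite(d)))
    return("data must be finite")
  TRUE
})

#' Construct a Hypercube
#'
#' @param data rows x cols x bands numeric array
#' @param wavelengths band centers in nm, strictly increasing
#' @param metadata optional named list
#' @return a \linkS4class{Hypercube}
#' @export
Hypercube <- function(data, wavelengths, metadata = list()) {
  new("Hypercube", data = data, wavelengths = as.numeric(wavelengths),
      metadata = metadata)
}

#' @describeIn Hypercube band-center wavelengths (nm)
#' @param x a Hypercube
#' @export
setMethod("wavelengths", "Hypercube", function(x) x@wavelengths)

#' @describeIn Hypercube the underlying rows x cols x bands array
#' @export
setMethod("cubeData", "Hypercube", function(x) x@data)

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  cat(sprintf("Hypercube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(object@wavelengths), max(object@wavelengths)))
  if (length(object@metadata))
    cat("metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("dim", "Hypercube", function(x) dim(x@data))

#' @describeIn Hypercube free-form metadata list
#' @export
setMethod("metadata", "Hypercube", function(x) x@metadata)

#' White/dark reference pair for reflectance calibration
#'
#' Holds the white reference cube (diffuse-reflectance standard) and the dark
#' current cube (lens occluded) used to convert raw digital numbers to
#' relative reflectance.
#'
#' @slot white \linkS4class{Hypercube} of the white reference
#' @slot dark \linkS4class{Hypercube} of the dark reference
#' @export
setClass("CalibrationPair",
  representation(white = "Hypercube", dark = "Hypercube"))

setValidity("CalibrationPair", function(object) {
  if (!identical(dim(object@white@data), dim(object@dark@data)))
    return("white and dark cubes must share shape")
  if (!isTRUE(all.equal(object@white@wavelengths, object@dark@wavelengths)))
    return("white and dark cubes must share wavelengths")
  TRUE
})

#' @rdname CalibrationPair-class
#' @param white,dark white and dark reference \linkS4class{Hypercube}s
#' @export
CalibrationPair <- function(white, dark) new("CalibrationPair", white = white, dark = dark)

setMethod("show", "CalibrationPair", function(object) {
  cat("CalibrationPair of\n  white: "); show(object@white)
  cat("  dark:  "); show(object@dark)
})

#' Elliptical region-of-interest specification
#'
#' Axis-aligned ellipse in pixel coordinates; the major axis runs along image
#' rows or columns (the acquisition aligns the fruit stem-calyx axis with the
#' scan direction). Coordinates are 0-based.
#'
#' @slot centerRow,centerCol ellipse center, 0-based pixel coordinates
#' @slot semiMajor,semiMinor semi-axes in pixels, \code{semiMajor >= semiMinor > 0}
#' @slot orientation "row" if the major axis runs along rows, else "col"
#' @export
setClass("ROISpec",
  representation(centerRow = "numeric", centerCol = "numeric",
                 semiMajor = "numeric", semiMinor = "numeric",
                 orientation = "character"),
  prototype(orientation = "row"))

setValidity("ROISpec", function(object) {
  if (!(object@semiMajor >= object@semiMinor && object@semiMinor > 0))
    return("semi-axes must satisfy semiMajor >= semiMinor > 0")
  if (!object@orientation %in% c("row", "col"))
    return("orientation must be 'row' or 'col'")
  TRUE
})

#' @rdname ROISpec-class
#' @param centerRow,centerCol,semiMajor,semiMinor,orientation see slots
#' @export
ROISpec <- function(centerRow, centerCol, semiMajor, semiMinor,
                    orientation = c("row", "col")) {
  new("ROISpec", centerRow = centerRow, centerCol = centerCol,
      semiMajor = semiMajor, semiMinor = semiMinor,
      orientation = match.arg(orientation))
}

setMethod("show", "ROISpec", function(object) {
  cat(sprintf("ROISpec: center (%g, %g), semi-axes %g x %g px, major axis along %ss\n",
              object@centerRow, object@centerCol, object@semiMajor,
              object@semiMinor, object@orientation))
})

MATURITY_STAGES <- paste0("P", 1:5)

#' Table of sample spectra with quality targets
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"reflectance"}) holds bands x samples reflectance, with band
#' wavelengths in \code{rowData} and the per-sample quality record (FI in N,
#' SSC in %, FSR dimensionless) and maturity stage (P1-P5) in \code{colData}.
#' Construct with \code{\link{SpectrumTable}}.
#'
#' @export
setClass("SpectrumTable", contains = "SummarizedExperiment")

setValidity("SpectrumTable", function(object) {
  a <- assay(object, "reflectance")
  if (anyNA(a)) return("reflectance must not contain NA/NaN")
  if (is.null(rowData(object)$wavelength_nm))
    return("rowData must carry wavelength_nm")
  wl <- rowData(object)$wavelength_nm
  if (length(wl) > 1L && any(diff(wl) <= 0))
    return("wavelengths must be strictly increasing")
  st <- colData(object)$stage
  if (!is.null(st) && !all(is.na(st) | st %in% MATURITY_STAGES))
    return("stage labels must be P1..P5")
  TRUE
})

#' Construct a SpectrumTable
#'
#' Reflectance is clipped into \code{[0, clipUpper]}: negative calibration
#' artifacts are floored at 0, while values above 1 (specular highlights) are
#' retained up to the configurable ceiling.
#'
#' @param spectra N x B matrix, one sample per row
#' @param wavelengths length-B band centers (nm)
#' @param sampleIds optional length-N ids (default "s1".."sN")
#' @param targets optional data.frame with columns FI, SSC and optionally FSR
#'   (recomputed as FI/SSC when absent)
#' @param stage optional length-N maturity labels among P1..P5
#' @param clipUpper reflectance ceiling (default 1.2)
#' @return a \linkS4class{SpectrumTable}
#' @export
SpectrumTable <- function(spectra, wavelengths, sampleIds = NULL,
                          targets = NULL, stage = NULL, clipUpper = 1.2) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths))
    stop("ncol(spectra) must equal length(wavelengths)")
  if (anyNA(spectra)) stop("spectra must not contain NA/NaN")
  spectra <- pmin(pmax(spectra, 0), clipUpper)
  n <- nrow(spectra)
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(n))
  cd <- S4Vectors::DataFrame(sample_id = as.character(sampleIds))
  if (!is.null(targets)) {
    targets <- as.data.frame(targets)
    stopifnot(nrow(targets) == n)
    if (is.null(targets$FSR) && !is.null(targets$FI) && !is.null(targets$SSC))
      targets$FSR <- targets$FI / targets$SSC
    for (cc in intersect(c("FI", "SSC", "FSR"), names(targets)))
      cd[[cc]] <- targets[[cc]]
  }
  if (!is.null(stage)) cd$stage <- as.character(stage)
  se <- SummarizedExperiment(
    assays = list(reflectance = t(spectra)),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = cd)
  colnames(se) <- cd$sample_id
  new("SpectrumTable", se)
}

#' @describeIn SpectrumTable N x B reflectance matrix (samples in rows)
#' @param x a SpectrumTable
#' @export
setMethod("spectra", "SpectrumTable", function(x) t(assay(x, "reflectance")))

#' @describeIn SpectrumTable band wavelengths (nm)
#' @export
setMethod("wavelengths", "SpectrumTable", function(x) rowData(x)$wavelength_nm)

#' @describeIn SpectrumTable maturity stage labels (or NULL)
#' @export
setMethod("stages", "SpectrumTable", function(x) colData(x)$stage)

#' @describeIn SpectrumTable data.frame of FI/SSC/FSR targets present
#' @export
setMethod("qualityData", "SpectrumTable", function(x) {
  cc <- intersect(c("FI", "SSC", "FSR", "stage"), colnames(colData(x)))
  as.data.frame(colData(x)[, cc, drop = FALSE])
})

#' @describeIn SpectrumTable sample identifiers
#' @export
setMethod("sampleIds", "SpectrumTable", function(x) colData(x)$sample_id)

setMethod("show", "SpectrumTable", function(object) {
  wl <- wavelengths(object)
  cat(sprintf("SpectrumTable: %d samples x %d bands (%.1f-%.1f nm)\n",
              ncol(object), nrow(object), min(wl), max(wl)))
  tg <- intersect(c("FI", "SSC", "FSR"), colnames(colData(object)))
  if (length(tg)) cat("targets:", paste(tg, collapse = ", "), "\n")
  st <- stages(object)
  if (!is.null(st)) {
    tb <- table(st)
    cat("stages:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
})

#' Calibration/prediction split assignment
#'
#' Result of \code{\link{stratifiedSpxySplit}}: disjoint ordered index lists
#' covering all samples, with per-stratum counts and the configuration that
#' produced them.
#'
#' @slot calibration,prediction ordered integer sample indices (1-based)
#' @slot perStratum data.frame with columns stage, nCal, nPred
#' @slot config list echo of split parameters
#' @export
setClass("SplitAssignment",
  representation(calibration = "integer", prediction = "integer",
                 perStratum = "data.frame", config = "list"))

setValidity("SplitAssignment", function(object) {
  if (length(intersect(object@calibration, object@prediction)))
    return("calibration and prediction indices must be disjoint")
  TRUE
})

#' @describeIn SplitAssignment-class calibration-set indices
#' @param x a SplitAssignment
#' @export
calibrationIndices <- function(x) x@calibration

#' @describeIn SplitAssignment-class prediction-set indices
#' @export
predictionIndices <- function(x) x@prediction

setMethod("show", "SplitAssignment", function(object) {
  cat(sprintf("SplitAssignment: %d calibration / %d prediction samples\n",
              length(object@calibration), length(object@prediction)))
  if (nrow(object@perStratum)) print(object@perStratum, row.names = FALSE)
})

#' Spectral deep-learning predictor
#'
#' A fitted (or initialized) computational graph for one of the three
#' architectures: \code{"mscnn"} (multiscale CNN with learnable branch
#' fusion), \code{"mscnn_lstm"} (same trunk with a single-step LSTM head) or
#' \code{"resnet18_1d"}. Parameters live in a named list of arrays; band and
#' target standardization statistics captured from the calibration set are
#' stored alongside and applied automatically at prediction time.
#'
#' @slot architecture one of "mscnn", "mscnn_lstm", "resnet18_1d"
#' @slot config architecture geometry echo (list)
#' @slot params named list of parameter arrays (empty until initialized)
#' @slot state named list of non-trainable state (batch-norm running stats)
#' @slot standardization per-band and target statistics (calibration set)
#' @slot fitted logical, whether the graph has been trained
#' @slot history training history (per-epoch losses)
#' @export
setClass("PredictorGraph",
  representation(architecture = "character", config = "list",
                 params = "list", state = "list",
                 standardization = "list", fitted = "logical",
                 history = "list"),
  prototype(fitted = FALSE, params = list(), state = list(),
            standardization = list(), history = list()))

setValidity("PredictorGraph", function(object) {
  if (!object@architecture %in% c("mscnn", "mscnn_lstm", "resnet18_1d"))
    return("unknown architecture")
  TRUE
})

setMethod("show", "PredictorGraph", function(object) {
  cat(sprintf("PredictorGraph <%s>: input length %d, %s\n",
              object@architecture, object@config$inputLength,
              if (object@fitted) sprintf("fitted (%d epochs)",
                                         length(object@history$train))
              else if (length(object@params)) "initialized" else "unbuilt"))
})
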