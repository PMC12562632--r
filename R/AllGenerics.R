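#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @export
setGeneric("qualityData", function(x) standardGeneric("qualityData"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Restrict a spectral object to a wavelength window
#'
#' Retains bands with \code{loNm <= lambda <= hiNm} (both endpoints
#' inclusive), preserving band order and all sample annotations.
#'
#' @param x a \linkS4class{SpectrumTable} or \linkS4class{Hypercube}
#' @param loNm,hiNm window limits in nm (\code{loNm < hiNm})
#' @return an object of the same class with only the in-window bands
#' @export
setGeneric("truncateBands", function(x, loNm, hiNm) standardGeneric("truncateBands"))
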