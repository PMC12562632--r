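#' Write a SpectrumTable as delimited text
#'
#' Column layout: \code{id,stage,FI,SSC,FSR,wl_<nm>,...}; target/stage
#' columns are emitted only when present.
#'
#' @param table a \linkS4class{SpectrumTable}
#' @param path output CSV path
#' @return invisibly, \code{path}
#' @export
writeSpectrumTable <- function(table, path) {
  stopifnot(is(table, "SpectrumTable"))
  q <- qualityData(table)
  df <- data.frame(id = sampleIds(table), stringsAsFactors = FALSE)
  for (cc in c("stage", "FI", "SSC", "FSR"))
    if (!is.null(q[[cc]])) df[[cc]] <- q[[cc]]
  sp <- spectra(table)
  colnames(sp) <- paste0("wl_", sprintf("%.10g", wavelengths(table)))
  write.csv(cbind(df, sp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SpectrumTable from delimited text
#'
#' Inverse of \code{\link{writeSpectrumTable}}: wavelength columns are
#' recognised by the \code{wl_} prefix, everything else is sample annotation.
#'
#' @param path CSV path
#' @param clipUpper reflectance ceiling passed to \code{\link{SpectrumTable}}
#' @return a \linkS4class{SpectrumTable}
#' @export
readSpectrumTable <- function(path, clipUpper = 1.2) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wlCols <- grep("^wl_", names(df), value = TRUE)
  if (!length(wlCols)) stop("format error: no wl_<nm> columns in ", path)
  wl <- as.numeric(sub("^wl_", "", wlCols))
  targets <- df[intersect(c("FI", "SSC", "FSR"), names(df))]
  SpectrumTable(as.matrix(df[wlCols]), wl,
                sampleIds = if ("id" %in% names(df)) df$id else NULL,
                targets = if (ncol(targets)) targets else NULL,
                stage = if ("stage" %in% names(df)) df$stage else NULL,
                clipUpper = clipUpper)
}

## target column fetch shared by models/metrics
.targetVector <- function(table, target = c("FI", "SSC", "FSR")) {
  target <- match.arg(target)
  y <- colData(table)[[target]]
  if (is.null(y)) stop("contract error: target column ", target, " absent")
  as.numeric(y)
}
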