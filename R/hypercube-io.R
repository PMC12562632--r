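## ENVI-style cube I/O: text header (samples/lines/bands/data type/interleave/
## wavelength) + flat binary data file. Only the keys this pipeline needs are
## supported; the header grammar follows the de-facto ENVI conventions.

.enviDataTypes <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE))

.parseEnviHeader <- function(headerPath) {
  lines <- readLines(headerPath, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  out <- list()
  # scan key = value, where value is either till end-of-line or a {...} block
  pat <- "(?m)^\\s*([A-Za-z][A-Za-z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("not an ENVI-style header: ", headerPath)
  starts <- as.vector(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("^\\s*([A-Za-z][A-Za-z0-9 _]*?)\\s*=.*$", "\\1",
                              piece, perl = TRUE)))
    val <- trimws(sub("^[^=]*=\\s*", "", piece))
    out[[key]] <- val
  }
  out
}

.headerNumList <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(strsplit(val, ",")[[1]])
}

#' Read an ENVI-style hyperspectral cube
#'
#' Reads a text header + binary data pair. The header must declare
#' \code{samples} (columns), \code{lines} (rows), \code{bands},
#' \code{data type} and a \code{wavelength} list in nm; \code{interleave}
#' (bsq/bil/bip, default bsq) and \code{byte order} (default 0, little
#' endian) are honoured.
#'
#' @param headerPath path to the header file; the data file is taken from the
#'   header's basename with the \code{.hdr} extension stripped (or
#'   \code{.dat} appended) unless \code{dataPath} is given
#' @param dataPath optional explicit path to the binary data file
#' @return a \linkS4class{Hypercube}
#' @export
readEnviCube <- function(headerPath, dataPath = NULL) {
  if (!file.exists(headerPath)) stop("header file not found: ", headerPath)
  h <- .parseEnviHeader(headerPath)
  need <- c("samples", "lines", "bands", "data type", "wavelength")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("header missing keys: ", paste(miss, collapse = ", "))
  ns <- as.integer(h$samples); nl <- as.integer(h$lines); nb <- as.integer(h$bands)
  wl <- .headerNumList(h$wavelength)
  if (length(wl) != nb)
    stop("format error: wavelength list length (", length(wl),
         ") does not match bands (", nb, ")")
  if (is.null(dataPath)) {
    cand <- c(sub("\\.hdr$", "", headerPath),
              sub("\\.hdr$", ".dat", headerPath),
              paste0(headerPath, ".dat"))
    cand <- cand[cand != headerPath]
    dataPath <- cand[file.exists(cand)][1]
    if (is.na(dataPath)) stop("data file not found for header: ", headerPath)
  }
  if (!file.exists(dataPath)) stop("data file not found: ", dataPath)
  dt <- .enviDataTypes[[as.character(as.integer(h[["data type"]]))]]
  if (is.null(dt)) stop("unsupported data type: ", h[["data type"]])
  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1L)
    "big" else "little"
  nvals <- as.numeric(ns) * nl * nb
  avail <- file.size(dataPath) / dt$size
  if (avail != nvals)
    stop("format error: data file holds ", avail,
         " values but header declares ", nvals)
  con <- file(dataPath, "rb"); on.exit(close(con))
  v <- readBin(con, what = dt$what, n = nvals, size = dt$size,
               signed = dt$signed, endian = endian)
  il <- tolower(if (is.null(h$interleave)) "bsq" else h$interleave)
  a <- switch(il,
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3, 2, 1)),
    stop("unsupported interleave: ", il))
  meta <- h[setdiff(names(h), c(need, "interleave", "byte order"))]
  Hypercube(a, wl, metadata = lapply(meta, as.character))
}

#' Write an ENVI-style hyperspectral cube
#'
#' @param cube a \linkS4class{Hypercube}
#' @param headerPath output header path (conventionally \code{*.hdr})
#' @param dataPath output binary path (default: header minus \code{.hdr})
#' @param dataType ENVI data-type code: 4 (float32) or 5 (float64)
#' @return invisibly, the two paths written
#' @export
writeEnviCube <- function(cube, headerPath,
                          dataPath = sub("\\.hdr$", "", headerPath),
                          dataType = 4L) {
  stopifnot(is(cube, "Hypercube"))
  if (identical(dataPath, headerPath)) dataPath <- paste0(headerPath, ".dat")
  d <- dim(cube@data)
  size <- .enviDataTypes[[as.character(dataType)]]$size
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           paste0("data type = ", dataType),
           "interleave = bsq",
           "byte order = 0",
           paste0("wavelength = { ",
                  paste(sprintf("%.10g", cube@wavelengths), collapse = ", "),
                  " }"))
  writeLines(hdr, headerPath)
  v <- as.vector(aperm(cube@data, c(2, 1, 3)))  # bsq: sample, line, band
  con <- file(dataPath, "wb"); on.exit(close(con))
  writeBin(as.numeric(v), con, size = size, endian = "little")
  invisible(c(header = headerPath, data = dataPath))
}
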