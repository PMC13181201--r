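# File formats: NPY arrays (interchange with the Python stack), PNG
# previews with a JSON scaling sidecar, CSV encodings/histories, JSON
# specs/geometry/reports, YAML run configurations, RDS checkpoints.

#' Write a numeric matrix as NPY
#'
#' Minimal NPY (version 1.0) writer for 1- and 2-D double arrays,
#' column-major (\code{fortran_order}), readable by numpy.
#'
#' @param x numeric vector or matrix
#' @param path output file
#' @return the path, invisibly
#' @export
writeNpy <- function(x, path) {
  shape <- if (is.matrix(x)) sprintf("(%d, %d)", nrow(x), ncol(x))
           else sprintf("(%d,)", length(x))
  hdr <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': %s, }",
                 shape)
  total <- 10L + nchar(hdr) + 1L
  padlen <- (64L - total %% 64L) %% 64L
  hdr <- paste0(hdr, strrep(" ", padlen), "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2, endian = "little")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NPY array
#'
#' Supports little-endian float32/float64 and int32/int64, 1- or 2-D, in
#' either storage order.
#'
#' @param path NPY file
#' @return numeric vector or matrix
#' @export
readNpy <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, utf8ToInt("NUMPY")))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else readBin(con, "integer", 1, size = 2, signed = FALSE,
               endian = "little")
  hdr <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", hdr)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  nel <- prod(shape)
  x <- switch(descr,
    "<f8" = readBin(con, "numeric", nel, size = 8, endian = "little"),
    "<f4" = readBin(con, "numeric", nel, size = 4, endian = "little"),
    "<i4" = readBin(con, "integer", nel, size = 4, endian = "little"),
    "<i8" = readBin(con, "numeric", nel, size = 8, endian = "little"),
    stop("unsupported NPY dtype: ", descr))
  if (length(shape) == 1L) return(x)
  if (length(shape) != 2L) stop("only 1- and 2-D NPY arrays are supported")
  if (fortran) matrix(x, shape[1], shape[2])
  else t(matrix(x, shape[2], shape[1]))
}

#' Write an image preview as PNG with a scaling sidecar
#'
#' Values are scaled linearly from [lo, hi] (the data range by default) to
#' the PNG range; the scaling is recorded in \code{<path>.json} so the
#' preview is invertible to its quantisation precision. Full-precision
#' data should travel as NPY.
#'
#' @param image a \linkS4class{CTImage} or matrix
#' @param path output PNG file
#' @param lo,hi scaling bounds; default the image's own range
#' @return the path, invisibly
#' @export
writeImagePNG <- function(image, path, lo = NULL, hi = NULL) {
  m <- .asMat(image)
  if (is.null(lo)) lo <- min(m)
  if (is.null(hi)) hi <- max(m)
  if (hi <= lo) hi <- lo + 1
  png::writePNG(pmin(pmax((m - lo) / (hi - lo), 0), 1), path)
  jsonlite::write_json(list(lo = lo, hi = hi),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a PNG preview back using its scaling sidecar
#' @param path PNG file written by \code{\link{writeImagePNG}}
#' @return numeric matrix on the original scale
#' @export
readImagePNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side)
    m <- m * (sc$hi - sc$lo) + sc$lo
  }
  m
}

#' Save / load a sinogram as NPY plus a geometry JSON sidecar
#' @param sino a \linkS4class{Sinogram}
#' @param path NPY path (sidecar at \code{<path>.json})
#' @return the path (save) or a \linkS4class{Sinogram} (load)
#' @export
saveSinogram <- function(sino, path) {
  writeNpy(sino@values, path)
  g <- sino@geometry
  jsonlite::write_json(list(nDetectors = g@nDetectors, nAngles = g@nAngles,
                            detectorSpacing = g@detectorSpacing),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveSinogram
#' @export
loadSinogram <- function(path) {
  g <- jsonlite::read_json(paste0(path, ".json"))
  sinogram(readNpy(path),
           ctGeometry(g$nDetectors, g$nAngles, g$detectorSpacing))
}

#' Write / read a sampling code as CSV (index, e)
#' @param encoding a \linkS4class{ProjectionEncoding}
#' @param path CSV file
#' @export
writeEncodingCSV <- function(encoding, path) {
  write.csv(data.frame(index = seq_along(encoding@e), e = encoding@e),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEncodingCSV
#' @export
readEncodingCSV <- function(path) {
  projectionEncoding(read.csv(path)$e)
}

#' Save / load a phantom specification as JSON
#' @param spec a \linkS4class{PhantomSpec}
#' @param path JSON file
#' @export
savePhantomSpec <- function(spec, path) {
  jsonlite::write_json(spec@ellipses, path, digits = NA)
  invisible(path)
}

#' @rdname savePhantomSpec
#' @export
loadPhantomSpec <- function(path) {
  e <- jsonlite::fromJSON(path)
  if (length(e) == 0)
    return(phantomSpec())
  phantomSpec(as.data.frame(e))
}

#' Save / load a trained joint model checkpoint
#'
#' One archive per run: the three parameter groups, the geometry and a
#' configuration echo. RDS is a run-time artifact format; experiment
#' inputs and reports use the plain-text formats.
#'
#' @param model a \linkS4class{JointModel}
#' @param path checkpoint file
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' Write a training history as CSV
#' @param history data.frame from the training functions
#' @param path CSV file
#' @export
writeHistoryCSV <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}
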