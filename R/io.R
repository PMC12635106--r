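#' Read an OPD or phase image
#'
#' 32-bit float TIFF or whitespace-delimited plain-text matrix.  Pixel
#' size and wavelength are acquisition metadata and must be supplied by
#' the caller; the file holds only the values (nm for OPD, radians for
#' phase).
#'
#' @param path file path (.tif/.tiff or text matrix).
#' @param pixelSize pixel size (nm).
#' @param kind "opd" (default) or "phase".
#' @param wavelength wavelength (nm), required for phase input.
#' @return an [OpdImage-class] or [PhaseImage-class].
#' @export
readOpdImage <- function(path, pixelSize, kind = c("opd", "phase"),
                         wavelength = NULL) {
  kind <- match.arg(kind)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    v <- matrix(as.numeric(v), nrow(v), ncol(v))
    rangeFile <- paste0(path, ".range")
    if (file.exists(rangeFile)) {       # unpack the affine value encoding
      lohi <- scan(rangeFile, quiet = TRUE)
      v <- v * (lohi[2] - lohi[1]) + lohi[1]
    }
  } else {
    v <- as.matrix(utils::read.table(path))
    dimnames(v) <- NULL
  }
  if (kind == "phase") {
    if (is.null(wavelength)) stop("phase input requires a wavelength")
    PhaseImage(v, wavelength = wavelength, pixelSize = pixelSize)
  } else {
    OpdImage(v, pixelSize = pixelSize)
  }
}

#' Write an OPD image as 32-bit float TIFF
#'
#' TIFF samples are stored in [0, 1] (the writer's value contract), so the
#' OPD values are affinely rescaled and the original range is written to a
#' sidecar text file `<path>.range` (two numbers: min and max, nm).
#' [readOpdImage()] detects the sidecar and restores physical values; a
#' TIFF without one is read as raw nm.
#'
#' @param opd an [OpdImage-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeOpdTiff <- function(opd, path) {
  stopifnot(is(opd, "OpdImage"))
  v <- opd@values
  lo <- min(v); hi <- max(v)
  if (hi <= lo) hi <- lo + 1
  tiff::writeTIFF((v - lo) / (hi - lo), path, bits.per.sample = 32L,
                  reduce = TRUE)
  writeLines(format(c(lo, hi), digits = 17), paste0(path, ".range"))
  invisible(path)
}

#' Write a binary mask as 8-bit TIFF (0/255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMaskTiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Write a feature or mass table as CSV with a units header
#'
#' @param tab a data.frame.
#' @param path output path.
#' @param comment a header comment line (units/provenance), written
#'   prefixed with '#'.
#' @return the path, invisibly.
#' @export
writeTableCsv <- function(tab, path,
                          comment = "units: um/um2 for geometry, nm for OPD, fg for mass") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
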