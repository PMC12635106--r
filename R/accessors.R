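#' Accessors for image and model objects
#'
#' `opdValues` returns the OPD (or phase) matrix, `pixelSize` the physical
#' pixel size in nm, `isLeveled`/`isSmoothed` the processing state flags.
#' `bgSurface` and `bgOrder` expose the fitted background surface and its
#' total degree.
#'
#' @param object a [PhaseImage-class], [OpdImage-class] or
#'   [BackgroundModel-class].
#' @return the requested slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("opdValues", function(object) standardGeneric("opdValues"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("isLeveled", function(object) standardGeneric("isLeveled"))
#' @rdname accessors
#' @export
setGeneric("isSmoothed", function(object) standardGeneric("isSmoothed"))
#' @rdname accessors
#' @export
setGeneric("bgSurface", function(object) standardGeneric("bgSurface"))
#' @rdname accessors
#' @export
setGeneric("bgOrder", function(object) standardGeneric("bgOrder"))

#' @rdname accessors
setMethod("opdValues", "OpdImage", function(object) object@values)
#' @rdname accessors
setMethod("opdValues", "PhaseImage", function(object) object@values)
#' @rdname accessors
setMethod("pixelSize", "OpdImage", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "PhaseImage", function(object) object@pixelSize)
#' @rdname accessors
setMethod("isLeveled", "OpdImage", function(object) object@leveled)
#' @rdname accessors
setMethod("isSmoothed", "OpdImage", function(object) object@smoothed)
#' @rdname accessors
setMethod("bgSurface", "BackgroundModel", function(object) object@surface)
#' @rdname accessors
setMethod("bgOrder", "BackgroundModel", function(object) object@order)

#' Construct a PhaseImage
#'
#' @param values numeric matrix of phase shifts (radians).
#' @param wavelength illumination wavelength (nm).
#' @param pixelSize physical pixel size at the sample plane (nm).
#' @return a [PhaseImage-class].
#' @examples
#' ph <- PhaseImage(matrix(0.1, 8, 8), wavelength = 666, pixelSize = 90.6)
#' @export
PhaseImage <- function(values, wavelength, pixelSize) {
  bad <- which(!is.finite(values))
  if (length(bad)) {
    idx <- arrayInd(utils::head(bad, 5L), dim(values))
    stop(sprintf("non-finite phase values at %d pixel(s), first at (row,col): %s",
                 length(bad),
                 paste(apply(idx, 1L, function(r) sprintf("(%d,%d)", r[1], r[2])),
                       collapse = " ")))
  }
  new("PhaseImage", values = values, wavelength = as.numeric(wavelength),
      pixelSize = as.numeric(pixelSize))
}

#' Construct an OpdImage
#'
#' @param values numeric matrix of OPD (nm).
#' @param pixelSize physical pixel size (nm).
#' @param leveled,smoothed processing state flags.
#' @return an [OpdImage-class].
#' @examples
#' opd <- OpdImage(matrix(0, 16, 16), pixelSize = 90.6)
#' @export
OpdImage <- function(values, pixelSize, leveled = FALSE, smoothed = FALSE) {
  new("OpdImage", values = values, pixelSize = as.numeric(pixelSize),
      leveled = leveled, smoothed = smoothed)
}
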