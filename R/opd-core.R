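#' Convert a phase image to optical path difference
#'
#' OPD(x,y) = lambda / (2*pi) * phi(x,y).  The phase delay accumulated
#' through a cell, expressed as a physical length in nm, is proportional to
#' the dry-mass surface density through the refractive index increment.
#'
#' @param phase a [PhaseImage-class].
#' @return an [OpdImage-class] with both state flags FALSE.
#' @examples
#' ph <- PhaseImage(matrix(pi, 8, 8), wavelength = 500, pixelSize = 90.6)
#' range(opdValues(phaseToOpd(ph)))  # 250 nm everywhere
#' @export
phaseToOpd <- function(phase) {
  stopifnot(is(phase, "PhaseImage"))
  OpdImage(phase@wavelength / (2 * pi) * phase@values, phase@pixelSize)
}

## 1-D polynomial basis orthonormalized on the actual pixel grid: QR of the
## Vandermonde in the scaled coordinate.  Columns span exactly the
## polynomials of degree 0..deg and are orthonormal in the discrete inner
## product, so tensor least squares reduces to an orthogonal projection.
.orthoBasis <- function(n, deg) {
  if (deg > n - 1L)
    stop(sprintf("polynomial degree %d needs at least %d grid points, have %d",
                 deg, deg + 1L, n))
  x <- if (n == 1L) 0 else seq(-1, 1, length.out = n)
  V <- outer(x, 0:deg, `^`)
  qr.Q(qr(V))
}

#' Level the image background with a 2-D polynomial surface fit
#'
#' Fits a bivariate polynomial of total degree `order` to the whole image
#' by least squares and subtracts it, removing smooth aberrations
#' (curvature, tilt, uneven illumination).  Cells are not excluded from the
#' fit: they occupy a negligible fraction of the field of view.  The fit is
#' computed as an exact orthogonal projection on a basis of 1-D polynomials
#' orthonormalized on the pixel grid, so it is numerically stable at any
#' order and nested across orders.
#'
#' @param opd an [OpdImage-class].
#' @param order total polynomial degree N (default 16).
#' @return a list with elements `opd` (the residual image, flagged as
#'   leveled) and `model` (a [BackgroundModel-class]).
#' @examples
#' img <- OpdImage(matrix(50, 32, 32), pixelSize = 90.6)
#' lv <- levelBackground(img, order = 2)
#' max(abs(opdValues(lv$opd)))  # ~0: a constant is degree 0
#' @export
levelBackground <- function(opd, order = 16L) {
  stopifnot(is(opd, "OpdImage"))
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  Z <- opd@values
  if (order > min(dim(Z)) - 1L)
    stop(sprintf("order %d is degenerate for a %d x %d image", order,
                 nrow(Z), ncol(Z)))
  Px <- .orthoBasis(nrow(Z), order)
  Py <- .orthoBasis(ncol(Z), order)
  C <- crossprod(Px, Z) %*% Py
  keep <- outer(0:order, 0:order, `+`) <= order
  C[!keep] <- 0
  surface <- Px %*% C %*% t(Py)
  ij <- which(keep, arr.ind = TRUE) - 1L
  coefs <- data.frame(degree_row = ij[, 1L], degree_col = ij[, 2L],
                      coefficient = C[keep])
  model <- new("BackgroundModel", order = order, coefficients = coefs,
               surface = surface)
  out <- OpdImage(Z - surface, opd@pixelSize, leveled = TRUE,
                  smoothed = opd@smoothed)
  list(opd = out, model = model)
}

## Separable convolution with an odd symmetric 1-D kernel, reflective
## boundaries ("abc|cba"), applied along rows then columns via band
## operators.  Each output pixel's weights sum to 1 when `w` does.
.reflectIdx <- function(m, n) {
  m <- ((m - 1L) %% (2L * n))
  ifelse(m < n, m + 1L, 2L * n - m)
}

.bandOperator <- function(n, w) {
  t <- (length(w) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (k in -t:t) {
    j <- .reflectIdx(seq_len(n) + k, n)
    A[cbind(seq_len(n), j)] <- A[cbind(seq_len(n), j)] + w[k + t + 1L]
  }
  A
}

.sepConv <- function(Z, w) {
  Ar <- .bandOperator(nrow(Z), w)
  Ac <- .bandOperator(ncol(Z), w)
  Ar %*% Z %*% t(Ac)
}

.gaussKernel1d <- function(sigma, halfwidth = ceiling(3 * sigma)) {
  x <- -halfwidth:halfwidth
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing of an OPD image
#'
#' Convolves the image with a normalized, separable Gaussian kernel of
#' standard deviation `radius` pixels, truncated at 3 sigma, with
#' reflective boundary handling.  Removes high-frequency noise while
#' preserving the integrated OPD (hence the dry mass) of structures away
#' from the borders.
#'
#' @param opd an [OpdImage-class].
#' @param radius kernel standard deviation in pixels (default 4).
#' @return the smoothed [OpdImage-class], flagged as smoothed.
#' @export
gaussianSmooth <- function(opd, radius = 4) {
  stopifnot(is(opd, "OpdImage"))
  if (radius <= 0) stop("radius must be > 0")
  w <- .gaussKernel1d(radius)
  OpdImage(.sepConv(opd@values, w), opd@pixelSize,
           leveled = opd@leveled, smoothed = TRUE)
}

#' Normalized 2-D Fourier magnitude spectrum in dB
#'
#' Computes the 2-D discrete Fourier transform of the image, shifts the
#' zero frequency to the center, normalizes the magnitude to its maximum
#' and expresses it as 20*log10 (dB).  Spatial frequency axes are in 1/um,
#' derived from the physical pixel size.
#'
#' @param opd an [OpdImage-class].
#' @return a list with `db` (matrix, dB), `kx` (row-frequency axis, 1/um)
#'   and `ky` (column-frequency axis, 1/um).
#' @export
spectrumDb <- function(opd) {
  stopifnot(is(opd, "OpdImage"))
  Z <- opd@values
  mag <- Mod(stats::fft(Z))
  shift1 <- function(v, n) c(v[(floor(n / 2) + 1L):n], v[seq_len(floor(n / 2))])
  nr <- nrow(Z); nc <- ncol(Z)
  mag <- mag[shift1(seq_len(nr), nr), shift1(seq_len(nc), nc), drop = FALSE]
  p_um <- opd@pixelSize / 1000
  freqAxis <- function(n) (seq_len(n) - 1L - floor(n / 2)) / (n * p_um)
  db <- 20 * log10(pmax(mag / max(mag), .Machine$double.xmin))
  list(db = db, kx = freqAxis(nr), ky = freqAxis(nc))
}

#' Background OPD noise statistics
#'
#' Mean and sample standard deviation of the OPD over background pixels.
#' With an exclusion mask (TRUE = cell pixel) the statistics are computed
#' over cell-free pixels only; this standard deviation is the per-image OPD
#' uncertainty used in the dry-mass error propagation.
#'
#' @param opd an [OpdImage-class].
#' @param excludeMask optional logical matrix marking cell pixels to drop.
#' @return a [NoiseStats-class].
#' @export
backgroundNoise <- function(opd, excludeMask = NULL) {
  stopifnot(is(opd, "OpdImage"))
  v <- opd@values
  kind <- "whole-image"
  if (!is.null(excludeMask)) {
    if (!identical(dim(excludeMask), dim(v)))
      stop("excludeMask shape must match the image")
    v <- v[!excludeMask]
    kind <- "cell-free"
  }
  if (length(v) < 2L) stop("fewer than 2 retained pixels")
  new("NoiseStats", mean = mean(v), sd = stats::sd(v),
      nPixels = length(v), regionKind = kind)
}

#' Relative OPD standard-deviation reduction versus polynomial order
#'
#' For each candidate leveling order, computes 100 * (1 - sd(residual) /
#' sd(raw)): the fraction of the image's OPD variability explained by the
#' fitted polynomial background.  Non-decreasing in the order because the
#' polynomial spaces are nested.
#'
#' @param opd an [OpdImage-class] (raw, unleveled).
#' @param orders integer vector of total degrees to evaluate.
#' @return a data.frame with columns `order` and `reduction_pct`.
#' @export
stdReductionCurve <- function(opd, orders) {
  stopifnot(is(opd, "OpdImage"), length(orders) >= 1L)
  raw_sd <- stats::sd(as.vector(opd@values))
  red <- vapply(as.integer(orders), function(N) {
    res <- levelBackground(opd, N)$opd@values
    100 * (1 - stats::sd(as.vector(res)) / raw_sd)
  }, numeric(1))
  data.frame(order = as.integer(orders), reduction_pct = red)
}
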