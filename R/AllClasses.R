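#' @import methods
NULL

.check_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) return(sprintf("%s must be a numeric matrix", what))
  if (nrow(x) < 1L || ncol(x) < 1L) return(sprintf("%s must be non-empty", what))
  if (!all(is.finite(x))) return(sprintf("%s contains non-finite values", what))
  NULL
}

#' PhaseImage: a calibrated 2-D phase map
#'
#' Holds a reconstructed phase image (radians) together with the acquisition
#' metadata needed downstream: illumination wavelength and physical pixel
#' size at the sample plane, both in nanometers.
#'
#' @slot values numeric matrix of phase shifts (radians), row-major with
#'   origin at the top-left.
#' @slot wavelength illumination wavelength lambda (nm).
#' @slot pixelSize physical pixel size p at the sample plane (nm).
#' @export
setClass("PhaseImage",
  representation(values = "matrix", wavelength = "numeric", pixelSize = "numeric"),
  validity = function(object) {
    msg <- .check_matrix(object@values, "phase values")
    if (!is.null(msg)) return(msg)
    if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
        object@wavelength <= 0) return("wavelength must be a single positive number (nm)")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) return("pixelSize must be a single positive number (nm)")
    TRUE
  })

#' OpdImage: a 2-D optical path difference field
#'
#' The central measurement object: OPD in nanometers on a regular pixel
#' grid.  Two state flags record whether background leveling and Gaussian
#' smoothing have been applied, so downstream steps can warn when run on
#' unprocessed data.
#'
#' @slot values numeric matrix of OPD (nm).
#' @slot pixelSize physical pixel size (nm).
#' @slot leveled logical, TRUE after background leveling.
#' @slot smoothed logical, TRUE after Gaussian smoothing.
#' @export
setClass("OpdImage",
  representation(values = "matrix", pixelSize = "numeric",
                 leveled = "logical", smoothed = "logical"),
  prototype(leveled = FALSE, smoothed = FALSE),
  validity = function(object) {
    msg <- .check_matrix(object@values, "OPD values")
    if (!is.null(msg)) return(msg)
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) return("pixelSize must be a single positive number (nm)")
    if (length(object@leveled) != 1L || length(object@smoothed) != 1L)
      return("state flags must be single logicals")
    TRUE
  })

#' BackgroundModel: fitted 2-D polynomial background surface
#'
#' Result of least-squares background leveling.  The fit uses a bivariate
#' polynomial space of total degree <= order, represented in a basis of 1-D
#' polynomials orthonormalized on the pixel grid, so `coefficients` are
#' projection coefficients (one per basis function, (order+1)(order+2)/2 in
#' total).
#'
#' @slot order total polynomial degree N (integer >= 0).
#' @slot coefficients data.frame with columns `degree_row`, `degree_col`,
#'   `coefficient`.
#' @slot surface evaluated background surface (nm), same shape as the image.
#' @export
setClass("BackgroundModel",
  representation(order = "integer", coefficients = "data.frame", surface = "matrix"),
  validity = function(object) {
    N <- object@order
    if (length(N) != 1L || is.na(N) || N < 0L) return("order must be a single integer >= 0")
    expected <- (N + 1L) * (N + 2L) / 2L
    if (nrow(object@coefficients) != expected)
      return(sprintf("expected %d coefficients for order %d, got %d",
                     expected, N, nrow(object@coefficients)))
    TRUE
  })

#' NoiseStats: background OPD noise statistics
#'
#' Mean and sample standard deviation of the OPD over background pixels,
#' used as the per-image OPD uncertainty (delta_OPD) in mass error
#' propagation.  `regionKind` records whether cell pixels were excluded
#' ("cell-free") or the whole image was used ("whole-image").
#'
#' @slot mean mean OPD over retained pixels (nm).
#' @slot sd sample standard deviation (nm).
#' @slot nPixels number of retained pixels.
#' @slot regionKind "whole-image" or "cell-free".
#' @export
setClass("NoiseStats",
  representation(mean = "numeric", sd = "numeric", nPixels = "integer",
                 regionKind = "character"),
  validity = function(object) {
    if (object@nPixels < 2L) return("need at least 2 pixels for noise statistics")
    if (!is.finite(object@sd) || object@sd < 0) return("sd must be finite and >= 0")
    if (!object@regionKind %in% c("whole-image", "cell-free"))
      return("regionKind must be 'whole-image' or 'cell-free'")
    TRUE
  })

#' MixtureModel: 1-D Gaussian mixture fitted by EM
#'
#' Components are sorted by descending mean, so for the two-component
#' circularity model component 1 is the high-circularity "singles" mode.
#'
#' @slot K number of components.
#' @slot weight,mean,sd per-component parameters (descending mean order).
#' @slot logLik maximized log-likelihood.
#' @slot aic,bic penalized-likelihood criteria with 3K-1 free parameters.
#' @slot n number of observations.
#' @slot converged logical, EM convergence flag.
#' @slot seed seed used for the restarts.
#' @export
setClass("MixtureModel",
  representation(K = "integer", weight = "numeric", mean = "numeric",
                 sd = "numeric", logLik = "numeric", aic = "numeric",
                 bic = "numeric", n = "integer", converged = "logical",
                 seed = "integer"),
  validity = function(object) {
    K <- object@K
    if (length(object@weight) != K || length(object@mean) != K || length(object@sd) != K)
      return("component parameter vectors must have length K")
    if (abs(sum(object@weight) - 1) > 1e-8) return("weights must sum to 1")
    if (any(object@sd <= 0)) return("component sds must be positive")
    if (K > 1 && any(diff(object@mean) > 1e-12))
      return("components must be sorted by descending mean")
    TRUE
  })

#' RegressionFit: simple linear regression summary
#'
#' Ordinary least squares of one response on one predictor, with standard
#' errors and goodness-of-fit diagnostics.  Used for the bacillus
#' length-vs-dry-mass relation.
#'
#' @slot slope,intercept fitted coefficients (length in um, mass in fg, so
#'   slope is um/fg).
#' @slot slopeSE,interceptSE standard errors.
#' @slot pearsonR Pearson correlation coefficient.
#' @slot rSquared coefficient of determination.
#' @slot rss residual sum of squares.
#' @slot n,dof sample size and residual degrees of freedom (n - 2).
#' @export
setClass("RegressionFit",
  representation(slope = "numeric", intercept = "numeric", slopeSE = "numeric",
                 interceptSE = "numeric", pearsonR = "numeric", rSquared = "numeric",
                 rss = "numeric", n = "integer", dof = "integer"),
  validity = function(object) {
    if (object@dof != object@n - 2L) return("dof must equal n - 2")
    TRUE
  })

#' DivisionModel: Koch-Schaechter steady-state size model
#'
#' Parameters of the steady-state dry-mass density for an asynchronous,
#' binary-dividing population: theta(m) = A/(2 m^2) * (erf((mu_div - m) /
#' (sqrt(2) sigma_div)) - erf((mu_div - 2m)/(sqrt(2) sigma_div))), with A a
#' normalization constant computed by quadrature.
#'
#' @slot muDiv mean division mass (fg).
#' @slot sigmaDiv standard deviation of the division mass (fg).
#' @slot A normalization constant.
#' @slot cv coefficient of variation of the division mass (%).
#' @slot fitRSquared R-squared of the fitted density against a
#'   Freedman-Diaconis-binned histogram (NA when the model was not fitted
#'   to data).
#' @slot converged optimizer convergence flag (TRUE for directly
#'   constructed models).
#' @export
setClass("DivisionModel",
  representation(muDiv = "numeric", sigmaDiv = "numeric", A = "numeric",
                 cv = "numeric", fitRSquared = "numeric", converged = "logical"),
  validity = function(object) {
    if (object@muDiv <= 0) return("muDiv must be positive")
    if (object@sigmaDiv < 0) return("sigmaDiv must be >= 0")
    TRUE
  })

#' DistributionComparison: EMD between two mass distributions
#'
#' @slot emd Earth Mover's Distance between the observed samples (fg).
#' @slot bootstrapEmds per-resample EMD values (fg), length B.
#' @slot B number of bootstrap resamples.
#' @slot meanEmd,ciLower,ciUpper bootstrap mean and central 95% interval (fg).
#' @slot seed seed used for resampling.
#' @export
setClass("DistributionComparison",
  representation(emd = "numeric", bootstrapEmds = "numeric", B = "integer",
                 meanEmd = "numeric", ciLower = "numeric", ciUpper = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@emd < 0) return("emd must be >= 0")
    if (length(object@bootstrapEmds) && length(object@bootstrapEmds) != object@B)
      return("bootstrapEmds must have length B")
    TRUE
  })

#' LabelMap: labeled segmentation of an OPD image
#'
#' Integer-valued matrix where 0 is background and 1..nLabels index
#' connected cell regions, numbered by raster order (column-major) of each
#' region's first pixel.
#'
#' @slot values integer matrix of labels.
#' @slot nLabels number of labels.
#' @slot pixelSize physical pixel size (nm).
#' @slot borderTouching logical vector of length nLabels: TRUE when the
#'   region touches the image border.
#' @export
setClass("LabelMap",
  representation(values = "matrix", nLabels = "integer", pixelSize = "numeric",
                 borderTouching = "logical"),
  validity = function(object) {
    lab <- sort(unique(as.integer(object@values)))
    lab <- lab[lab > 0L]
    if (length(lab) != object@nLabels ||
        (length(lab) && !identical(lab, seq_len(object@nLabels))))
      return("labels must be 1..nLabels with no gaps")
    if (length(object@borderTouching) != object@nLabels)
      return("borderTouching must have one entry per label")
    TRUE
  })

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %d region(s) on %d x %d px (%d border-touching)\n",
              object@nLabels, nrow(object@values), ncol(object@values),
              sum(object@borderTouching)))
})

#' SceneTruth: analytic ground truth for a synthetic scene
#'
#' @slot cells data.frame with one row per generated cell: kind, analytic
#'   geometry (um), refractive contrast, and true dry mass (fg).
#' @slot mask integer label matrix of true cell supports (0 = background).
#' @slot background the noiseless background surface (nm).
#' @export
setClass("SceneTruth",
  representation(cells = "data.frame", mask = "matrix", background = "matrix"))

setMethod("show", "PhaseImage", function(object) {
  cat(sprintf("PhaseImage: %d x %d px, lambda = %g nm, pixel = %g nm\n",
              nrow(object@values), ncol(object@values),
              object@wavelength, object@pixelSize))
  cat(sprintf("  phase range [%.3g, %.3g] rad\n",
              min(object@values), max(object@values)))
})

setMethod("show", "OpdImage", function(object) {
  cat(sprintf("OpdImage: %d x %d px, pixel = %g nm [leveled: %s, smoothed: %s]\n",
              nrow(object@values), ncol(object@values), object@pixelSize,
              object@leveled, object@smoothed))
  cat(sprintf("  OPD range [%.3g, %.3g] nm\n", min(object@values), max(object@values)))
})

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf("BackgroundModel: total degree %d (%d basis functions)\n",
              object@order, nrow(object@coefficients)))
  cat(sprintf("  surface range [%.3g, %.3g] nm\n",
              min(object@surface), max(object@surface)))
})

setMethod("show", "NoiseStats", function(object) {
  cat(sprintf("NoiseStats (%s): mean = %.3g nm, sd = %.3g nm over %d px\n",
              object@regionKind, object@mean, object@sd, object@nPixels))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: K = %d, n = %d, logLik = %.3f (converged: %s)\n",
              object@K, object@n, object@logLik, object@converged))
  for (k in seq_len(object@K))
    cat(sprintf("  comp %d: weight %.3f, mean %.4f, sd %.4f\n",
                k, object@weight[k], object@mean[k], object@sd[k]))
  cat(sprintf("  AIC = %.2f, BIC = %.2f\n", object@aic, object@bic))
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit: intercept %.4g +/- %.2g, slope %.4g +/- %.2g\n",
              object@intercept, object@interceptSE, object@slope, object@slopeSE))
  cat(sprintf("  r = %.3f, R^2 = %.3f, RSS = %.4g (n = %d, dof = %d)\n",
              object@pearsonR, object@rSquared, object@rss, object@n, object@dof))
})

setMethod("show", "DivisionModel", function(object) {
  cat(sprintf("DivisionModel: mu_div = %.4g fg, sigma_div = %.4g fg (CV %.1f%%)\n",
              object@muDiv, object@sigmaDiv, object@cv))
  cat(sprintf("  A = %.6g, histogram R^2 = %s, converged: %s\n", object@A,
              ifelse(is.na(object@fitRSquared), "NA",
                     sprintf("%.3f", object@fitRSquared)),
              object@converged))
})

setMethod("show", "DistributionComparison", function(object) {
  cat(sprintf("DistributionComparison: EMD = %.4g fg\n", object@emd))
  if (object@B > 0L)
    cat(sprintf("  bootstrap (B = %d): mean %.4g fg, 95%% [%.4g, %.4g] fg\n",
                object@B, object@meanEmd, object@ciLower, object@ciUpper))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d cells on a %d x %d px scene\n",
              nrow(object@cells), nrow(object@mask), ncol(object@mask)))
})
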