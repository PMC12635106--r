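#' Mass constants: refractive index increment and its uncertainty
#'
#' The refractive index increment alpha links OPD to dry-mass surface
#' density.  It is stored in um^3/fg (1.9e-4 m^3/kg is numerically
#' 1.9e-4 um^3/fg), so mass(fg) = integrated OPD(um * um^2) / alpha with
#' no further unit conversion.
#'
#' @param alpha refractive index increment (um^3/fg, default 1.9e-4).
#' @param deltaAlpha its literature uncertainty (um^3/fg, default 0.03e-4).
#' @return a named list.
#' @export
massConstants <- function(alpha = 1.9e-4, deltaAlpha = 0.03e-4) {
  if (alpha <= 0) stop("alpha must be positive")
  if (deltaAlpha < 0) stop("deltaAlpha must be >= 0")
  list(alpha = alpha, deltaAlpha = deltaAlpha)
}

#' Per-cell dry mass from integrated OPD
#'
#' M_i = (1/alpha) * integral of OPD over the cell area
#'     = S_i * mean(OPD_i) / alpha.
#' The feature table carries integrated OPD in nm*um^2; dividing by 1000
#' converts to um*um^2, and by alpha (um^3/fg) to femtograms.
#'
#' @param features a feature data.frame from [extractFeatures()].
#' @param const a [massConstants()] list.
#' @return numeric vector of dry masses (fg), one per feature row.
#' @examples
#' # mean OPD 19 nm over 1 um^2 at the default alpha -> 100 fg
#' f <- data.frame(area_um2 = 1, integrated_opd_nm_um2 = 19)
#' dryMass(f)
#' @export
dryMass <- function(features, const = massConstants()) {
  if (any(features$area_um2 <= 0)) stop("regions must have positive area")
  features$integrated_opd_nm_um2 / 1000 / const$alpha
}

#' Propagated dry-mass uncertainty
#'
#' Standard error propagation with three independent contributions:
#' \itemize{
#'   \item OPD noise: S_i * delta_OPD / alpha, with delta_OPD the standard
#'     deviation of the cell-free background of the same image;
#'   \item refractive-index increment: mean(OPD_i) * S_i * delta_alpha /
#'     alpha^2;
#'   \item mask area: mean(OPD_i)/alpha * delta_S with delta_S ~ P_i * p,
#'     the one-pixel boundary band of the segmentation.
#' }
#' The total is the root sum of squares.
#'
#' @param features a feature data.frame from [extractFeatures()].
#' @param noise a cell-free [NoiseStats-class] for the image.
#' @param const a [massConstants()] list.
#' @param pixelSize physical pixel size (nm).
#' @return a data.frame: `label`, `mass_fg`, `dmass_fg`, `opd_term_fg`,
#'   `alpha_term_fg`, `area_term_fg`, `relative_error_pct`,
#'   `low_confidence`.
#' @export
massUncertainty <- function(features, noise, const = massConstants(),
                            pixelSize) {
  stopifnot(is(noise, "NoiseStats"))
  if (noise@regionKind != "cell-free")
    stop("noise statistics must come from the cell-free background")
  if (any(features$area_um2 <= 0)) stop("regions must have positive area")
  S <- features$area_um2                       # um^2
  meanOpd <- features$mean_opd_nm / 1000       # um
  dOpd <- noise@sd / 1000                      # um
  P <- features$perimeter_um                   # um
  p_um <- pixelSize / 1000
  a <- const$alpha
  opdTerm <- S * dOpd / a
  alphaTerm <- meanOpd * S * const$deltaAlpha / a^2
  areaTerm <- meanOpd / a * (P * p_um)
  total <- sqrt(opdTerm^2 + alphaTerm^2 + areaTerm^2)
  M <- dryMass(features, const)
  lowFloor <- 3 * dOpd * S / a
  data.frame(label = features$label, mass_fg = M, dmass_fg = total,
             opd_term_fg = opdTerm, alpha_term_fg = alphaTerm,
             area_term_fg = areaTerm,
             relative_error_pct = 100 * total / abs(M),
             low_confidence = abs(M) < lowFloor)
}

#' Population-level dry-mass summary
#'
#' Mean mass, coefficient of variation, and the mean relative mass error
#' with a 95% Student-t confidence interval.
#'
#' @param measurements a data.frame from [massUncertainty()] (possibly
#'   pooled over images).
#' @return a list: `n`, `mean_mass_fg`, `cv_pct`,
#'   `mean_relative_error_pct`, `ci_lower_pct`, `ci_upper_pct`.
#' @export
populationSummary <- function(measurements) {
  n <- nrow(measurements)
  if (n < 2L) stop("need at least 2 measurements")
  m <- measurements$mass_fg
  rel <- measurements$relative_error_pct
  half <- stats::qt(0.975, df = n - 1L) * stats::sd(rel) / sqrt(n)
  list(n = n, mean_mass_fg = mean(m), cv_pct = 100 * stats::sd(m) / mean(m),
       mean_relative_error_pct = mean(rel),
       ci_lower_pct = mean(rel) - half, ci_upper_pct = mean(rel) + half)
}
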