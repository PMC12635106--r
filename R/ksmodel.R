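.erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

## unnormalized steady-state density
.ksKernel <- function(m, muDiv, sigmaDiv) {
  if (sigmaDiv > 0) {
    1 / (2 * m^2) * (.erf((muDiv - m) / (sqrt(2) * sigmaDiv)) -
                     .erf((muDiv - 2 * m) / (sqrt(2) * sigmaDiv)))
  } else {
    ifelse(m >= muDiv / 2 & m <= muDiv, 1 / m^2, 0)
  }
}

## The kernel behaves like 1/m near zero mass, so the quadrature runs on the
## log-mass scale where the integrand is smooth and bounded.
.ksNormalize <- function(muDiv, sigmaDiv) {
  upper <- muDiv + 6 * sigmaDiv
  lower <- max(muDiv / 2 - 6 * sigmaDiv, upper * 1e-9)
  I <- stats::integrate(function(u) exp(u) * .ksKernel(exp(u), muDiv, sigmaDiv),
                        log(lower), log(upper), rel.tol = 1e-8,
                        subdivisions = 500L)$value
  1 / I
}

#' Construct a Koch-Schaechter division model
#'
#' Steady-state dry-mass density of an asynchronously growing,
#' binary-dividing population: theta(m) = A/m^2 * P(division mass in
#' (m, 2m)), which for a normal division-mass distribution has the closed
#' form theta(m) = A/(2 m^2) (erf((mu_div - m)/(sqrt(2) sigma_div)) -
#' erf((mu_div - 2m)/(sqrt(2) sigma_div))).  The normalization A is
#' computed by adaptive quadrature; in the deterministic limit
#' sigma_div -> 0, A -> mu_div and the mean mass -> mu_div * ln 2.
#'
#' @param muDiv mean division mass (fg).
#' @param sigmaDiv standard deviation of the division mass (fg).
#' @param fitRSquared optional histogram R-squared diagnostic.
#' @param converged optimizer flag (TRUE for direct construction).
#' @return a [DivisionModel-class].
#' @export
divisionModel <- function(muDiv, sigmaDiv, fitRSquared = NA_real_,
                          converged = TRUE) {
  if (muDiv <= 0) stop("muDiv must be positive")
  if (sigmaDiv < 0) stop("sigmaDiv must be >= 0")
  new("DivisionModel", muDiv = muDiv, sigmaDiv = sigmaDiv,
      A = .ksNormalize(muDiv, sigmaDiv), cv = 100 * sigmaDiv / muDiv,
      fitRSquared = fitRSquared, converged = converged)
}

#' Koch-Schaechter steady-state density
#'
#' @param model a [DivisionModel-class].
#' @param m masses at which to evaluate (fg, positive).
#' @return density values (1/fg).
#' @export
ksPdf <- function(model, m) {
  stopifnot(is(model, "DivisionModel"))
  if (any(m <= 0)) stop("m must be positive")
  model@A * .ksKernel(m, model@muDiv, model@sigmaDiv)
}

## dense grid over the effective support, for inverse-CDF sampling.  The
## density behaves like 1/m near zero mass (the erf form keeps a small
## residual probability of near-zero division masses), so the low end uses
## log spacing to resolve it; the bulk uses a linear grid.
.ksGrid <- function(model, nGrid = 4096L) {
  upper <- model@muDiv + 6 * model@sigmaDiv
  lower <- max(model@muDiv / 2 - 6 * model@sigmaDiv, upper * 1e-9)
  knee <- model@muDiv / 4
  if (lower >= knee) return(seq(lower, upper, length.out = nGrid))
  nLog <- nGrid %/% 4L
  c(exp(seq(log(lower), log(knee), length.out = nLog))[-nLog],
    seq(knee, upper, length.out = nGrid - nLog + 1L))
}

#' Sample masses from a Koch-Schaechter model
#'
#' Inverse-CDF sampling on a dense grid (trapezoidal CDF, linear
#' interpolation), reproducible under a fixed seed.
#'
#' @param model a [DivisionModel-class].
#' @param n number of samples.
#' @param seed RNG seed.
#' @return numeric vector of masses (fg).
#' @export
ksSample <- function(model, n, seed = 1L) {
  stopifnot(is(model, "DivisionModel"), n >= 1L)
  g <- .ksGrid(model)
  pdf <- ksPdf(model, g)
  dg <- diff(g)
  cdf <- c(0, cumsum((pdf[-1] + pdf[-length(pdf)]) / 2 * dg))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  u <- stats::runif(n)
  stats::approx(cdf[keep], g[keep], xout = u, rule = 2)$y
}

## R^2 of the model density against a Freedman-Diaconis-binned histogram
.histRSquared <- function(masses, model) {
  h <- graphics::hist(masses, breaks = "FD", plot = FALSE)
  obs <- h$density
  pred <- ksPdf(model, pmax(h$mids, .Machine$double.eps))
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Fit the Koch-Schaechter model to observed dry masses
#'
#' Maximum-likelihood estimation of (mu_div, sigma_div) by direct
#' numerical optimization, renormalizing the density at every evaluation.
#' A histogram R-squared (Freedman-Diaconis bins) is reported as a
#' goodness-of-fit diagnostic; it is not the fitting objective, which
#' avoids bin-choice sensitivity.
#'
#' @param masses observed dry masses (fg), n >= 30.
#' @return a [DivisionModel-class] with `fitRSquared` set.
#' @export
fitKS <- function(masses) {
  masses <- as.numeric(masses)
  if (length(masses) < 30L) stop("need at least 30 masses")
  if (any(masses <= 0)) stop("masses must be positive")
  negLL <- function(par) {
    mu <- exp(par[1]); sg <- exp(par[2])
    if (!is.finite(mu) || !is.finite(sg)) return(1e10)
    A <- tryCatch(.ksNormalize(mu, sg), error = function(e) NA_real_)
    if (!is.finite(A)) return(1e10)
    d <- A * .ksKernel(masses, mu, sg)
    if (any(d <= 0) || any(!is.finite(d))) return(1e10)
    -sum(log(d))
  }
  ## observed mean ~ muDiv*ln2 gives the starting point
  start <- c(log(mean(masses) / log(2)), log(stats::sd(masses)))
  opt <- stats::optim(start, negLL, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
  conv <- opt$convergence == 0L
  if (!conv) warning("optimizer did not converge; returning best iterate")
  model <- divisionModel(exp(opt$par[1]), exp(opt$par[2]), converged = conv)
  model@fitRSquared <- .histRSquared(masses, model)
  model
}

#' One-dimensional Earth Mover's Distance between samples
#'
#' For equal-weight samples the 1-D optimal-transport cost equals the
#' integral of the absolute difference of the empirical CDFs.
#'
#' @param sampleA,sampleB numeric vectors (fg), non-empty.
#' @return the EMD (fg).
#' @export
emd <- function(sampleA, sampleB) {
  if (!length(sampleA) || !length(sampleB)) stop("samples must be non-empty")
  all_x <- sort(unique(c(sampleA, sampleB)))
  if (length(all_x) == 1L) return(0)
  cdfA <- stats::ecdf(sampleA)(all_x)
  cdfB <- stats::ecdf(sampleB)(all_x)
  n <- length(all_x)
  sum(abs(cdfA[-n] - cdfB[-n]) * diff(all_x))
}

#' Bootstrap EMD between two mass densities
#'
#' Draws B paired resamples from each density (Koch-Schaechter models or
#' empirical samples), computes the EMD per pair, and summarizes with the
#' mean and central 95% interval.
#'
#' @param pdfA,pdfB either [DivisionModel-class] objects (sampled via
#'   [ksSample()]) or numeric vectors (resampled with replacement).
#' @param B number of bootstrap resamples (default 10000).
#' @param nA,nB per-resample sample sizes; default the original sample
#'   size for vectors, 179 for models.
#' @param seed RNG seed.
#' @return a [DistributionComparison-class].  The `emd` slot holds the
#'   point EMD between single size-nA/nB draws (for model inputs) or the
#'   observed samples themselves.
#' @export
bootstrapEmd <- function(pdfA, pdfB, B = 10000L, nA = NULL, nB = NULL,
                         seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  sizeOf <- function(p, n) {
    if (!is.null(n)) n else if (is.numeric(p)) length(p) else 179L
  }
  nA <- sizeOf(pdfA, nA); nB <- sizeOf(pdfB, nB)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  drawFrom <- function(p, n) {
    if (is(p, "DivisionModel")) {
      s <- sample.int(2^30, 1L)   # force before ksSample snapshots the RNG
      ksSample(p, n, seed = s)
    } else sample(p, n, replace = TRUE)
  }
  point <- if (is.numeric(pdfA) && is.numeric(pdfB)) emd(pdfA, pdfB)
           else emd(drawFrom(pdfA, nA), drawFrom(pdfB, nB))
  boots <- vapply(seq_len(B), function(i)
    emd(drawFrom(pdfA, nA), drawFrom(pdfB, nB)), numeric(1))
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  new("DistributionComparison", emd = point, bootstrapEmds = boots,
      B = as.integer(B), meanEmd = mean(boots), ciLower = qs[1],
      ciUpper = qs[2], seed = as.integer(seed))
}
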