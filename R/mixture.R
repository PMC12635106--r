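## k-means++-style seeding for 1-D EM initialization
.kppMeans <- function(x, K) {
  centers <- numeric(K)
  centers[1] <- x[sample.int(length(x), 1L)]
  if (K > 1L) for (k in 2:K) {
    d2 <- vapply(x, function(v) min((v - centers[seq_len(k - 1L)])^2), numeric(1))
    if (sum(d2) == 0) centers[k] <- x[sample.int(length(x), 1L)]
    else centers[k] <- x[sample.int(length(x), 1L, prob = d2)]
  }
  centers
}

.emOnce <- function(x, K, maxIter, tol) {
  n <- length(x)
  mu <- .kppMeans(x, K)
  sg <- rep(stats::sd(x) / K + 1e-12, K)
  w <- rep(1 / K, K)
  sdFloor <- max(stats::sd(x), .Machine$double.eps) * 1e-4
  ll <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * stats::dnorm(x, mu[k], sg[k]),
                   numeric(n))
    dens <- matrix(dens, n, K)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    newLL <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, `-`))^2) / nk)
    sg <- pmax(sg, sdFloor)
    if (is.finite(ll) && abs(newLL - ll) < tol) { ll <- newLL; converged <- TRUE; break }
    ll <- newLL
  }
  list(w = w, mu = mu, sg = sg, ll = ll, converged = converged)
}

#' Fit a 1-D Gaussian mixture by expectation-maximization
#'
#' Best of `nInit` random restarts (k-means++-style seeding) by
#' log-likelihood.  Information criteria use 3K - 1 free parameters
#' (weights constrained to sum to 1): AIC = 2(3K-1) - 2 logLik,
#' BIC = (3K-1) log(n) - 2 logLik.  Components are returned sorted by
#' descending mean, so for the circularity model component 1 is the
#' high-circularity "singles" mode.
#'
#' @param values numeric vector of observations.
#' @param K number of components.
#' @param seed RNG seed for the restarts.
#' @param nInit number of EM restarts (default 10).
#' @param maxIter maximum EM iterations per restart (default 500).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @return a [MixtureModel-class].
#' @export
fitMixture <- function(values, K, seed = 1L, nInit = 10L, maxIter = 500L,
                       tol = 1e-6) {
  K <- as.integer(K)
  x <- as.numeric(values)
  n <- length(x)
  if (n <= 3L * K) stop("need more than 3K observations")
  best <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_len(nInit)) {
    fit <- .emOnce(x, K, maxIter, tol)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within maxIter; returning best iterate")
  ord <- order(best$mu, decreasing = TRUE)
  npar <- 3L * K - 1L
  new("MixtureModel", K = K, weight = best$w[ord] / sum(best$w),
      mean = best$mu[ord], sd = best$sg[ord], logLik = best$ll,
      aic = 2 * npar - 2 * best$ll, bic = npar * log(n) - 2 * best$ll,
      n = n, converged = best$converged, seed = as.integer(seed))
}

#' Select the mixture component count by BIC
#'
#' Fits mixtures with K in `Krange` and picks the K minimizing BIC (ties
#' broken toward the smaller K).
#'
#' @param values numeric vector of observations.
#' @param Krange candidate component counts (default 1:5).
#' @param seed RNG seed.
#' @param nInit restarts per K (default 10).
#' @return a list with `table` (data.frame of K, logLik, aic, bic),
#'   `chosenK`, and `models` (one [MixtureModel-class] per K).
#' @export
selectComponents <- function(values, Krange = 1:5, seed = 1L, nInit = 10L) {
  models <- lapply(Krange, function(K)
    fitMixture(values, K, seed = seed, nInit = nInit))
  tab <- data.frame(K = as.integer(Krange),
                    logLik = vapply(models, function(m) m@logLik, numeric(1)),
                    aic = vapply(models, function(m) m@aic, numeric(1)),
                    bic = vapply(models, function(m) m@bic, numeric(1)))
  chosen <- tab$K[which.min(tab$bic)]
  list(table = tab, chosenK = chosen, models = models)
}

#' Posterior component memberships under a two-component mixture
#'
#' @param model a [MixtureModel-class] with K = 2.
#' @param values numeric vector.
#' @return matrix with columns `posterior_single`, `posterior_cluster`
#'   (rows sum to 1).
#' @export
mixturePosteriors <- function(model, values) {
  stopifnot(is(model, "MixtureModel"))
  if (model@K != 2L) stop("posterior classification requires K = 2")
  d1 <- model@weight[1] * stats::dnorm(values, model@mean[1], model@sd[1])
  d2 <- model@weight[2] * stats::dnorm(values, model@mean[2], model@sd[2])
  tot <- d1 + d2
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  cbind(posterior_single = d1 / tot, posterior_cluster = d2 / tot)
}

#' Fraction of ambiguous classifications
#'
#' A value is ambiguous when its maximum posterior membership under the
#' two-component mixture falls below the confidence threshold.
#'
#' @param model a [MixtureModel-class] with K = 2.
#' @param values numeric vector.
#' @param confidence threshold in (0.5, 1), e.g. 0.70 or 0.90.
#' @return percentage of ambiguous values.
#' @export
ambiguousFraction <- function(model, values, confidence = 0.70) {
  if (confidence <= 0.5 || confidence >= 1)
    stop("confidence must be in (0.5, 1)")
  post <- mixturePosteriors(model, values)
  100 * mean(pmax(post[, 1], post[, 2]) < confidence)
}

#' Filter single cells by the mu1 +/- 2 sigma1 circularity window
#'
#' Retains rows whose circularity lies within two standard deviations of
#' the high-circularity ("singles") component mean.
#'
#' @param model a [MixtureModel-class] with K = 2 (component 1 = higher
#'   mean).
#' @param features a feature data.frame with a `circularity` column.
#' @return the filtered data.frame.
#' @export
singleFilter <- function(model, features) {
  stopifnot(is(model, "MixtureModel"))
  if (model@K != 2L) stop("singleFilter requires K = 2")
  lo <- model@mean[1] - 2 * model@sd[1]
  hi <- model@mean[1] + 2 * model@sd[1]
  features[features$circularity >= lo & features$circularity <= hi, ,
           drop = FALSE]
}

#' Ordinary least-squares fit of bacillus length on dry mass
#'
#' Rod-shaped cells elongate at near-constant width, so length grows
#' linearly with dry mass; the fitted line L(um) = intercept + slope * M(fg)
#' turns a simple length measurement into a mass estimate.
#'
#' @param lengths cell lengths (um).
#' @param masses dry masses (fg).
#' @return a [RegressionFit-class].
#' @export
fitLengthMass <- function(lengths, masses) {
  n <- length(masses)
  if (n < 3L) stop("need at least 3 points")
  if (stats::var(masses) == 0) stop("zero mass variance")
  fit <- stats::lm(lengths ~ masses)
  sm <- summary(fit)
  r <- stats::cor(masses, lengths)
  new("RegressionFit",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      slopeSE = sm$coefficients[2, 2], interceptSE = sm$coefficients[1, 2],
      pearsonR = r, rSquared = sm$r.squared,
      rss = sum(stats::residuals(fit)^2), n = as.integer(n),
      dof = as.integer(n - 2L))
}
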