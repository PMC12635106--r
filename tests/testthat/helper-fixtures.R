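# Shared fixtures built in code.

# binary raster of a disk of radius R px centered in an n x n grid
rasterDisk <- function(R, n = 2L * ceiling(R) + 9L) {
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  (d2 <= R^2) * 1L
}

# binary raster of an axis-aligned ellipse with semi-axes (a, b) px
rasterEllipse <- function(a, b, n = 2L * ceiling(max(a, b)) + 9L) {
  ctr <- (n + 1) / 2
  x <- seq_len(n) - ctr
  (outer(x^2 / a^2, x^2 / b^2, `+`) <= 1) * 1L
}

# draws from the circularity mixture reported for the cocci population
paperMixture <- list(w = c(0.51, 0.49), mu = c(0.998, 0.83), sd = c(0.020, 0.098))

rPaperMixture <- function(n, seed) {
  set.seed(seed)
  comp <- sample(1:2, n, replace = TRUE, prob = paperMixture$w)
  stats::rnorm(n, paperMixture$mu[comp], paperMixture$sd[comp])
}

# the same mixture as a fitted-model object (for posterior-based operations)
paperMixtureModel <- function() {
  ll <- 0  # likelihood fields unused by posterior operations
  new("MixtureModel", K = 2L, weight = paperMixture$w, mean = paperMixture$mu,
      sd = paperMixture$sd, logLik = ll, aic = 0, bic = 0, n = 179L,
      converged = TRUE, seed = 1L)
}

# LabelMap wrapping a single binary shape
labelMapFrom <- function(bin, pixelSize = 90.6) {
  new("LabelMap", values = matrix(as.integer(bin > 0), nrow(bin), ncol(bin)),
      nLabels = 1L, pixelSize = pixelSize, borderTouching = FALSE)
}

cellFreeNoise <- function(sd_nm, mean_nm = 0) {
  new("NoiseStats", mean = mean_nm, sd = sd_nm, nPixels = 10000L,
      regionKind = "cell-free")
}
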