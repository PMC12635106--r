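test_that("phase-to-OPD conversion applies lambda/(2 pi) and is linear", {
  full <- PhaseImage(matrix(2 * pi, 8, 8), wavelength = 666, pixelSize = 90.6)
  expect_equal(opdValues(phaseToOpd(full)), matrix(666, 8, 8))

  zero <- PhaseImage(matrix(0, 8, 8), wavelength = 666, pixelSize = 90.6)
  expect_equal(opdValues(phaseToOpd(zero)), matrix(0, 8, 8))

  half <- PhaseImage(matrix(pi, 8, 8), wavelength = 500, pixelSize = 90.6)
  expect_equal(opdValues(phaseToOpd(half)), matrix(250, 8, 8))

  set.seed(1)
  phi <- matrix(rnorm(64), 8, 8)
  a <- 3.7
  one <- phaseToOpd(PhaseImage(phi, 666, 90.6))
  scaled <- phaseToOpd(PhaseImage(a * phi, 666, 90.6))
  expect_equal(opdValues(scaled), a * opdValues(one))

  out <- phaseToOpd(PhaseImage(phi, 666, 90.6))
  expect_false(isLeveled(out))
  expect_false(isSmoothed(out))
})

test_that("non-finite phase values are rejected with located indices", {
  phi <- matrix(0, 6, 6)
  phi[3, 4] <- NaN
  expect_error(PhaseImage(phi, 666, 90.6), "\\(3,4\\)")
})

test_that("background leveling recovers nested polynomial surfaces exactly", {
  # constant image
  lv <- levelBackground(OpdImage(matrix(50, 40, 40), 90.6), order = 2)
  expect_lt(max(abs(opdValues(lv$opd))), 1e-9)
  expect_true(isLeveled(lv$opd))

  # exact total-degree-2 surface fitted at order 16
  x <- seq(-1, 1, length.out = 60); y <- seq(-1, 1, length.out = 55)
  Z <- outer(x, y, function(u, v) 3 + 2 * u - v + 0.5 * u^2 - u * v + 0.2 * v^2)
  lv16 <- levelBackground(OpdImage(Z, 90.6), order = 16)
  expect_lt(max(abs(opdValues(lv16$opd))), 1e-6)

  # coefficient count invariant
  expect_equal(nrow(lv16$model@coefficients), (16 + 1) * (16 + 2) / 2)
  expect_equal(dim(bgSurface(lv16$model)), dim(Z))
  expect_equal(bgOrder(lv16$model), 16L)
})

test_that("leveling residual is orthogonal to the fitted surface", {
  set.seed(4)
  Z <- matrix(rnorm(80 * 70), 80, 70) +
    outer(seq(-1, 1, length.out = 80), seq(-1, 1, length.out = 70),
          function(u, v) 20 * u + 10 * v^2)
  lv <- levelBackground(OpdImage(Z, 90.6), order = 6)
  resid <- opdValues(lv$opd)
  surf <- bgSurface(lv$model)
  expect_lt(abs(sum(resid * surf)) / sum(surf^2), 1e-10)
})

test_that("degenerate leveling orders fail explicitly", {
  expect_error(levelBackground(OpdImage(matrix(0, 10, 10), 90.6), order = 10),
               "degenerate")
  expect_error(levelBackground(OpdImage(matrix(0, 10, 10), 90.6), order = -1))
})

test_that("leveling a synthetic scene recovers the generating background", {
  sc <- makeScene(sceneConfig(), n = 20, seed = 8)
  lv <- levelBackground(sc$opd, order = 16)
  cellFree <- sc$truth@mask == 0L
  err <- bgSurface(lv$model) - sc$truth@background
  # remove the fit's mean response to the noise floor: compare shapes
  rms <- sqrt(mean(err[cellFree]^2))
  expect_lt(rms, 1)
})

test_that("Gaussian smoothing has unit DC gain, normalized kernel and known noise gain", {
  const <- OpdImage(matrix(7, 30, 30), 90.6)
  expect_equal(opdValues(gaussianSmooth(const, 4)), matrix(7, 30, 30),
               tolerance = 1e-12)

  imp <- matrix(0, 61, 61); imp[31, 31] <- 1
  sm <- gaussianSmooth(OpdImage(imp, 90.6), 4)
  expect_equal(sum(opdValues(sm)), 1, tolerance = 1e-12)
  expect_true(isSmoothed(sm))

  # white-noise SD gain: sum of squared kernel weights, ~0.070 at radius 4
  w <- dnorm(-12:12, 0, 4); w <- w / sum(w)
  gain <- sum(w^2)                      # separable 2-D: (sum w^2)^1 per axis pair
  expect_equal(gain, 0.0705, tolerance = 0.02)
  set.seed(2)
  noise <- matrix(rnorm(600 * 600), 600, 600)
  out <- opdValues(gaussianSmooth(OpdImage(noise, 90.6), 4))
  expect_equal(sd(as.vector(out)) / sd(as.vector(noise)), gain,
               tolerance = 0.06)
})

test_that("smoothing preserves the integrated OPD of interior structure", {
  Z <- matrix(0, 120, 120)
  Z[50:70, 50:70] <- 40
  sm <- gaussianSmooth(OpdImage(Z, 90.6), 4)
  expect_equal(sum(opdValues(sm)) / sum(Z), 1, tolerance = 0.01)
})

test_that("spectrum is max-normalized with physical frequency axes", {
  sp0 <- spectrumDb(OpdImage(matrix(5, 64, 64), 90.6))
  expect_equal(max(sp0$db), 0)
  expect_equal(sum(sp0$db > -100), 1L)   # single 0 dB point at DC
  expect_equal(sp0$kx[which.max(apply(sp0$db, 1, max))], 0)

  # sinusoid of period 10 px at 90.6 nm/px peaks at +/- 1.104 1/um
  n <- 256
  Z <- matrix(sin(2 * pi * (1:n) / 10), n, n)
  sp <- spectrumDb(OpdImage(Z, 90.6))
  bin <- 1 / (n * 0.0906)
  top <- which(sp$db == max(sp$db), arr.ind = TRUE)
  expect_lt(abs(abs(sp$kx[top[1, 1]]) - 1.104), bin)   # within one bin
  expect_true(all(abs(abs(sp$kx[top[, 1]]) - 1.104) < bin))

  # axis extent reaches the Nyquist frequency 1/(2 p)
  expect_equal(max(abs(sp$kx)), 1 / (2 * 0.0906), tolerance = bin)
})

test_that("background noise statistics honor the exclusion mask", {
  z <- OpdImage(matrix(0, 50, 50), 90.6)
  ns <- backgroundNoise(z)
  expect_equal(ns@mean, 0); expect_equal(ns@sd, 0)
  expect_equal(ns@regionKind, "whole-image")

  set.seed(3)
  g <- matrix(rnorm(400 * 300, 0, 2), 400, 300)
  ns2 <- backgroundNoise(OpdImage(g, 90.6))
  expect_equal(ns2@sd, 2, tolerance = 0.05)

  disk <- rasterDisk(10, 400)[, 1:300]
  withDisk <- g + 50 * disk
  ns3 <- backgroundNoise(OpdImage(withDisk, 90.6), excludeMask = disk > 0)
  ns4 <- backgroundNoise(OpdImage(withDisk + 950 * disk, 90.6),
                         excludeMask = disk > 0)
  expect_identical(ns3@mean, ns4@mean)   # stats independent of disk amplitude
  expect_identical(ns3@sd, ns4@sd)
  expect_equal(ns3@regionKind, "cell-free")
  expect_equal(ns3@nPixels, sum(disk == 0))

  expect_error(backgroundNoise(OpdImage(g, 90.6), excludeMask = g > -100),
               "fewer than 2")
})

test_that("std reduction is near zero for white noise and saturates for nested surfaces", {
  set.seed(5)
  wn <- OpdImage(matrix(rnorm(200 * 180), 200, 180), 90.6)
  cur <- stdReductionCurve(wn, c(2, 8, 16))
  expect_true(all(cur$reduction_pct < 1.5))
  expect_true(all(diff(cur$reduction_pct) >= -1e-9))  # monotone non-decreasing

  # strong degree-2 background + weak noise: plateau reached at order 2
  x <- seq(-1, 1, length.out = 200); y <- seq(-1, 1, length.out = 180)
  bg <- outer(x, y, function(u, v) 30 * u^2 - 20 * u * v + 10 * v)
  img <- OpdImage(bg + matrix(rnorm(200 * 180, 0, 0.1), 200, 180), 90.6)
  cur2 <- stdReductionCurve(img, c(2, 4, 6, 16, 32))
  expect_gt(cur2$reduction_pct[1], 98)
  expect_lt(cur2$reduction_pct[5] - cur2$reduction_pct[1], 1)
  expect_gte(cur2$reduction_pct[cur2$order == 32],
             cur2$reduction_pct[cur2$order == 16] - 1e-9)
})
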