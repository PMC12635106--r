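test_that("rendered cells conserve the analytic OPD integral and mass", {
  p <- 90.6; p_um2 <- (p / 1000)^2; alpha <- 1.9e-4

  zero <- cellSpec("coccus", center = c(2, 2), radius = 0.5, deltaN = 0)
  z <- cellOpdAndMass(zero, shape = c(50, 50), pixelSize = p)
  expect_equal(max(z$opd), 0); expect_equal(z$mass_fg, 0)

  sph <- cellSpec("coccus", center = c(2.2, 2.2), radius = 0.5, deltaN = 0.06)
  s <- cellOpdAndMass(sph, shape = c(50, 50), pixelSize = p)
  expect_equal(s$mass_fg, 165.3, tolerance = 0.1)      # deltaN * V / alpha
  gridMass <- sum(s$opd) / 1000 * p_um2 / alpha
  expect_equal(gridMass, s$mass_fg, tolerance = s$mass_fg * 0.01)
  expect_false(s$clipped)

  rod <- cellSpec("bacillus", center = c(3, 3), radius = 0.5, length = 3,
                  orientation = 0.4, deltaN = 0.031)
  r <- cellOpdAndMass(rod, shape = c(70, 70), pixelSize = p)
  expect_equal(r$mass_fg, 469.9, tolerance = 0.1)
  expect_equal(sum(r$opd) / 1000 * p_um2 / alpha, r$mass_fg,
               tolerance = r$mass_fg * 0.01)

  # finer sub-pixel sampling improves conservation
  e1 <- abs(sum(cellOpdAndMass(sph, shape = c(50, 50), pixelSize = p,
                               supersample = 1)$opd) / 1000 * p_um2 / alpha -
            s$mass_fg)
  e4 <- abs(gridMass - s$mass_fg)
  expect_lte(e4, e1 + 1e-9)

  clip <- cellSpec("coccus", center = c(0.1, 0.1), radius = 0.5, deltaN = 0.05)
  expect_true(cellOpdAndMass(clip, shape = c(50, 50), pixelSize = p)$clipped)
})

test_that("population sampling honours the geometry rules", {
  pop <- samplePopulation(400, strain = "bacilli", seed = 2)
  expect_true(all(vapply(pop, function(s) s$kind, "") == "bacillus"))
  for (s in pop[1:20]) {
    M <- s$deltaN * (pi * s$radius^2 * s$length + 4 / 3 * pi * s$radius^3) / 1.9e-4
    expect_equal(s$length + 2 * s$radius, 1.193 + 0.006 * M, tolerance = 1e-8)
    expect_equal(2 * s$radius, 1.19)
  }

  # coccus radius inversion: M = 165.3 fg at deltaN = 0.06 gives R = 0.5 um
  R <- (3 * 165.3 * 1.9e-4 / (4 * pi * 0.06))^(1 / 3)
  expect_equal(R, 0.5, tolerance = 1e-3)

  pop2 <- samplePopulation(2000, strain = "cocci", seed = 4)
  kinds <- vapply(pop2, function(s) s$kind, "")
  expect_true(all(kinds %in% c("coccus", "cluster")))
  expect_equal(mean(kinds == "cluster"), 0.49, tolerance = 0.025)
  radii <- vapply(pop2, function(s) s$radius, numeric(1))
  expect_true(all(radii >= 0.25))
})

test_that("generated masses support division-model recovery", {
  pop <- samplePopulation(600, strain = "cocci", clusterFraction = 0,
                          seed = 6)
  masses <- vapply(pop, function(s)
    s$deltaN * 4 / 3 * pi * s$radius^3 / 1.9e-4, numeric(1))
  fit <- fitKS(masses)
  expect_equal(fit@muDiv, 272, tolerance = 272 * 0.10)
})

test_that("scenes are reproducible with exact ground truth bookkeeping", {
  cfg <- sceneConfig(shape = c(300, 280))
  a <- makeScene(cfg, n = 5, seed = 7)
  b <- makeScene(cfg, n = 5, seed = 7)
  expect_identical(opdValues(a$opd), opdValues(b$opd))
  expect_identical(a$truth@cells, b$truth@cells)

  # no cells, no noise: the scene is exactly its background surface
  quiet <- makeScene(sceneConfig(shape = c(200, 180), noiseSd = 0),
                     cells = list(), seed = 9)
  expect_equal(opdValues(quiet$opd), quiet$truth@background, tolerance = 1e-12)
  expect_equal(nrow(quiet$truth@cells), 0L)
  expect_true(all(quiet$truth@mask == 0L))
})

test_that("well-separated scenes are fully recovered by the pipeline", {
  sc <- makeScene(sceneConfig(), n = 20, seed = 2)
  expect_equal(length(unique(sc$truth@mask[sc$truth@mask > 0])), 20L)
  res <- runProcess(sc$opd, runConfig())
  # every true cell is hit by exactly one recovered label
  hits <- vapply(1:20, function(i) {
    labs <- res$labels[[1]]@values[sc$truth@mask == i]
    length(unique(labs[labs > 0]))
  }, integer(1))
  expect_true(all(hits == 1L))
})

test_that("circularity separates generated singles from clusters", {
  singles <- lapply(seq(0.35, 0.75, length.out = 6), function(R)
    cellSpec("coccus", center = c(3, 3), radius = R, deltaN = 0.05))
  cs <- vapply(singles, function(s) {
    sup <- cellOpdAndMass(s, shape = c(70, 70), pixelSize = 90.6)$support
    extractFeatures(labelMapFrom(sup), OpdImage(sup * 1, 90.6))$circularity
  }, numeric(1))
  expect_true(all(cs >= 0.95 & cs <= 1.05))

  pairs <- lapply(c(0, pi / 4, pi / 3), function(ang) {
    d <- 2 * 0.45 * (1 - 0.3)    # 30% overlap of two R = 0.45 um members
    off <- d / 2 * c(cos(ang), sin(ang))
    cellSpec("cluster", center = c(3, 3), radius = 0.45,
             memberOffsets = list(-off, off), deltaN = 0.05)
  })
  cc <- vapply(pairs, function(s) {
    sup <- cellOpdAndMass(s, shape = c(70, 70), pixelSize = 90.6)$support
    extractFeatures(labelMapFrom(sup), OpdImage(sup * 1, 90.6))$circularity
  }, numeric(1))
  expect_true(all(cc < 0.95))
})
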