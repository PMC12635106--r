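leveledImg <- function(Z, p = 90.6) OpdImage(Z, p, leveled = TRUE, smoothed = TRUE)

test_that("adaptive mask is empty on constants, tight on isolated disks, scale-invariant", {
  expect_false(any(adaptiveMask(leveledImg(matrix(3, 200, 200)))))

  disk <- rasterDisk(20, 200)
  img <- leveledImg(50 * disk)
  mask <- adaptiveMask(img, segmentationParams(offsetMultiplier = 1))
  # foreground equals the disk up to a one-pixel boundary band
  core <- rasterDisk(19, 200) > 0
  grown <- rasterDisk(21, 200) > 0
  expect_true(all(mask[core]))
  expect_false(any(mask[!grown]))

  mask2 <- adaptiveMask(leveledImg(7.3 * 50 * disk),
                        segmentationParams(offsetMultiplier = 1))
  expect_identical(mask, mask2)

  expect_error(adaptiveMask(leveledImg(matrix(0, 50, 50)),
                            segmentationParams(blockSize = 127)), "blockSize")
  expect_warning(adaptiveMask(OpdImage(50 * disk, 90.6)), "leveled")
})

test_that("refinement removes specks, separates distant disks and fills holes", {
  p <- segmentationParams(openingRadius = 1, dilationRadius = 0, minArea = 0)
  speck <- matrix(FALSE, 40, 40); speck[20, 20] <- TRUE
  expect_equal(refineAndLabel(speck, p, 90.6)@nLabels, 0L)

  # two 10-px disks, 10-px gap: dilation by 2 px cannot bridge them
  m <- matrix(FALSE, 80, 120)
  d <- rasterDisk(10, 29) > 0
  m[26:54, 20:48] <- d
  m[26:54, 78:106] <- d   # edge-to-edge gap of 29 px between columns 48 and 78
  lab2 <- refineAndLabel(m, segmentationParams(), 90.6)
  expect_equal(lab2@nLabels, 2L)

  # interior hole pixel: single label whose dilated support covers the hole
  hole <- matrix(FALSE, 60, 60)
  hole[16:44, 16:44] <- rasterDisk(14, 29) > 0
  hole[30, 30] <- FALSE
  labH <- refineAndLabel(hole, segmentationParams(), 90.6)
  expect_equal(labH@nLabels, 1L)
  expect_equal(labH@values[30, 30], 1L)
})

test_that("labeling is deterministic and respects the area floor and border flag", {
  set.seed(9)
  m <- matrix(runif(150 * 150) > 0.7, 150, 150)
  a <- refineAndLabel(m, segmentationParams(), 90.6)
  b <- refineAndLabel(m, segmentationParams(), 90.6)
  expect_identical(a@values, b@values)

  # a 3x3 block (9 px = 0.074 um^2) falls below the 0.2 um^2 floor
  tiny <- matrix(FALSE, 50, 50); tiny[20:22, 20:22] <- TRUE
  expect_equal(refineAndLabel(tiny, segmentationParams(openingRadius = 1),
                              90.6)@nLabels, 0L)

  edge <- matrix(FALSE, 60, 60)
  edge[1:12, 20:31] <- TRUE
  labE <- refineAndLabel(edge, segmentationParams(), 90.6)
  expect_true(labE@borderTouching[1])
})

test_that("region features match analytic disk and ellipse geometry", {
  p_um <- 90.6 / 1000
  disk <- rasterDisk(20, 60)
  f <- extractFeatures(labelMapFrom(disk), OpdImage(disk * 25, 90.6))
  expect_equal(f$area_um2, pi * 20^2 * p_um^2, tolerance = 0.02)
  expect_gt(f$circularity, 0.95); expect_lt(f$circularity, 1.05)
  expect_lt(f$eccentricity, 0.25)
  expect_equal(f$mean_opd_nm, 25)
  expect_equal(f$integrated_opd_nm_um2, 25 * sum(disk) * p_um^2)

  ell <- rasterEllipse(30, 15, 75)
  fe <- extractFeatures(labelMapFrom(ell), OpdImage(ell * 1, 90.6))
  expect_equal(fe$eccentricity, sqrt(3) / 2, tolerance = 0.02)
  expect_gte(fe$major_axis_um, fe$minor_axis_um)
  expect_equal(fe$major_axis_um / 2, 30 * p_um, tolerance = 0.03)

  empty <- new("LabelMap", values = matrix(0L, 10, 10), nLabels = 0L,
               pixelSize = 90.6, borderTouching = logical(0))
  expect_equal(nrow(extractFeatures(empty, OpdImage(matrix(0, 10, 10), 90.6))), 0L)
})

test_that("circularity of digitized disks approaches 1 as radius grows", {
  cs <- sapply(c(16, 20, 32, 64), function(R) {
    d <- rasterDisk(R)
    extractFeatures(labelMapFrom(d), OpdImage(d, 90.6))$circularity
  })
  expect_true(all(abs(cs - 1) < 0.05))
  expect_lt(abs(cs[4] - 1), abs(cs[1] - 1) + 0.01)
})

test_that("eccentricity stays in [0, 1) for assorted shapes", {
  shapes <- list(rasterDisk(5), rasterDisk(25), rasterEllipse(40, 4),
                 rasterEllipse(12, 11))
  for (s in shapes) {
    e <- extractFeatures(labelMapFrom(s), OpdImage(s, 90.6))$eccentricity
    expect_gte(e, 0); expect_lt(e, 1)
  }
})

test_that("cell-free mask excludes the guarded neighbourhood of labels", {
  empty <- new("LabelMap", values = matrix(0L, 30, 30), nLabels = 0L,
               pixelSize = 90.6, borderTouching = logical(0))
  expect_true(all(cellFreeMask(empty, 2)))

  disk <- rasterDisk(8, 40)
  lm <- labelMapFrom(disk)
  cf <- cellFreeMask(lm, 2)
  grown <- EBImage::dilate(disk, EBImage::makeBrush(5, "disc")) > 0
  expect_true(all(!cf[grown]))
  expect_true(all(cf[!grown]))

  sc <- makeScene(sceneConfig(shape = c(400, 380)), n = 8, seed = 3)
  res <- runProcess(sc$opd, runConfig())
  cf2 <- cellFreeMask(res$labels[[1]], 3)
  expect_gte(mean(cf2), 0.85)
})
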