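#' Run configuration for batch processing
#'
#' @param order background-leveling polynomial order (default 16).
#' @param radius Gaussian smoothing radius in px (default 4).
#' @param segParams a [segmentationParams()] list.
#' @param const a [massConstants()] list.
#' @param guardRadius guard band (px) for the cell-free noise region.
#' @param seed RNG seed recorded in the run report.
#' @return a named list.
#' @export
runConfig <- function(order = 16L, radius = 4, segParams = segmentationParams(),
                      const = massConstants(), guardRadius = 3L, seed = 1L) {
  list(order = as.integer(order), radius = radius, segParams = segParams,
       const = const, guardRadius = as.integer(guardRadius),
       seed = as.integer(seed))
}

#' Process a batch of OPD images through the full pipeline
#'
#' Per image: background leveling, Gaussian smoothing, adaptive masking,
#' morphological refinement and labeling, feature extraction, cell-free
#' noise estimation, and dry mass with propagated uncertainty.  Features
#' and masses are aggregated across images with an `image` column; the
#' report records all parameters and per-image noise levels.
#'
#' @param images a list of [OpdImage-class]s (or a single one).
#' @param config a [runConfig()] list.
#' @return list with `features` (data.frame), `masses` (data.frame),
#'   `labels` (list of [LabelMap-class]), `noise` (list of
#'   [NoiseStats-class]) and `report` (parameter manifest).
#' @export
runProcess <- function(images, config = runConfig()) {
  if (is(images, "OpdImage")) images <- list(images)
  feats <- list(); masses <- list(); labelMaps <- list(); noises <- list()
  for (i in seq_along(images)) {
    opd <- images[[i]]
    lev <- levelBackground(opd, config$order)
    sm <- gaussianSmooth(lev$opd, config$radius)
    mask <- adaptiveMask(sm, config$segParams)
    labels <- refineAndLabel(mask, config$segParams, pixelSize(sm))
    f <- extractFeatures(labels, sm)
    noise <- backgroundNoise(sm, excludeMask = !cellFreeMask(labels,
                                                            config$guardRadius))
    if (nrow(f)) {
      m <- massUncertainty(f, noise, config$const, pixelSize(sm))
      if (config$segParams$excludeBorder) {
        keep <- !f$border_touching
        f <- f[keep, , drop = FALSE]
        m <- m[keep, , drop = FALSE]
      }
      if (nrow(f)) { f$image <- i; m$image <- i }
      feats[[length(feats) + 1L]] <- f
      masses[[length(masses) + 1L]] <- m
    }
    labelMaps[[i]] <- labels
    noises[[i]] <- noise
  }
  features <- if (length(feats)) do.call(rbind, feats) else data.frame()
  massTab <- if (length(masses)) do.call(rbind, masses) else data.frame()
  report <- list(
    n_images = length(images), order = config$order, radius = config$radius,
    segParams = config$segParams, alpha = config$const$alpha,
    deltaAlpha = config$const$deltaAlpha, guardRadius = config$guardRadius,
    seed = config$seed,
    delta_opd_nm = vapply(noises, function(x) x@sd, numeric(1)),
    n_regions = vapply(labelMaps, function(x) x@nLabels, integer(1)))
  list(features = features, masses = massTab, labels = labelMaps,
       noise = noises, report = report)
}

#' Frozen-mask leveling-order sweep
#'
#' With the segmentation mask frozen from the reference pipeline
#' (order-16 leveling), re-levels the raw image at each order and
#' recomputes every cell's integrated OPD under the frozen mask.  The
#' maximum relative discrepancy with respect to the reference order
#' quantifies how much the background model choice biases dry mass.
#'
#' @param opd the raw [OpdImage-class].
#' @param labels the frozen [LabelMap-class] from the reference run.
#' @param orders leveling orders to sweep (default c(2,4,8,16,32,64,128)).
#' @param refOrder reference order (default 16).
#' @param radius Gaussian radius applied after each leveling (default 4).
#' @return list with `table` (data.frame: order, cell, integrated OPD,
#'   relative discrepancy in %) and `max_discrepancy_pct`.
#' @export
frozenMaskSweep <- function(opd, labels, orders = c(2L, 4L, 8L, 16L, 32L, 64L, 128L),
                            refOrder = 16L, radius = 4) {
  stopifnot(is(opd, "OpdImage"), is(labels, "LabelMap"))
  if (!refOrder %in% orders) orders <- sort(c(orders, refOrder))
  lab <- labels@values
  n <- labels@nLabels
  if (n < 1L) stop("frozen mask has no labels")
  iopd <- sapply(orders, function(N) {
    sm <- gaussianSmooth(levelBackground(opd, N)$opd, radius)
    vapply(seq_len(n), function(i) sum(sm@values[lab == i]), numeric(1))
  })
  iopd <- matrix(iopd, nrow = n)
  ref <- iopd[, which(orders == refOrder)]
  relDisc <- 100 * abs(iopd - ref) / abs(ref)
  tab <- data.frame(
    order = rep(orders, each = n), cell = rep(seq_len(n), length(orders)),
    integrated_opd = as.vector(iopd), rel_discrepancy_pct = as.vector(relDisc))
  list(table = tab, max_discrepancy_pct = max(relDisc))
}

#' Segmentation robustness sweeps on a synthetic scene
#'
#' Reruns segmentation over a grid of threshold multipliers, opening and
#' dilation radii, and adaptive block sizes, measuring cell recall and
#' mean absolute area error against the scene's ground truth, plus the
#' frozen-mask leveling-order sweep.
#'
#' @param scene a [makeScene()] result.
#' @param config a [runConfig()] list (reference parameters).
#' @param offsetMultipliers swept threshold multipliers (default
#'   seq(1, 3, 0.25)).
#' @param radii swept opening/dilation radii (default 1:3).
#' @param blockSizes swept adaptive block sizes (default c(33,65,127),
#'   the nearest odd sizes to 32/64/128 px).
#' @param orders frozen-mask leveling orders.
#' @return list with `grid` (data.frame of swept parameters, recall,
#'   area error), `frozen_mask` (see [frozenMaskSweep()]) and `report`.
#' @export
runSweeps <- function(scene, config = runConfig(),
                      offsetMultipliers = seq(1, 3, by = 0.25),
                      radii = 1:3, blockSizes = c(33L, 65L, 127L),
                      orders = c(2L, 4L, 8L, 16L, 32L, 64L, 128L)) {
  truth <- scene$truth
  nTrue <- nrow(truth@cells)
  lev <- levelBackground(scene$opd, config$order)
  sm <- gaussianSmooth(lev$opd, config$radius)
  evalOnce <- function(params) {
    mask <- adaptiveMask(sm, params)
    labels <- refineAndLabel(mask, params, pixelSize(sm))
    ## match each true cell to the label covering most of its support
    hit <- 0L; areaErr <- numeric(0)
    p_um2 <- (pixelSize(sm) / 1000)^2
    for (i in seq_len(nTrue)) {
      sup <- truth@mask == i
      labs <- labels@values[sup]
      labs <- labs[labs > 0L]
      if (!length(labs)) next
      best <- as.integer(names(which.max(table(labs))))
      hit <- hit + 1L
      trueArea <- sum(sup) * p_um2
      segArea <- sum(labels@values == best) * p_um2
      areaErr <- c(areaErr, abs(segArea - trueArea) / trueArea)
    }
    c(recall = if (nTrue) hit / nTrue else NA_real_,
      mean_area_err = if (length(areaErr)) mean(areaErr) else NA_real_)
  }
  grid <- expand.grid(offsetMultiplier = offsetMultipliers,
                      morphRadius = radii, blockSize = blockSizes)
  res <- t(apply(grid, 1L, function(g) {
    params <- segmentationParams(
      blockSize = g[["blockSize"]], offsetMultiplier = g[["offsetMultiplier"]],
      openingRadius = g[["morphRadius"]], dilationRadius = g[["morphRadius"]],
      minArea = config$segParams$minArea,
      connectivity = config$segParams$connectivity,
      excludeBorder = config$segParams$excludeBorder)
    evalOnce(params)
  }))
  grid$recall <- res[, "recall"]
  grid$mean_area_err <- res[, "mean_area_err"]
  refLabels <- refineAndLabel(adaptiveMask(sm, config$segParams),
                              config$segParams, pixelSize(sm))
  fm <- frozenMaskSweep(scene$opd, refLabels, orders = orders,
                        refOrder = config$order, radius = config$radius)
  list(grid = grid, frozen_mask = fm,
       report = list(blockSizes = blockSizes, radii = radii,
                     offsetMultipliers = offsetMultipliers, orders = orders))
}
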