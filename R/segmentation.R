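#' Segmentation parameters
#'
#' Bundles the adaptive-masking and morphological-refinement settings.
#' The threshold offset is `offsetMultiplier` times the global standard
#' deviation of the image, swept over 1-3 in robustness studies; block
#' size is the local-mean window (odd, in pixels).
#'
#' @param blockSize adaptive window size in pixels (odd, default 127).
#' @param offsetMultiplier k: threshold offset in units of the image's
#'   global standard deviation (default 2).
#' @param openingRadius disk radius (px) of the morphological opening
#'   (default 2).
#' @param dilationRadius disk radius (px) of the per-label dilation
#'   (default 2).
#' @param minArea smallest retained component area in um^2 (default 0.2,
#'   well below a single coccus).
#' @param connectivity 4 or 8 (default 8).
#' @param excludeBorder flag border-touching regions for exclusion from
#'   population statistics (default TRUE).
#' @return a named list of validated parameters.
#' @export
segmentationParams <- function(blockSize = 127L, offsetMultiplier = 2,
                               openingRadius = 2L, dilationRadius = 2L,
                               minArea = 0.2, connectivity = 8L,
                               excludeBorder = TRUE) {
  blockSize <- as.integer(blockSize)
  if (blockSize < 3L || blockSize %% 2L == 0L)
    stop("blockSize must be odd and >= 3")
  if (offsetMultiplier < 0) stop("offsetMultiplier must be >= 0")
  if (openingRadius < 0 || dilationRadius < 0) stop("radii must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  list(blockSize = blockSize, offsetMultiplier = offsetMultiplier,
       openingRadius = as.integer(openingRadius),
       dilationRadius = as.integer(dilationRadius), minArea = minArea,
       connectivity = as.integer(connectivity), excludeBorder = excludeBorder)
}

#' Adaptive binary masking
#'
#' Foreground pixels are those strictly exceeding a Gaussian-weighted local
#' mean (window `blockSize`, sigma = (blockSize-1)/6) plus
#' `offsetMultiplier` times the global standard deviation of the image.
#' The local mean absorbs residual illumination gradients; the global-std
#' offset rejects background noise.  Scaling the image by a positive
#' constant leaves the mask unchanged.
#'
#' @param opd an [OpdImage-class]; expected leveled and smoothed (a warning
#'   is raised otherwise).
#' @param params a [segmentationParams()] list.
#' @return a logical matrix (TRUE = foreground).
#' @export
adaptiveMask <- function(opd, params = segmentationParams()) {
  stopifnot(is(opd, "OpdImage"))
  if (!opd@leveled || !opd@smoothed)
    warning("adaptiveMask expects a leveled and smoothed image")
  Z <- opd@values
  b <- params$blockSize
  if (b > min(dim(Z))) stop("blockSize larger than image")
  w <- .gaussKernel1d((b - 1) / 6, halfwidth = (b - 1L) %/% 2L)
  localMean <- .sepConv(Z, w)
  # guard against rounding in the local mean on (near-)constant images
  eps <- sqrt(.Machine$double.eps) * max(abs(Z), 1)
  (Z - localMean) > params$offsetMultiplier * stats::sd(as.vector(Z)) + eps
}

.discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

## 8-connectivity: merge 4-connected labels that touch diagonally
## (union-find over label ids).
.merge8 <- function(lab) {
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, integer(1))
    lab[] <- c(0L, root)[lab + 1L]
  }
  lab
}

## renumber labels 1..K by raster (column-major) order of first pixel
.renumber <- function(lab) {
  ids <- unique(as.integer(lab)[as.integer(lab) > 0L])
  first <- vapply(ids, function(i) which(lab == i)[1L], integer(1))
  ids <- ids[order(first)]
  map <- integer(max(c(lab, 0L)) + 1L)
  map[ids + 1L] <- seq_along(ids)
  lab[] <- map[lab + 1L]
  lab
}

#' Morphological refinement and labeling of a binary mask
#'
#' Applies a disk-shaped morphological opening (removes specks smaller
#' than the element and smooths contours), labels connected components,
#' drops components below `minArea`, then dilates each label with a disk;
#' pixels contested between labels join the nearest one (Voronoi
#' propagation).  Dilation reconnects fragmented cells and fills small
#' interior holes.
#'
#' @param mask logical matrix from [adaptiveMask()].
#' @param params a [segmentationParams()] list.
#' @param pixelSize physical pixel size (nm), used for the area floor.
#' @return a [LabelMap-class].
#' @export
refineAndLabel <- function(mask, params = segmentationParams(), pixelSize) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (params$openingRadius > 0L)
    m <- EBImage::opening(m, .discBrush(params$openingRadius))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (params$connectivity == 8L) lab <- .merge8(lab)
  ## area floor (pre-dilation), in um^2
  pxArea <- (pixelSize / 1000)^2
  if (max(lab) > 0L) {
    counts <- tabulate(lab[lab > 0L])
    drop <- which(counts * pxArea < params$minArea)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  lab <- .renumber(lab)
  n <- max(lab)
  if (n > 0L && params$dilationRadius > 0L) {
    grown <- EBImage::dilate(matrix(as.numeric(lab > 0L), nrow(lab), ncol(lab)),
                             .discBrush(params$dilationRadius))
    lab <- matrix(as.integer(EBImage::propagate(matrix(0, nrow(lab), ncol(lab)),
                                                seeds = lab, mask = grown)),
                  nrow(lab), ncol(lab))
    lab <- .renumber(lab)
    n <- max(lab)
  }
  border <- logical(n)
  if (n > 0L) {
    edge <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    border[edge[edge > 0L]] <- TRUE
  }
  new("LabelMap", values = lab, nLabels = as.integer(n),
      pixelSize = as.numeric(pixelSize), borderTouching = border)
}

## Crofton-type perimeter from boundary crossings in 4 directions
## (axial spacing 1 px, diagonal spacing 1/sqrt(2) px):
## P = pi/8 * (n_h + n_v + (n_d1 + n_d2)/sqrt(2)), in pixels.
.croftonPerimeter <- function(bin) {
  padded <- matrix(0L, nrow(bin) + 2L, ncol(bin) + 2L)
  padded[2:(nrow(bin) + 1L), 2:(ncol(bin) + 1L)] <- bin
  nr <- nrow(padded); nc <- ncol(padded)
  n_h <- sum(padded[, -1] != padded[, -nc])
  n_v <- sum(padded[-1, ] != padded[-nr, ])
  n_d1 <- sum(padded[-1, -1] != padded[-nr, -nc])
  n_d2 <- sum(padded[-nr, -1] != padded[-1, -nc])
  pi / 8 * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Per-region geometric and OPD features
#'
#' For each labeled region: area and perimeter in physical units,
#' circularity C = 4*pi*Area/Perimeter^2 (1 for a perfect circle, not
#' clamped: digitized disks can slightly exceed 1), second-moment ellipse
#' semi-axes and eccentricity eps = sqrt(1 - (b/a)^2), centroid, and the
#' mean and integrated OPD over the region's pixels.  Perimeter uses a
#' 4-direction Crofton (line-intercept) estimator, which is unbiased for
#' isotropic shapes and keeps C of digitized disks near 1.
#'
#' @param labels a [LabelMap-class].
#' @param opd the matching [OpdImage-class].
#' @return a data.frame with one row per region: `label`, `area_um2`,
#'   `perimeter_um`, `circularity`, `eccentricity`, `major_axis_um`,
#'   `minor_axis_um`, `centroid_row_um`, `centroid_col_um`, `mean_opd_nm`,
#'   `integrated_opd_nm_um2`, `border_touching`.
#' @export
extractFeatures <- function(labels, opd) {
  stopifnot(is(labels, "LabelMap"), is(opd, "OpdImage"))
  if (!identical(dim(labels@values), dim(opd@values)))
    stop("label map and OPD image shapes differ")
  p_um <- labels@pixelSize / 1000
  n <- labels@nLabels
  out <- vector("list", n)
  lab <- labels@values
  Z <- opd@values
  for (i in seq_len(n)) {
    px <- which(lab == i, arr.ind = TRUE)
    npx <- nrow(px)
    area <- npx * p_um^2
    rr <- range(px[, 1]); cc <- range(px[, 2])
    sub <- matrix(0L, diff(rr) + 1L, diff(cc) + 1L)
    sub[cbind(px[, 1] - rr[1] + 1L, px[, 2] - cc[1] + 1L)] <- 1L
    per <- .croftonPerimeter(sub) * p_um
    circ <- 4 * pi * area / per^2
    mu_r <- mean(px[, 1]); mu_c <- mean(px[, 2])
    if (npx > 1L) {
      cv <- stats::cov(px) * (npx - 1) / npx   # population second moments
      ev <- eigen(cv, symmetric = TRUE)$values
      ev <- pmax(ev, 0)
      a_px <- 2 * sqrt(ev[1]); b_px <- 2 * sqrt(ev[2])
      ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
    } else {
      a_px <- b_px <- 0; ecc <- 0
    }
    vals <- Z[lab == i]
    out[[i]] <- data.frame(
      label = i, area_um2 = area, perimeter_um = per, circularity = circ,
      eccentricity = ecc, major_axis_um = 2 * a_px * p_um,
      minor_axis_um = 2 * b_px * p_um,
      centroid_row_um = mu_r * p_um, centroid_col_um = mu_c * p_um,
      mean_opd_nm = mean(vals),
      integrated_opd_nm_um2 = sum(vals) * p_um^2,
      border_touching = labels@borderTouching[i])
  }
  if (!n) {
    return(data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), circularity = numeric(),
                      eccentricity = numeric(), major_axis_um = numeric(),
                      minor_axis_um = numeric(), centroid_row_um = numeric(),
                      centroid_col_um = numeric(), mean_opd_nm = numeric(),
                      integrated_opd_nm_um2 = numeric(),
                      border_touching = logical()))
  }
  do.call(rbind, out)
}

#' Cell-free background mask
#'
#' Complement of all labeled regions grown by a guard band: the region
#' over which the per-image OPD noise (delta_OPD) is estimated.
#'
#' @param labels a [LabelMap-class].
#' @param guardRadius disk radius (px) by which labels are grown before
#'   taking the complement (default 3).
#' @return logical matrix, TRUE = cell-free pixel.
#' @export
cellFreeMask <- function(labels, guardRadius = 3L) {
  stopifnot(is(labels, "LabelMap"), guardRadius >= 0)
  cells <- labels@values > 0L
  if (any(cells) && guardRadius > 0L) {
    cells <- EBImage::dilate(matrix(as.numeric(cells), nrow(cells), ncol(cells)),
                             .discBrush(guardRadius)) > 0
  }
  if (all(cells)) stop("no cell-free pixels remain")
  !cells
}
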