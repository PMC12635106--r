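#' Specify a synthetic cell
#'
#' Geometry and refractive contrast of one simulated cell.  A coccus is a
#' sphere of radius `radius`; a bacillus is a spherocylinder (cylinder of
#' length `length` capped by hemispheres of radius `radius`); a cluster is
#' a set of spheres at `memberOffsets` relative to the center, with
#' per-member radii `memberRadii`.
#'
#' @param kind "coccus", "bacillus" or "cluster".
#' @param center c(row, col) center in um (NA until placed in a scene).
#' @param radius sphere/cap radius R (um).
#' @param length cylinder length l (um, bacillus only; total length is
#'   l + 2R).
#' @param orientation axis angle (radians, bacillus only).
#' @param memberOffsets list of c(row, col) um offsets (cluster only).
#' @param memberRadii numeric vector of member radii (cluster only;
#'   defaults to `radius` for every member).
#' @param deltaN refractive contrast n_c - n_m (dimensionless).
#' @return a list of class `CellSpec`.
#' @export
cellSpec <- function(kind = c("coccus", "bacillus", "cluster"),
                     center = c(NA_real_, NA_real_), radius, length = 0,
                     orientation = 0, memberOffsets = NULL,
                     memberRadii = NULL, deltaN) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("radius must be positive")
  if (length < 0) stop("length must be >= 0")
  if (deltaN < 0) stop("deltaN must be >= 0")
  if (kind == "cluster") {
    if (is.null(memberOffsets) || base::length(memberOffsets) < 2L)
      stop("a cluster needs at least 2 member offsets")
    if (is.null(memberRadii))
      memberRadii <- rep(radius, base::length(memberOffsets))
    if (base::length(memberRadii) != base::length(memberOffsets))
      stop("memberRadii must match memberOffsets")
  }
  structure(list(kind = kind, center = center, radius = radius,
                 length = length, orientation = orientation,
                 memberOffsets = memberOffsets, memberRadii = memberRadii,
                 deltaN = deltaN),
            class = "CellSpec")
}

## analytic volume in um^3
.cellVolume <- function(spec) {
  switch(spec$kind,
    coccus = 4 / 3 * pi * spec$radius^3,
    bacillus = pi * spec$radius^2 * spec$length + 4 / 3 * pi * spec$radius^3,
    cluster = sum(4 / 3 * pi * spec$memberRadii^3))
}

## projected thickness (um) at points (r, c) in um, for one primitive
.sphereThickness <- function(r, c, center, R) {
  d2 <- (r - center[1])^2 + (c - center[2])^2
  2 * sqrt(pmax(R^2 - d2, 0))
}

.rodThickness <- function(r, c, center, R, l, phi) {
  ## distance to the axis segment of half-length l/2 along direction phi
  ur <- cos(phi); uc <- sin(phi)
  dr <- r - center[1]; dc <- c - center[2]
  t <- pmin(pmax(dr * ur + dc * uc, -l / 2), l / 2)
  d2 <- (dr - t * ur)^2 + (dc - t * uc)^2
  2 * sqrt(pmax(R^2 - d2, 0))
}

.cellThickness <- function(spec, r, c) {
  switch(spec$kind,
    coccus = .sphereThickness(r, c, spec$center, spec$radius),
    bacillus = .rodThickness(r, c, spec$center, spec$radius, spec$length,
                             spec$orientation),
    cluster = {
      h <- 0
      for (i in seq_along(spec$memberOffsets))
        h <- h + .sphereThickness(r, c, spec$center + spec$memberOffsets[[i]],
                                  spec$memberRadii[i])
      h
    })
}

## footprint half-extent in um (bounding radius around the center)
.cellExtent <- function(spec) {
  switch(spec$kind,
    coccus = spec$radius,
    bacillus = spec$length / 2 + spec$radius,
    cluster = max(vapply(seq_along(spec$memberOffsets), function(i)
      sqrt(sum(spec$memberOffsets[[i]]^2)) + spec$memberRadii[i], numeric(1))))
}

#' Render one cell's OPD patch and analytic dry mass
#'
#' The OPD of a cell with uniform refractive contrast is deltaN times the
#' projected thickness, so the grid-summed OPD equals deltaN * V and the
#' true dry mass is deltaN * V / alpha with V the analytic shape volume.
#' Pixels are rendered with `supersample` x `supersample` sub-pixel
#' averaging to reduce digitization error.
#'
#' @param spec a [cellSpec()] with a placed center.
#' @param const a [massConstants()] list.
#' @param shape c(rows, cols) of the target grid.
#' @param pixelSize pixel size (nm).
#' @param supersample sub-pixel sampling factor (default 4).
#' @return list with `opd` (matrix, nm, full grid), `support` (logical
#'   matrix), `mass_fg` (analytic truth), and `clipped` (TRUE when the
#'   cell extends beyond the grid).
#' @export
cellOpdAndMass <- function(spec, const = massConstants(), shape,
                           pixelSize, supersample = 4L) {
  stopifnot(inherits(spec, "CellSpec"), all(is.finite(spec$center)))
  p_um <- pixelSize / 1000
  ext <- .cellExtent(spec)
  r0 <- floor((spec$center[1] - ext) / p_um) - 1L
  r1 <- ceiling((spec$center[1] + ext) / p_um) + 1L
  c0 <- floor((spec$center[2] - ext) / p_um) - 1L
  c1 <- ceiling((spec$center[2] + ext) / p_um) + 1L
  clipped <- r0 < 1L || c0 < 1L || r1 > shape[1] || c1 > shape[2]
  rr <- max(r0, 1L):min(r1, shape[1])
  cc <- max(c0, 1L):min(c1, shape[2])
  s <- as.integer(supersample)
  off <- (seq_len(s) - 0.5) / s - 0.5       # sub-pixel offsets in px
  patch <- matrix(0, length(rr), length(cc))
  for (dr in off) for (dc in off) {
    rg <- (rr - 0.5 + dr) * p_um
    cg <- (cc - 0.5 + dc) * p_um
    G <- expand.grid(r = rg, c = cg)
    patch <- patch + matrix(.cellThickness(spec, G$r, G$c),
                            length(rr), length(cc))
  }
  patch <- patch / s^2
  opd <- matrix(0, shape[1], shape[2])
  opd[rr, cc] <- spec$deltaN * patch * 1000   # um thickness -> nm OPD
  ## true pixel mask: pixels whose center falls inside the cell (antialiased
  ## partial-coverage pixels at the rim are excluded)
  Gc <- expand.grid(r = (rr - 0.5) * p_um, c = (cc - 0.5) * p_um)
  support <- matrix(FALSE, shape[1], shape[2])
  support[rr, cc] <- matrix(.cellThickness(spec, Gc$r, Gc$c) > 0,
                            length(rr), length(cc))
  list(opd = opd, support = support,
       mass_fg = spec$deltaN * .cellVolume(spec) / const$alpha,
       clipped = clipped)
}

#' Sample a synthetic cell population
#'
#' Draws dry masses from a Koch-Schaechter division model and converts
#' them to cell geometries.  Bacilli have fixed width (2R = 1.19 um) and
#' total length L = 1.193 + 0.006 * M, with the refractive contrast solved
#' from mass and volume.  Cocci draw a contrast uniformly from
#' `deltaNRange` and solve the radius from R = (3 M alpha / (4 pi
#' deltaN))^(1/3); a fraction of cocci entries become clusters of 2-4
#' touching members, each member with its own mass.
#'
#' @param n number of population entries.
#' @param strain "cocci" or "bacilli".
#' @param model a [DivisionModel-class]; defaults to (272, 77) fg for
#'   cocci and (751, 213) fg for bacilli.
#' @param clusterFraction fraction of cocci entries generated as clusters
#'   (default 0.49).
#' @param deltaNRange contrast range for cocci (default c(0.03, 0.08)).
#' @param memberOverlap relative center overlap of cluster members
#'   (default 0.35: centers at (R1+R2)*(1-overlap)).
#' @param minRadius smallest generated coccus radius (um, default 0.25,
#'   half the instrument's 0.53 um lateral resolution): the steady-state
#'   density's erf form diverges like 1/m near zero mass, and the
#'   corresponding sub-resolution cells are invisible to the instrument,
#'   so such draws are rejected and resampled.
#' @param seed RNG seed.
#' @param const a [massConstants()] list.
#' @return a list of [cellSpec()] objects (centers unplaced).
#' @export
samplePopulation <- function(n, strain = c("cocci", "bacilli"), model = NULL,
                             clusterFraction = 0.49,
                             deltaNRange = c(0.03, 0.08),
                             memberOverlap = 0.35, minRadius = 0.25,
                             seed = 1L, const = massConstants()) {
  strain <- match.arg(strain)
  if (is.null(model))
    model <- if (strain == "cocci") divisionModel(272, 77)
             else divisionModel(751, 213)
  masses <- ksSample(model, 20L * n, seed = seed)  # head used; spares for retries
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 1L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  nextMass <- local({ i <- 0L; function() {
    i <<- i + 1L
    if (i > length(masses)) stop("mass reservoir exhausted; too many rejections")
    masses[i]
  } })
  coccusGeom <- function() {
    for (try in 1:50) {
      M <- nextMass()
      dn <- stats::runif(1, deltaNRange[1], deltaNRange[2])
      R <- (3 * M * const$alpha / (4 * pi * dn))^(1 / 3)
      if (R >= minRadius) return(list(R = R, dn = dn))
    }
    stop("could not draw a resolvable coccus")
  }
  makeCoccus <- function() {
    g <- coccusGeom()
    cellSpec("coccus", radius = g$R, deltaN = g$dn)
  }
  makeBacillus <- function() {
    R <- 1.19 / 2
    for (try in 1:50) {
      M <- nextMass()
      L <- 1.193 + 0.006 * M
      l <- L - 2 * R
      if (l <= 0) next
      V <- pi * R^2 * l + 4 / 3 * pi * R^3
      dn <- M * const$alpha / V
      if (dn >= 0.01 && dn <= 0.12)
        return(cellSpec("bacillus", radius = R, length = l,
                        orientation = stats::runif(1, 0, pi), deltaN = dn))
    }
    stop("could not draw a feasible bacillus contrast")
  }
  makeCluster <- function() {
    k <- sample(2:4, 1L, prob = c(0.6, 0.3, 0.1))
    dn <- stats::runif(1, deltaNRange[1], deltaNRange[2])
    memberR <- function() {
      for (try in 1:50) {
        R <- (3 * nextMass() * const$alpha / (4 * pi * dn))^(1 / 3)
        if (R >= minRadius) return(R)
      }
      stop("could not draw a resolvable cluster member")
    }
    Rs <- vapply(seq_len(k), function(i) memberR(), numeric(1))
    ## chain members along a random direction, touching with overlap
    offs <- vector("list", k)
    offs[[1]] <- c(0, 0)
    pos <- c(0, 0)
    for (i in 2:k) {
      ang <- stats::runif(1, 0, 2 * pi)
      d <- (Rs[i - 1] + Rs[i]) * (1 - memberOverlap)
      pos <- pos + d * c(cos(ang), sin(ang))
      offs[[i]] <- pos
    }
    ctr <- colMeans(do.call(rbind, offs))
    offs <- lapply(offs, function(o) o - ctr)
    cellSpec("cluster", radius = max(Rs), memberOffsets = offs,
             memberRadii = Rs, deltaN = dn)
  }
  lapply(seq_len(n), function(i) {
    if (strain == "bacilli") makeBacillus()
    else if (stats::runif(1) < clusterFraction) makeCluster()
    else makeCoccus()
  })
}

#' Scene configuration
#'
#' Defaults emulate the instrument: an 802 x 764 px field at 90.6 nm
#' pixels, a smooth random polynomial background (total degree 6, ~30 nm
#' peak-to-valley) and 2.0 nm Gaussian noise (the stated vertical
#' resolution).
#'
#' @param shape c(rows, cols) in pixels.
#' @param pixelSize pixel size (nm).
#' @param backgroundDegree maximum total degree of the background surface.
#' @param backgroundPV target background peak-to-valley (nm).
#' @param noiseSd Gaussian noise standard deviation (nm).
#' @param marginPx minimum cell distance from the border (px), beyond the
#'   cell's own extent.
#' @param supersample sub-pixel rendering factor.
#' @return a named list.
#' @export
sceneConfig <- function(shape = c(802L, 764L), pixelSize = 90.6,
                        backgroundDegree = 6L, backgroundPV = 30,
                        noiseSd = 2.0, marginPx = 3L, supersample = 4L) {
  list(shape = as.integer(shape), pixelSize = pixelSize,
       backgroundDegree = as.integer(backgroundDegree),
       backgroundPV = backgroundPV, noiseSd = noiseSd,
       marginPx = as.integer(marginPx), supersample = as.integer(supersample))
}

## random smooth background: orthonormal-basis coefficients decaying
## geometrically with total degree, rescaled to the target peak-to-valley
.randomBackground <- function(shape, degree, pv) {
  Px <- .orthoBasis(shape[1], degree)
  Py <- .orthoBasis(shape[2], degree)
  C <- matrix(0, degree + 1L, degree + 1L)
  for (i in 0:degree) for (j in 0:degree) {
    if (i + j > degree || (i == 0L && j == 0L)) next
    C[i + 1L, j + 1L] <- stats::rnorm(1, 0, 0.5^(i + j))
  }
  S <- Px %*% C %*% t(Py)
  rng <- max(S) - min(S)
  if (rng > 0) S <- S * (pv / rng)
  S
}

#' Generate a synthetic OPD scene with analytic ground truth
#'
#' Places cells without overlap (bounded retries), adds a smooth random
#' polynomial background and i.i.d. Gaussian noise, and records per-cell
#' true masses, the true support mask, and the background surface.
#' Reproducible under a fixed seed.
#'
#' @param config a [sceneConfig()] list.
#' @param cells list of [cellSpec()]s; unplaced centers are assigned
#'   random non-overlapping positions.  If NULL, `n` cells are drawn with
#'   [samplePopulation()].
#' @param n number of cells when `cells` is NULL (default 20).
#' @param strain population strain when `cells` is NULL.
#' @param seed RNG seed.
#' @param const a [massConstants()] list.
#' @return list with `opd` (the raw [OpdImage-class]) and `truth` (a
#'   [SceneTruth-class]).
#' @export
makeScene <- function(config = sceneConfig(), cells = NULL, n = 20L,
                      strain = "cocci", seed = 1L, const = massConstants()) {
  if (is.null(cells))
    cells <- samplePopulation(n, strain = strain, seed = seed, const = const)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 2L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  shape <- config$shape
  p_um <- config$pixelSize / 1000
  fieldR <- shape[1] * p_um; fieldC <- shape[2] * p_um
  placed <- list(); centers <- list(); exts <- numeric(0)
  for (i in seq_along(cells)) {
    spec <- cells[[i]]
    ext <- .cellExtent(spec)
    lo <- ext + config$marginPx * p_um
    ok <- FALSE
    for (try in 1:500) {
      ctr <- c(stats::runif(1, lo, fieldR - lo), stats::runif(1, lo, fieldC - lo))
      if (all(vapply(seq_along(centers), function(j)
        sqrt(sum((ctr - centers[[j]])^2)) > ext + exts[j] + 6 * p_um,
        logical(1)))) { ok <- TRUE; break }
    }
    if (!ok) stop(sprintf("could not place cell %d without overlap", i))
    spec$center <- ctr
    placed[[i]] <- spec
    centers[[i]] <- ctr
    exts[i] <- ext
  }
  bg <- .randomBackground(shape, config$backgroundDegree, config$backgroundPV)
  Z <- bg + matrix(stats::rnorm(prod(shape), 0, config$noiseSd),
                   shape[1], shape[2])
  mask <- matrix(0L, shape[1], shape[2])
  rows <- vector("list", length(placed))
  for (i in seq_along(placed)) {
    cm <- cellOpdAndMass(placed[[i]], const, shape, config$pixelSize,
                         config$supersample)
    if (cm$clipped) warning(sprintf("cell %d clipped at the border", i))
    Z <- Z + cm$opd
    mask[cm$support] <- i
    sp <- placed[[i]]
    rows[[i]] <- data.frame(
      cell = i, kind = sp$kind, center_row_um = sp$center[1],
      center_col_um = sp$center[2], radius_um = sp$radius,
      length_um = sp$length,
      n_members = if (sp$kind == "cluster") length(sp$memberOffsets) else 1L,
      delta_n = sp$deltaN, mass_fg = cm$mass_fg)
  }
  cellTab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(), kind = character(), center_row_um = numeric(),
               center_col_um = numeric(), radius_um = numeric(),
               length_um = numeric(), n_members = integer(),
               delta_n = numeric(), mass_fg = numeric())
  truth <- new("SceneTruth", cells = cellTab, mask = mask, background = bg)
  list(opd = OpdImage(Z, config$pixelSize), truth = truth, cells = placed)
}
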