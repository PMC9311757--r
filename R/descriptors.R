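## Conformational size and dipole descriptors.
##
## The minimal projection area (MPA) is the smallest area of the union of
## the molecule's van-der-Waals disks projected onto a plane, minimized
## over projection directions; Rmin = sqrt(MPA/pi) is the radius of the
## circle of equal area.  Areas are computed by exact-in-y chord slicing
## (see src/kernels.cpp); the direction search is a Fibonacci hemisphere
## grid plus local Nelder-Mead refinement (antipodal directions are
## identified).

# orthonormal basis of the plane perpendicular to d (unit)
.planeBasis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Area of a molecule's projection along one direction
#'
#' Projects every atom centre onto the plane perpendicular to `direction`
#' and returns the area of the union of the resulting van-der-Waals disks.
#' Invariant to the sign of `direction`.
#'
#' @param coords numeric `n x 3` matrix of atom coordinates, Å.
#' @param radii per-atom van der Waals radii, Å.
#' @param direction non-zero 3-vector (normalized internally).
#' @param nSlices slicing resolution of the area kernel; the default keeps
#'   the relative quadrature error well below 0.2%.
#' @return Projected area, Å^2.
#' @examples
#' projectionArea(matrix(0, 1, 3), 2, c(0, 0, 1))  # pi * 4
#' @export
projectionArea <- function(coords, radii, direction, nSlices = 4096L) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("empty atom list")
  radii <- rep_len(radii, nrow(coords))
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be non-zero")
  d <- direction / nd
  b <- .planeBasis(d)
  .disk_union_area(as.vector(coords %*% b$e1),
                   as.vector(coords %*% b$e2), radii,
                   as.integer(nSlices))
}

# Fibonacci grid on the upper hemisphere (antipodal pairs identified)
.fibonacciHemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  zc <- i / n                      # cos(theta) in (0, 1): upper hemisphere
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  st <- sqrt(1 - zc^2)
  cbind(st * cos(phi), st * sin(phi), zc)
}

#' Minimal projection area of a conformer
#'
#' Minimizes [projectionArea()] over projection directions: a Fibonacci
#' hemisphere grid of `nDirs` directions followed by local Nelder-Mead
#' refinement in spherical angles around the best grid direction.  The
#' returned area never exceeds the best sampled direction, and is bounded
#' below by the largest single-atom disk `pi * max(radii)^2`.
#'
#' @inheritParams projectionArea
#' @param nDirs number of hemisphere grid directions (>= 32; default 512).
#' @param refineTol relative convergence tolerance of the local refinement.
#' @param nSlices slicing resolution for the search stage; the final value
#'   is evaluated at `4 * nSlices`.
#' @return list with `mpa` (Å^2), `direction` (unit 3-vector, the
#'   minimizing projection axis), and `method` metadata (search size,
#'   slicing resolutions).
#' @examples
#' rod <- cbind(0, 0, seq(0, 12, by = 1.5))
#' out <- minimalProjectionArea(rod, 1.7)
#' out$mpa / (pi * 1.7^2)  # ~1 for a thin rod
#' @export
minimalProjectionArea <- function(coords, radii, nDirs = 512L,
                                  refineTol = 1e-4, nSlices = 1024L) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("empty atom list")
  radii <- rep_len(radii, nrow(coords))
  if (all(radii <= 0)) stop("degenerate input: all radii are zero")
  if (nDirs < 32L) stop("nDirs must be >= 32")
  dirs <- .fibonacciHemisphere(as.integer(nDirs))
  areas <- vapply(seq_len(nrow(dirs)), function(i)
    projectionArea(coords, radii, dirs[i, ], nSlices), numeric(1))
  obj <- function(a) {
    d <- c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))
    projectionArea(coords, radii, d, nSlices)
  }
  ## multi-start local refinement from the best grid directions (the area
  ## landscape over directions is multimodal for branched shapes)
  starts <- order(areas)[seq_len(min(6L, length(areas)))]  # ties: first
  bestVal <- areas[starts[1]]
  d0 <- dirs[starts[1], ]
  aBest <- c(acos(min(1, max(-1, d0[3]))), atan2(d0[2], d0[1]))
  for (s in starts) {
    ds <- dirs[s, ]
    a0 <- c(acos(min(1, max(-1, ds[3]))), atan2(ds[2], ds[1]))
    opt <- stats::optim(a0, obj, method = "Nelder-Mead",
                        control = list(reltol = refineTol, maxit = 200))
    if (opt$value < bestVal) {
      bestVal <- opt$value
      aBest <- opt$par
    }
  }
  dBest <- c(sin(aBest[1]) * cos(aBest[2]),
             sin(aBest[1]) * sin(aBest[2]), cos(aBest[1]))
  mpa <- projectionArea(coords, radii, dBest, 4L * as.integer(nSlices))
  list(mpa = mpa, direction = dBest,
       method = list(search = "fibonacci+nelder-mead", nDirs = nDirs,
                     nSlicesSearch = nSlices, nSlicesFinal = 4L * nSlices,
                     areaMethod = "chord-slicing union of vdW disks",
                     relTolArea = 2e-3))
}

#' Minimum radius from a projection area
#'
#' The radius of the circle with the same area, `sqrt(MPA / pi)`.
#'
#' @param mpa projection area, Å^2 (>= 0).
#' @return Radius, Å.
#' @examples
#' rminFromArea(pi)        # 1
#' rminFromArea(pi * 3.4^2)  # 3.4
#' @export
rminFromArea <- function(mpa) {
  if (any(mpa < 0)) stop("negative area")
  sqrt(mpa / pi)
}

#' Electric dipole moment from point charges
#'
#' `mu = sum_i q_i (r_i - r0)` converted from e·Å to Debye.  For neutral
#' molecules the result is origin independent; for net-charged species the
#' origin convention matters and is recorded by the caller (default:
#' centre of mass).
#'
#' @param coords numeric `n x 3`, Å.
#' @param charges per-atom charges, e.
#' @param masses per-atom masses (needed for `origin = "com"`; equal
#'   masses assumed if missing).
#' @param origin `"com"` (centre of mass, default), `"geometric"` (mean of
#'   atom positions) or `"zero"` (laboratory origin).
#' @return Dipole 3-vector, Debye.
#' @examples
#' dipoleMoment(rbind(c(1, 0, 0), c(-1, 0, 0)), c(0.5, -0.5))
#' @export
dipoleMoment <- function(coords, charges, masses = NULL,
                         origin = c("com", "geometric", "zero")) {
  origin <- match.arg(origin)
  coords <- rbind(coords)
  if (length(charges) != nrow(coords))
    stop("coords and charges lengths differ")
  r0 <- switch(origin,
    com = {
      if (is.null(masses)) masses <- rep(1, nrow(coords))
      colSums(coords * masses) / sum(masses)
    },
    geometric = colMeans(coords),
    zero = c(0, 0, 0))
  mu <- colSums((coords - rep(r0, each = nrow(coords))) * charges)
  unname(mu * .E_ANG_TO_DEBYE)
}

#' Transversal component of a dipole with respect to the main axis
#'
#' Magnitude of the dipole component in the plane perpendicular to the
#' molecular main axis `n` (the MPA projection direction):
#' `|mu - (mu . n) n|`.
#'
#' @param mu dipole 3-vector, Debye.
#' @param n unit 3-vector (checked to tolerance 1e-6).
#' @return Transversal dipole magnitude, Debye.
#' @examples
#' transversalDipole(c(3, 4, 0), c(1, 0, 0))  # 4
#' @export
transversalDipole <- function(mu, n) {
  if (abs(sqrt(sum(n^2)) - 1) > 1e-6) stop("n must be a unit vector")
  perp <- mu - sum(mu * n) * n
  sqrt(sum(perp^2))
}

#' Per-frame descriptors of a conformer ensemble
#'
#' Computes, frame by frame, the minimal projection area (MPA), the
#' minimum radius Rmin, the dipole vector and its total and transversal
#' magnitudes, where transversal means perpendicular to the MPA axis.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param nDirs direction-search size for [minimalProjectionArea()].
#' @param origin dipole origin convention, see [dipoleMoment()].
#' @param nSlices slicing resolution of the area kernel.
#' @return data.frame with one row per frame: `frame`, `mpa` (Å^2),
#'   `rmin` (Å), `nx`, `ny`, `nz` (MPA axis), `mux`, `muy`, `muz`,
#'   `dipoleTotal`, `dipoleXY` (Debye).  Metadata (origin convention, area
#'   method and tolerance) is attached as `attr(x, "method")`.
#' @examples
#' ens <- simulateConformers("rod", nAtoms = 4, nFrames = 2,
#'                           charges = c(0.5, 0, 0, -0.5))
#' computeDescriptors(ens, nDirs = 64)
#' @export
computeDescriptors <- function(ensemble, nDirs = 512L,
                               origin = c("com", "geometric", "zero"),
                               nSlices = 1024L) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  origin <- match.arg(origin)
  nf <- nFrames(ensemble)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    m <- frameCoords(ensemble, f)
    mp <- minimalProjectionArea(m, vdwRadii(ensemble), nDirs = nDirs,
                                nSlices = nSlices)
    mu <- dipoleMoment(m, atomCharges(ensemble),
                       masses = atomMasses(ensemble), origin = origin)
    out[[f]] <- data.frame(
      frame = f, mpa = mp$mpa, rmin = rminFromArea(mp$mpa),
      nx = mp$direction[1], ny = mp$direction[2], nz = mp$direction[3],
      mux = mu[1], muy = mu[2], muz = mu[3],
      dipoleTotal = sqrt(sum(mu^2)),
      dipoleXY = transversalDipole(mu, mp$direction))
  }
  res <- do.call(rbind, out)
  attr(res, "method") <- list(origin = origin, nDirs = nDirs,
                              areaMethod = "chord-slicing union of vdW disks",
                              relTolArea = 2e-3)
  res
}

#' Summarize the distribution of one descriptor
#'
#' Mean, fixed-width histogram (normalized to integrate to 1) and
#' histogram modes.  Modes are bin centres of local density maxima whose
#' height exceeds the deeper adjacent valley by at least 1% of the peak
#' density, so bimodal ensembles (e.g. extended vs compact conformer
#' populations) report both modes.
#'
#' @param x numeric vector of per-frame values (>= 1).
#' @param binWidth histogram bin width; the conventional choices are
#'   0.1 Å for Rmin and 1 D for dipoles.
#' @return A [DescriptorSummary-class].
#' @examples
#' s <- summarizeDescriptor(c(rep(4.0, 50), rep(4.7, 40)), binWidth = 0.1)
#' s@modes
#' @export
summarizeDescriptor <- function(x, binWidth = 0.1) {
  if (!length(x)) stop("empty input")
  if (binWidth <= 0) stop("binWidth must be positive")
  lo <- floor(min(x) / binWidth) * binWidth
  hi <- ceiling(max(x) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi + binWidth / 2, by = binWidth)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  dens <- cnt / (sum(cnt) * binWidth)
  new("DescriptorSummary", mean = mean(x), modes = .histModes(breaks, dens),
      breaks = breaks, density = dens, binWidth = binWidth,
      metadata = list(n = length(x)))
}

# bin centres of prominent local maxima of a histogram density
.histModes <- function(breaks, dens) {
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  n <- length(dens)
  if (n == 1L) return(centres)
  peak <- max(dens)
  padded <- c(-Inf, dens, -Inf)
  cand <- which(padded[2:(n + 1)] > padded[1:n] &
                  padded[2:(n + 1)] >= padded[3:(n + 2)])
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    ## valley-to-peak prominence against the nearest higher maxima
    leftHigher <- cand[cand < i & dens[cand] > dens[i]]
    rightHigher <- cand[cand > i & dens[cand] > dens[i]]
    promL <- if (length(leftHigher))
      dens[i] - min(dens[max(leftHigher):i]) else dens[i]
    promR <- if (length(rightHigher))
      dens[i] - min(dens[i:min(rightHigher)]) else dens[i]
    keep[k] <- min(promL, promR) >= 0.01 * peak
  }
  sort(centres[cand[keep]])
}

#' Overlap coefficient of two descriptor distributions
#'
#' `integral min(pdfA, pdfB) dx` of the two histogram densities after
#' re-binning onto a common fine grid; 1 for identical distributions, 0
#' for disjoint supports.
#'
#' @param a,b [DescriptorSummary-class] objects.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
distributionOverlap <- function(a, b) {
  stopifnot(is(a, "DescriptorSummary"), is(b, "DescriptorSummary"))
  step <- min(a@binWidth, b@binWidth) / 8
  lo <- min(a@breaks[1], b@breaks[1])
  hi <- max(tail(a@breaks, 1), tail(b@breaks, 1))
  xs <- seq(lo + step / 2, hi, by = step)
  pA <- .histDensityAt(a, xs)
  pB <- .histDensityAt(b, xs)
  min(1, max(0, sum(pmin(pA, pB)) * step))
}

.histDensityAt <- function(s, xs) {
  i <- findInterval(xs, s@breaks, rightmost.closed = TRUE)
  out <- numeric(length(xs))
  ok <- i >= 1L & i <= length(s@density)
  out[ok] <- s@density[i[ok]]
  out
}

#' Probe-accessible pore-size profile of a channel structure
#'
#' For each z slice, computes the area of in-plane points (inside a
#' circular outer boundary of radius `boxRadius`) whose distance to every
#' atom centre projected from the slab exceeds that atom's van der Waals
#' radius plus `probeRadius`, and reports the equivalent minimum radius
#' `sqrt(area / pi)`.  Slices with no atoms in the slab return the full
#' outer-box area and are flagged.
#'
#' @param coords numeric `n x 3` matrix (one structure/frame), Å.
#' @param radii per-atom van der Waals radii, Å.
#' @param probeRadius probe radius, Å (default 1.4, a water molecule).
#' @param zSlices either a number of slices (a single whole number >= 2,
#'   spread across the atoms' z extent; default 40) or a vector of
#'   explicit slice centres (Å).
#' @param slabHalfWidth half thickness of each slab, Å; default half the
#'   slice spacing.
#' @param boxRadius outer boundary radius, Å; default the largest radial
#'   distance of any atom centre from the z axis.
#' @param nSlices area-kernel slicing resolution.
#' @return data.frame with columns `z`, `area` (Å^2), `rmin` (Å),
#'   `nAtoms`, `flagged`; the channel minimum radius over unflagged slices
#'   is attached as `attr(x, "channelRmin")` and the outer box as
#'   `attr(x, "boxRadius")`.
#' @export
poreProfile <- function(coords, radii, probeRadius = 1.4, zSlices = 40L,
                        slabHalfWidth = NULL, boxRadius = NULL,
                        nSlices = 2048L) {
  if (probeRadius < 0) stop("probeRadius must be >= 0")
  coords <- rbind(coords)
  radii <- rep_len(radii, nrow(coords))
  if (length(zSlices) == 1L && zSlices >= 2 && zSlices == round(zSlices)) {
    ## a single whole number >= 2 is a slice count; anything else is taken
    ## as explicit slice centre(s)
    zr <- range(coords[, 3])
    zSlices <- seq(zr[1], zr[2], length.out = as.integer(zSlices))
  }
  if (is.null(slabHalfWidth))
    slabHalfWidth <- if (length(zSlices) > 1L)
      diff(zSlices[1:2]) / 2 else 1
  if (is.null(boxRadius))
    boxRadius <- max(sqrt(coords[, 1]^2 + coords[, 2]^2))
  rows <- lapply(zSlices, function(zc) {
    sel <- abs(coords[, 3] - zc) <= slabHalfWidth
    if (!any(sel)) {
      area <- pi * boxRadius^2
      return(data.frame(z = zc, area = area,
                        rmin = sqrt(area / pi), nAtoms = 0L,
                        flagged = TRUE))
    }
    area <- .free_area_in_circle(coords[sel, 1], coords[sel, 2],
                                 radii[sel] + probeRadius, boxRadius,
                                 as.integer(nSlices))
    data.frame(z = zc, area = area, rmin = sqrt(area / pi),
               nAtoms = sum(sel), flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !out$flagged
  attr(out, "channelRmin") <- if (any(ok)) min(out$rmin[ok]) else NA_real_
  attr(out, "boxRadius") <- boxRadius
  out
}
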