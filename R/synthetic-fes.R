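## Synthetic 2D free-energy surfaces with analytic ground truth.
##
## Functional form: a Gaussian barrier in z near the constriction (z = 0),
## Gaussian affinity wells, optional band-limited roughness, all multiplied
## by a smooth window that is exactly zero over `bulkWidth` at both z ends,
## so the bulk plateaus are the reference 0 by construction.  In the
## separable case a CV1-only confinement term may be added; it is shifted so
## its Boltzmann average over CV1 is exactly zero, hence the analytic
## marginal of a separable surface is the z-part itself.

#' Generate a synthetic 2D free-energy surface with known ground truth
#'
#' Emulates a metadynamics free-energy surface over (CV1, z): flat bulk
#' plateaus at both z ends, a central barrier near z = 0, optional affinity
#' wells and band-limited roughness.  For `separable = TRUE` the surface is
#' `F(cv1, z) = Fz(z) + Fc(cv1)` and the exact 1D marginal (`Fz`) is
#' returned as ground truth.
#'
#' @param zRange numeric `c(z_min, z_max)`, Å; z runs cis (extracellular,
#'   negative) to trans (periplasmic, positive) with the constriction at 0.
#' @param cv1Range numeric `c(a, b)`, dimensionless orientation variable.
#' @param dims integer `c(n_cv1, n_z)` grid shape.
#' @param bulkWidth width of the exactly flat plateau at each z end, Å.
#' @param barrierHeight central barrier height, kcal/mol (>= 0).
#' @param barrierWidth Gaussian width (sd) of the barrier, Å.
#' @param wells `NULL` or data.frame with columns `depth` (kcal/mol, > 0
#'   meaning a well), `z` (Å) and optionally `width` (Å, default 3) and
#'   `cv1` (well centre in CV1 for non-separable surfaces).
#' @param separable logical; if `TRUE` the surface is a sum of a z-part and
#'   a CV1-part and the analytic marginal is exact.
#' @param cv1Confinement amplitude of a quadratic CV1 confinement,
#'   kcal/mol (0 disables it; it is Boltzmann-centred so it never shifts
#'   the marginal).
#' @param roughnessAmplitude rms of a seeded band-limited roughness field,
#'   kcal/mol; in the separable case the roughness depends on z only, so
#'   the ground truth stays exact.
#' @param temperature K (controls the Boltzmann centring of the CV1 term).
#' @param seed integer seed; identical seed and arguments give identical grids.
#' @return list with elements `fes` (a [FES2D-class]) and `truth` (list:
#'   `marginal` — exact bulk-referenced 1D profile on the z grid (separable
#'   case), `barrierHeight` — analytic maximum of the z-part inside the
#'   channel, `zPart` — the analytic z-component).
#' @examples
#' g <- simulateFES(barrierHeight = 5, separable = TRUE, seed = 7)
#' max(g$truth$marginal)
#' @export
simulateFES <- function(zRange = c(-25, 25), cv1Range = c(-1, 1),
                        dims = c(41L, 121L), bulkWidth = 10,
                        barrierHeight = 5, barrierWidth = 4,
                        wells = NULL, separable = TRUE,
                        cv1Confinement = 0, roughnessAmplitude = 0,
                        temperature = 300, seed = 1L) {
  if (barrierHeight < 0) stop("barrierHeight must be >= 0")
  if (diff(zRange) <= 0 || diff(cv1Range) <= 0)
    stop("ranges must be increasing")
  if (bulkWidth <= 0 || 2 * bulkWidth >= diff(zRange))
    stop("bulkWidth must be positive and leave an interior region")
  nCv1 <- as.integer(dims[1]); nZ <- as.integer(dims[2])
  if (nCv1 < 2L || nZ < 4L) stop("grid too small")
  wells <- .normalizeWells(wells, zRange, bulkWidth)

  cv1 <- seq(cv1Range[1], cv1Range[2], length.out = nCv1)
  z <- seq(zRange[1], zRange[2], length.out = nZ)
  win <- .bulkWindow(z, zRange, bulkWidth)

  zPartRaw <- function(zz) {
    f <- barrierHeight * exp(-zz^2 / (2 * barrierWidth^2))
    if (nrow(wells)) {
      for (k in seq_len(nrow(wells)))
        f <- f - wells$depth[k] *
          exp(-(zz - wells$z[k])^2 / (2 * wells$width[k]^2))
    }
    f
  }

  rough <- .withSeed(seed, .roughField(roughnessAmplitude, separable,
                                       zRange, cv1Range))
  zPart <- (zPartRaw(z) + rough$fz(z)) * win
  kT <- .kT(temperature)

  if (separable) {
    fc <- cv1Confinement * ((cv1 - mean(cv1Range)) / (diff(cv1Range) / 2))^2
    # Boltzmann-centre the CV1 term so it contributes nothing to the marginal
    w <- .trapWeights(cv1)
    fc <- fc + kT * log(sum(w * exp(-fc / kT)) / sum(w))
    values <- outer(fc, zPart, `+`)
  } else {
    coupling <- outer(cv1 - mean(cv1Range), win * rough$fzc(z))
    base <- outer(rep(1, nCv1), zPart)
    wellPart <- 0
    if (nrow(wells) && any(!is.na(wells$cv1))) {
      wellPart <- matrix(0, nCv1, nZ)
      for (k in seq_len(nrow(wells))) {
        if (is.na(wells$cv1[k])) next
        # re-add the z-only well and replace it by a localized (cv1, z) well
        wellPart <- wellPart +
          outer(rep(1, nCv1),
                win * wells$depth[k] *
                  exp(-(z - wells$z[k])^2 / (2 * wells$width[k]^2))) -
          outer(exp(-(cv1 - wells$cv1[k])^2 / (2 * (diff(cv1Range) / 6)^2)),
                win * wells$depth[k] *
                  exp(-(z - wells$z[k])^2 / (2 * wells$width[k]^2)))
      }
    }
    values <- base + coupling + rough$f2d(cv1, z, win) + wellPart
  }

  fes <- new("FES2D", cv1 = cv1, z = z, values = values,
             mask = matrix(FALSE, nCv1, nZ), temperature = temperature,
             metadata = list(separable = separable, seed = seed,
                             bulkWidth = bulkWidth))
  chan <- abs(z) <= (max(abs(zRange)) - bulkWidth)
  list(fes = fes,
       truth = list(marginal = if (separable) zPart else NULL,
                    zPart = zPart,
                    barrierHeight = max(zPart[chan])))
}

.normalizeWells <- function(wells, zRange, bulkWidth) {
  if (is.null(wells))
    return(data.frame(depth = numeric(), z = numeric(),
                      width = numeric(), cv1 = numeric()))
  wells <- as.data.frame(wells)
  if (!all(c("depth", "z") %in% names(wells)))
    stop("wells needs columns 'depth' and 'z'")
  if (is.null(wells$width)) wells$width <- 3
  if (is.null(wells$cv1)) wells$cv1 <- NA_real_
  bad <- wells$z < zRange[1] | wells$z > zRange[2]
  if (any(bad))
    stop(sprintf("well position(s) %s outside z range [%g, %g]",
                 paste(wells$z[bad], collapse = ", "),
                 zRange[1], zRange[2]))
  wells
}

# smooth window: exactly 0 over the bulk plateaus, cosine ramp to 1 over
# half a bulk width, 1 in the interior
.bulkWindow <- function(z, zRange, bulkWidth) {
  ramp <- bulkWidth / 2
  lo <- zRange[1] + bulkWidth; hi <- zRange[2] - bulkWidth
  wl <- ifelse(z <= lo, 0,
               ifelse(z >= lo + ramp, 1,
                      0.5 - 0.5 * cos(pi * (z - lo) / ramp)))
  wh <- ifelse(z >= hi, 0,
               ifelse(z <= hi - ramp, 1,
                      0.5 - 0.5 * cos(pi * (hi - z) / ramp)))
  wl * wh
}

# seeded band-limited roughness: a handful of random cosines, rms-scaled
.roughField <- function(amp, separable, zRange, cv1Range) {
  if (amp <= 0) {
    return(list(fz = function(z) 0 * z, fzc = function(z) 0 * z,
                f2d = function(cv1, z, win) 0))
  }
  K <- 6L
  wz <- runif(K, 0.2, 0.8) * 2 * pi / diff(zRange) * 8
  ph <- runif(K, 0, 2 * pi)
  a <- rnorm(K)
  a <- a / sqrt(sum(a^2) / 2) * amp  # rms of sum of cosines = amp
  fz <- function(z) {
    out <- 0 * z
    for (k in seq_len(K)) out <- out + a[k] * cos(wz[k] * z + ph[k])
    out
  }
  wc <- runif(K, 0.5, 2) * 2 * pi / diff(cv1Range)
  pc <- runif(K, 0, 2 * pi)
  if (separable) {
    list(fz = fz, fzc = function(z) 0 * z, f2d = function(cv1, z, win) 0)
  } else {
    list(fz = function(z) 0 * z,
         fzc = function(z) 0 * z,
         f2d = function(cv1, z, win) {
           out <- matrix(0, length(cv1), length(z))
           for (k in seq_len(K)) {
             out <- out + a[k] * outer(cos(wc[k] * cv1 + pc[k]),
                                       cos(wz[k] * z + ph[k]) * win)
           }
           out
         })
  }
}

.trapWeights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' Construct a synthetic 1D free-energy profile directly
#'
#' Convenience constructor for transport-stage studies: the same
#' barrier-plus-wells functional form as [simulateFES()] but built directly
#' as a referenced [FES1D-class] (bulk plateaus exactly 0), bypassing the
#' 2D stage.
#'
#' @inheritParams simulateFES
#' @param nZ number of z grid points.
#' @param channelThreshold |F| level (kcal/mol) that delimits the channel
#'   interval moving inward from the bulk; default `0.5 * kT`.
#' @return A [FES1D-class].
#' @examples
#' p <- syntheticProfile(barrierHeight = 3)
#' channelInterval(p)
#' @export
syntheticProfile <- function(zRange = c(-25, 25), nZ = 501L, bulkWidth = 10,
                             barrierHeight = 5, barrierWidth = 4,
                             wells = NULL, roughnessAmplitude = 0,
                             temperature = 300, seed = 1L,
                             channelThreshold = NULL) {
  g <- simulateFES(zRange = zRange, cv1Range = c(-1, 1),
                   dims = c(2L, as.integer(nZ)), bulkWidth = bulkWidth,
                   barrierHeight = barrierHeight,
                   barrierWidth = barrierWidth, wells = wells,
                   separable = TRUE, cv1Confinement = 0,
                   roughnessAmplitude = roughnessAmplitude,
                   temperature = temperature, seed = seed)
  z <- zGrid(g$fes)
  .makeFES1D(z, g$truth$zPart, temperature,
             bulkWindows = rbind(c(zRange[1], zRange[1] + bulkWidth),
                                 c(zRange[2] - bulkWidth, zRange[2])),
             channelThreshold = channelThreshold,
             metadata = list(synthetic = TRUE, seed = seed,
                             barrierHeight = barrierHeight))
}
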