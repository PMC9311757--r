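## Transport predictions from a 1D free-energy profile.
##
## Low concentration: the stationary Smoluchowski equation gives a current
## proportional to the concentration gradient with permeability
##   P = D * sigma_ref * gamma / integral_channel exp(F(z)/kT) dz,
## gamma converting molarity to number density.  High concentration: a
## single-occupancy two-state Markov channel (empty/occupied) whose exit
## rates come from the mean first-passage time out of the deepest channel
## well and the splitting probabilities, giving a linear-then-saturating
## current with Imax(cis->trans) = koff_trans and dwell time
## tau_b = 1/(koff_trans + koff_cis).
##
## Two brute-force oracles live here as well: a finite-difference solver
## of the stationary Smoluchowski equation and a continuous-time
## Markov-chain simulator on the discretized profile.

#' Transport configuration
#'
#' @param D effective diffusion constant, nm^2/ns (literature effective value: 1.0).
#' @param temperature K.
#' @param sigmaRef reference cross-section area converting bulk (3D)
#'   concentration to 1D boundary density, Å^2; defaults to the area of
#'   the 17 Å restraint cylinder used in the simulations, `pi * 17^2`.
#' @param channel optional `c(z_cis, z_trans)` override, Å; if omitted the
#'   profile's own channel interval is used.
#' @return A [TransportConfig-class].
#' @examples
#' transportConfig()
#' @export
transportConfig <- function(D = 1.0, temperature = 300,
                            sigmaRef = pi * 17^2, channel = numeric()) {
  new("TransportConfig", D = D, temperature = temperature,
      sigmaRef = sigmaRef, channel = as.numeric(channel))
}

.channelOf <- function(fes1d, config) {
  if (length(config@channel) == 2L) config@channel else fes1d@channel
}

.D_A2 <- function(config) config@D * .NM2_TO_A2  # nm^2/ns -> A^2/ns

# profile restricted to [a, b], with exact endpoints added by linear
# interpolation
.clipProfile <- function(fes1d, a, b) {
  z <- fes1d@z; f <- fes1d@values
  if (a < min(z) || b > max(z)) stop("channel interval outside the grid")
  inner <- z > a & z < b
  zz <- c(a, z[inner], b)
  ff <- c(stats::approx(z, f, xout = a)$y, f[inner],
          stats::approx(z, f, xout = b)$y)
  list(z = zz, f = ff)
}

# log of integral_a^b exp(beta * F) dz (trapezoid, log-sum-exp stabilized)
.logKramersIntegral <- function(fes1d, config, interval = NULL) {
  if (is.null(interval)) interval <- .channelOf(fes1d, config)
  cp <- .clipProfile(fes1d, interval[1], interval[2])
  beta <- 1 / .kT(config@temperature)
  a <- beta * cp$f + log(.trapWeights(cp$z))
  m <- max(a)
  m + log(sum(exp(a - m)))
}

#' Kramers-integral permeability of a channel
#'
#' `P = D * sigmaRef * gamma / integral exp(F/kT) dz` over the channel
#' interval, with `gamma = 6.0221e-4` molecules/Å^3 per M.  The integral
#' is evaluated in log space, so arbitrarily high barriers never overflow.
#' The linear-regime current is `J = P * (c_cis - c_trans)`.
#'
#' @param fes1d a referenced [FES1D-class].
#' @param config a [TransportConfig-class].
#' @return Permeability, molecules s^-1 M^-1.
#' @examples
#' p <- syntheticProfile(barrierHeight = 3)
#' permeability(p) * 1e-6  # current at 1 uM gradient, molecules/s
#' @export
permeability <- function(fes1d, config = transportConfig()) {
  stopifnot(is(fes1d, "FES1D"), is(config, "TransportConfig"))
  logI <- .logKramersIntegral(fes1d, config)
  logP <- log(.D_A2(config) * config@sigmaRef * .MOLAR_PER_A3) - logI
  exp(logP) * .PER_NS_TO_PER_S
}

#' Finite-difference steady-state Smoluchowski flux (oracle)
#'
#' Solves the stationary 1D Smoluchowski equation
#' `d/dz [ D e^{-F/kT} d/dz ( rho e^{F/kT} ) ] = 0` on the channel
#' interval by a conservative finite-difference scheme with midpoint
#' interface mobilities and a sparse tridiagonal solve.  The Dirichlet
#' boundary data are the bulk linear densities `c * gamma * sigmaRef` per
#' unit z, imposed through continuity of the equilibrium-weighted density
#' `u = rho e^{F/kT}` with the reservoir (in the bulk F = 0, so u equals
#' the bulk density; where the channel ends sit at F = 0 this is a plain
#' density clamp).  This is the brute-force oracle for [permeability()]:
#' for any profile the flux must match `P * (c_cis - c_trans)` closely.
#'
#' @inheritParams permeability
#' @param cCis,cTrans boundary concentrations, M.
#' @param nGrid number of grid points (>= 100).
#' @return Flux, molecules/s (positive cis -> trans).  The relative spread
#'   of the interface fluxes (a discretization diagnostic) is attached as
#'   `attr(x, "fluxSpread")`.
#' @export
smoluchowskiFlux <- function(fes1d, config = transportConfig(),
                             cCis = 1e-6, cTrans = 0, nGrid = 2000L) {
  stopifnot(is(fes1d, "FES1D"), is(config, "TransportConfig"))
  nGrid <- as.integer(nGrid)
  if (nGrid < 100L) stop("nGrid must be >= 100")
  interval <- .channelOf(fes1d, config)
  zz <- seq(interval[1], interval[2], length.out = nGrid)
  ff <- stats::spline(fes1d@z, fes1d@values, xout = zz)$y
  beta <- 1 / .kT(config@temperature)
  h <- zz[2] - zz[1]
  D <- .D_A2(config)
  fm <- stats::spline(fes1d@z, fes1d@values,
                      xout = (zz[-1] + zz[-nGrid]) / 2)$y
  g <- exp(-beta * fm)  # interface mobility
  u1 <- cCis * .MOLAR_PER_A3 * config@sigmaRef
  un <- cTrans * .MOLAR_PER_A3 * config@sigmaRef
  ni <- nGrid - 2L
  main <- -(g[1:ni] + g[2:(ni + 1L)])
  lower <- g[2:ni]
  A <- Matrix::bandSparse(ni, ni, k = c(-1L, 0L, 1L),
                          diagonals = list(lower, main, lower))
  rhs <- numeric(ni)
  rhs[1] <- -g[1] * u1
  rhs[ni] <- -g[ni + 1L] * un
  u <- tryCatch(as.vector(Matrix::solve(A, rhs)),
                error = function(e)
                  stop("linear solve failed (condition estimate ",
                       format(Matrix::condest(A)$est, digits = 3), "): ",
                       conditionMessage(e)))
  uAll <- c(u1, u, un)
  Jint <- -D * g * diff(uAll) / h                 # molecules/ns
  J <- mean(Jint)
  ## the stationary flux must be constant across interfaces up to roundoff
  ## on the natural flux scale of the boundary data
  fluxScale <- D * (abs(u1) + abs(un) + .Machine$double.xmin) / h
  if (diff(range(Jint)) > 1e-8 * fluxScale)
    warning("interface fluxes are not constant: solution not converged")
  J * .PER_NS_TO_PER_S
}

#' Mean first-passage time on a 1D free-energy profile
#'
#' Standard double-quadrature solution of the adjoint (backward) equation
#' for a particle diffusing on `F(z)`: with both boundaries absorbing,
#' `tau(x) = int_a^x psi(y) [C1 - G(y)/D] dy` where `psi = e^{F/kT}`,
#' `G(y) = int_a^y e^{-F/kT}` and `C1 = int_a^b psi G / (D int_a^b psi)`;
#' with one reflecting boundary it reduces to the classical single-barrier
#' form `tau(x) = (1/D) int_x^b psi(y) G(y) dy`.
#'
#' @inheritParams permeability
#' @param zStart starting position, Å (inside the boundaries).
#' @param boundaries `c(a, b)`, Å; defaults to the channel interval.
#' @param reflecting `"none"` (both ends absorbing), `"cis"` or `"trans"`.
#' @param nGrid quadrature grid size.
#' @return Mean first-passage time, ns.
#' @export
mfpt <- function(fes1d, config = transportConfig(), zStart,
                 boundaries = NULL, reflecting = c("none", "cis", "trans"),
                 nGrid = 2001L) {
  stopifnot(is(fes1d, "FES1D"))
  reflecting <- match.arg(reflecting)
  if (is.null(boundaries)) boundaries <- .channelOf(fes1d, config)
  a <- boundaries[1]; b <- boundaries[2]
  if (zStart <= a || zStart >= b)
    stop("start point outside the boundaries")
  zz <- sort(unique(c(seq(a, b, length.out = as.integer(nGrid)), zStart)))
  ff <- stats::spline(fes1d@z, fes1d@values, xout = zz)$y
  beta <- 1 / .kT(config@temperature)
  D <- .D_A2(config)
  psi <- exp(beta * ff)
  G <- pracma::cumtrapz(zz, exp(-beta * ff))[, 1]
  iS <- which(zz == zStart)[1]
  if (reflecting == "none") {
    C1 <- pracma::trapz(zz, psi * G) / (D * pracma::trapz(zz, psi))
    tau <- pracma::cumtrapz(zz, psi * (C1 - G / D))[, 1]
    tau[iS]
  } else if (reflecting == "cis") {
    # reflecting at a, absorbing at b
    intg <- pracma::cumtrapz(zz, psi * G)[, 1]
    (intg[length(zz)] - intg[iS]) / D
  } else {
    # reflecting at b, absorbing at a: mirror
    Gr <- rev(pracma::cumtrapz(rev(-zz), rev(exp(-beta * ff)))[, 1])
    intg <- pracma::cumtrapz(zz, psi * Gr)[, 1]
    intg[iS] / D
  }
}

# splitting probability of reaching b (trans) before a (cis) from x,
# computed in log space; returns c(phiCis, phiTrans) with exact unit sum
.splitting <- function(fes1d, config, zStart, boundaries) {
  beta <- 1 / .kT(config@temperature)
  cpL <- .clipProfile(fes1d, boundaries[1], zStart)
  cpR <- .clipProfile(fes1d, zStart, boundaries[2])
  lse <- function(zz, ff) {
    a <- beta * ff + log(.trapWeights(zz))
    m <- max(a)
    m + log(sum(exp(a - m)))
  }
  l1 <- lse(cpL$z, cpL$f)  # integral cis..start of e^{beta F}
  l2 <- lse(cpR$z, cpR$f)  # integral start..trans
  phiTrans <- 1 / (1 + exp(l2 - l1))
  c(phiCis = 1 - phiTrans, phiTrans = phiTrans)
}

#' Two-state Markov rates from a 1D free-energy profile
#'
#' Defines the occupied state as the deepest well inside the channel (if
#' several wells lie within 0.5 kT of the deepest, the widest is chosen
#' with a warning; a profile without wells uses its deepest interior point
#' and is flagged).  The escape time is the mean first-passage time from
#' the well to the two channel ends; the exit rates split it by the
#' splitting probabilities, `koff_side = phi_side / tau_escape`.  Entry
#' rates are fixed by linear-regime consistency with the Kramers
#' permeability: `kon_cis = P (koff_cis + koff_trans) / koff_trans` and
#' the mirrored expression for `kon_trans`, so the low-concentration slope
#' of [markovCurrent()] equals `P` by construction.  The dwell time is
#' `tau_b = 1 / (koff_trans + koff_cis)`.
#'
#' @inheritParams permeability
#' @return A [RateSet-class]; metadata records the occupied-state position
#'   and a `flat` flag for well-less profiles.
#' @examples
#' p <- syntheticProfile(barrierHeight = 3,
#'                       wells = data.frame(depth = 2, z = -8))
#' ratesFromFES(p)
#' @export
ratesFromFES <- function(fes1d, config = transportConfig()) {
  stopifnot(is(fes1d, "FES1D"), is(config, "TransportConfig"))
  interval <- .channelOf(fes1d, config)
  kT <- .kT(config@temperature)
  wells <- fes1d@features[fes1d@features$type == "well", , drop = FALSE]
  wells <- wells[wells$z > interval[1] & wells$z < interval[2], ,
                 drop = FALSE]
  flat <- nrow(wells) == 0L
  if (flat) {
    inside <- fes1d@z > interval[1] & fes1d@z < interval[2]
    zi <- fes1d@z[inside]
    zw <- zi[which.min(fes1d@values[inside])]
  } else {
    deepest <- min(wells$F)
    near <- wells[wells$F <= deepest + 0.5 * kT, , drop = FALSE]
    if (nrow(near) > 1L) {
      widths <- vapply(seq_len(nrow(near)), function(k)
        .wellWidth(fes1d, near$z[k], near$F[k] + 0.5 * kT), numeric(1))
      warning(sprintf(
        "%d wells within 0.5 kT of the deepest; choosing the widest",
        nrow(near)))
      zw <- near$z[which.max(widths)]
    } else zw <- near$z[1]
  }
  ## snap to the profile grid so the splitting integrals partition exactly
  zw <- fes1d@z[which.min(abs(fes1d@z - zw))]
  tauEsc <- mfpt(fes1d, config, zStart = zw, boundaries = interval)  # ns
  tauS <- tauEsc / .PER_NS_TO_PER_S
  phi <- .splitting(fes1d, config, zw, interval)
  koffTrans <- phi[["phiTrans"]] / tauS
  koffCis <- phi[["phiCis"]] / tauS
  P <- permeability(fes1d, config)
  ksum <- koffCis + koffTrans
  new("RateSet",
      konCis = P * ksum / koffTrans, konTrans = P * ksum / koffCis,
      koffCis = koffCis, koffTrans = koffTrans,
      tauB = 1 / ksum, phiCis = phi[["phiCis"]],
      phiTrans = phi[["phiTrans"]],
      metadata = list(zWell = zw, flat = flat, tauEscapeNs = tauEsc,
                      P = P, konConvention = "linear-regime consistency"))
}

# z extent of the region around zw where F stays below `level`
.wellWidth <- function(fes1d, zw, level) {
  below <- fes1d@values <= level
  i <- which.min(abs(fes1d@z - zw))
  lo <- i; while (lo > 1L && below[lo - 1L]) lo <- lo - 1L
  hi <- i; while (hi < length(below) && below[hi + 1L]) hi <- hi + 1L
  fes1d@z[hi] - fes1d@z[lo]
}

#' Steady-state current of the single-occupancy Markov channel
#'
#' `I = (kon_cis c_cis koff_trans - kon_trans c_trans koff_cis) /
#'      (kon_cis c_cis + kon_trans c_trans + koff_cis + koff_trans)`.
#' With an empty trans side the current rises linearly with slope `P` and
#' saturates at `Imax = koff_trans` (one molecule at a time in the
#' channel).
#'
#' @param rates a [RateSet-class].
#' @param cCis,cTrans concentrations, M (vectors recycled).
#' @return Current, molecules/s.
#' @export
markovCurrent <- function(rates, cCis, cTrans = 0) {
  stopifnot(is(rates, "RateSet"))
  n <- max(length(cCis), length(cTrans))
  cCis <- rep_len(cCis, n); cTrans <- rep_len(cTrans, n)
  if (any(cCis < 0 | cTrans < 0)) stop("concentrations must be >= 0")
  num <- rates@konCis * cCis * rates@koffTrans -
    rates@konTrans * cTrans * rates@koffCis
  den <- rates@konCis * cCis + rates@konTrans * cTrans +
    rates@koffCis + rates@koffTrans
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}

#' Predicted current versus concentration
#'
#' Builds the full saturation curve of the two-state Markov channel fed by
#' the Kramers permeability: current at each cis-side concentration, the
#' linear-regime permeability `P`, the saturated current
#' `Imax = koff_trans`, the half-saturation concentration
#' `K_half = (koff_cis + koff_trans)/kon_cis` and `c_sat90 = 9 K_half`.
#'
#' @inheritParams permeability
#' @param cGrid ascending concentration grid, M; default 60 log-spaced
#'   points between 0.1 µM and 0.1 M.
#' @param cTrans trans-side concentration, M (default 0).
#' @return A [CurrentCurve-class].
#' @examples
#' p <- syntheticProfile(barrierHeight = 3)
#' cc <- currentCurve(p)
#' cc
#' @export
currentCurve <- function(fes1d, config = transportConfig(),
                         cGrid = 10^seq(-7, -1, length.out = 60),
                         cTrans = 0) {
  if (any(diff(cGrid) <= 0) || any(cGrid <= 0))
    stop("cGrid must be positive and ascending")
  rates <- ratesFromFES(fes1d, config)
  I <- markovCurrent(rates, cGrid, cTrans)
  ksum <- rates@koffCis + rates@koffTrans
  Khalf <- ksum / rates@konCis
  new("CurrentCurve", concentration = cGrid, current = I,
      P = rates@konCis * rates@koffTrans / ksum,
      Imax = rates@koffTrans, Khalf = Khalf, cSat90 = 9 * Khalf,
      rates = rates,
      metadata = list(cTrans = cTrans, D = config@D,
                      sigmaRef = config@sigmaRef,
                      temperature = config@temperature))
}

#' Continuous-time Markov-chain escape simulation (oracle)
#'
#' Discretizes the channel stretch of the profile into a birth-death chain
#' with detailed-balance rates `k(i -> i+-1) = (D/h^2)
#' exp(-(F(i+-1) - F(i)) / 2kT)`, absorbing beyond both ends, and
#' simulates `nTraj` escape trajectories from the given start.  Serves as
#' the brute-force oracle for the MFPT quadrature and the splitting
#' probabilities in [ratesFromFES()].  Uses R's RNG: call `set.seed()`
#' for reproducibility.
#'
#' @inheritParams permeability
#' @param zStart start position, Å; default the deepest channel point.
#' @param nTraj number of trajectories.
#' @param nGrid number of lattice points across the channel.
#' @return list with `meanTime` (ns), `phiCis`, `phiTrans`, and the raw
#'   per-trajectory `times` (ns) and `side` (0 cis, 1 trans).
#' @export
simulateEscape <- function(fes1d, config = transportConfig(),
                           zStart = NULL, nTraj = 1e5, nGrid = 101L) {
  stopifnot(is(fes1d, "FES1D"))
  interval <- .channelOf(fes1d, config)
  zz <- seq(interval[1], interval[2], length.out = as.integer(nGrid))
  ff <- stats::spline(fes1d@z, fes1d@values, xout = zz)$y
  if (is.null(zStart)) zStart <- zz[which.min(ff)]
  if (zStart <= interval[1] || zStart >= interval[2])
    stop("start point outside the channel")
  h <- zz[2] - zz[1]
  beta <- 1 / .kT(config@temperature)
  D <- .D_A2(config)
  n <- length(zz)
  ## interior lattice states 2..n-1; jumping onto 1 or n absorbs
  idx <- 2:(n - 1L)
  kLeft <- (D / h^2) * exp(-beta * (ff[idx - 1L] - ff[idx]) / 2)
  kRight <- (D / h^2) * exp(-beta * (ff[idx + 1L] - ff[idx]) / 2)
  start <- which.min(abs(zz[idx] - zStart)) - 1L  # 0-based for C++
  sim <- .ctmc_escape(kLeft, kRight, start, as.integer(nTraj))
  list(meanTime = mean(sim$time), phiCis = mean(sim$side == 0L),
       phiTrans = mean(sim$side == 1L), times = sim$time,
       side = sim$side, zStart = zz[idx][start + 1L], h = h)
}
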