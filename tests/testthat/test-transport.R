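cfgDefault <- transportConfig()

test_that("unit conversion constants are single-sourced and correct", {
  k <- permConstants()
  expect_equal(k$kB * 300, 0.59616)            # kT at 300 K, kcal/mol
  expect_equal(k$eAngToDebye, 4.8032)
  ## Avogadro's number / 1e27 A^3 per litre
  expect_equal(k$molarPerA3, 6.02214076e23 / 1e27, tolerance = 1e-4)
  expect_equal(k$perNsToPerS, 1e9)
  expect_equal(k$nm2ToA2, 100)
  expect_equal(transportConfig()@sigmaRef, pi * 17^2)
  expect_equal(transportConfig()@D, 1.0)
})

test_that("flat channels reproduce the free-diffusion closed form", {
  flat <- syntheticProfile(barrierHeight = 0, zRange = c(-40, 40),
                           bulkWidth = 10, nZ = 801)
  cfg <- transportConfig(D = 1, channel = c(-20, 20))
  P <- permeability(flat, cfg)
  closed <- 100 * pi * 17^2 * 6.0221e-4 / 40 * 1e9  # D*sigma*gamma/L
  expect_equal(P, closed, tolerance = 1e-6)
  expect_equal(P * 1e-6, 1366.9, tolerance = 1e-3)  # current at 1 uM, /s
  ## finite-difference solver agrees to much better than 0.1%
  J <- smoluchowskiFlux(flat, cfg, cCis = 1e-6, cTrans = 0, nGrid = 2000)
  expect_equal(as.numeric(J), P * 1e-6, tolerance = 1e-3)
})

test_that("a dominant square barrier suppresses P by (w/L) e^{-bF}", {
  z <- seq(-30, 30, length.out = 1201)
  w <- 5; dF <- 6
  f <- ifelse(abs(z) <= w / 2, dF, 0)
  sq <- porinflux:::.makeFES1D(z, f, 300, channel = c(-20, 20))
  flat <- porinflux:::.makeFES1D(z, 0 * z, 300, channel = c(-20, 20))
  cfg <- transportConfig(channel = c(-20, 20))
  ratio <- permeability(sq, cfg) / permeability(flat, cfg)
  beta <- 1 / (0.0019872 * 300)
  expect_equal(ratio, (w / 40 * exp(beta * dF))^-1, tolerance = 0.02)
})

test_that("Kramers permeability matches the Smoluchowski oracle", {
  for (s in 1:4) {
    p <- randomSmoothProfile(barrier = c(1, 3, 5, 7)[s], seed = s)
    P <- permeability(p, cfgDefault)
    J <- smoluchowskiFlux(p, cfgDefault, cCis = 1e-6, cTrans = 0)
    expect_lt(abs(P * 1e-6 - J) / J, 0.01)
  }
})

test_that("the Smoluchowski solver respects equilibrium and antisymmetry", {
  p <- randomSmoothProfile(barrier = 3, seed = 11)
  scale <- abs(smoluchowskiFlux(p, cfgDefault, 1e-3, 0))
  expect_lt(abs(smoluchowskiFlux(p, cfgDefault, 1e-3, 1e-3)) / scale,
            1e-10)
  ## symmetric profile: reversing the gradient reverses the flux
  sym <- syntheticProfile(barrierHeight = 3)
  expect_equal(smoluchowskiFlux(sym, cfgDefault, 1e-4, 0),
               -smoluchowskiFlux(sym, cfgDefault, 0, 1e-4),
               tolerance = 1e-9)
  expect_error(smoluchowskiFlux(p, cfgDefault, nGrid = 50), "nGrid")
})

test_that("MFPT obeys its scaling laws and boundary limits", {
  p <- syntheticProfile(barrierHeight = 3,
                        wells = data.frame(depth = 2, z = 0))
  t1 <- mfpt(p, transportConfig(D = 1), zStart = 0)
  t2 <- mfpt(p, transportConfig(D = 2), zStart = 0)
  expect_equal(t1 / t2, 2, tolerance = 1e-12)  # exactly proportional to 1/D
  ## flat profile, both ends absorbing, start midpoint: L^2 / (8 D) +
  ## discrete master-equation oracle
  flat <- syntheticProfile(barrierHeight = 0, zRange = c(-40, 40),
                           bulkWidth = 10, nZ = 801)
  cfgL <- transportConfig(D = 1, channel = c(-20, 20))
  tFlat <- mfpt(flat, cfgL, zStart = 0)
  expect_equal(tFlat, 40^2 / (8 * 100), tolerance = 1e-4)
  ## master-equation linear solve on the discrete chain (independent route)
  n <- 401; h <- 40 / (n - 1)
  k <- 100 / h^2
  A <- diag(-2 * k, n - 2); A[cbind(1:(n - 3), 2:(n - 2))] <- k
  A[cbind(2:(n - 2), 1:(n - 3))] <- k
  tauChain <- solve(A, rep(-1, n - 2))
  expect_equal(tFlat, tauChain[(n - 1) / 2], tolerance = 0.01)
  ## a practically insurmountable wall at one boundary reduces to the
  ## reflecting form (the wall must sit at the boundary: a wall strictly
  ## inside the domain leaves an O(1) sojourn contribution behind it)
  z <- seq(-20, 20, length.out = 801)
  wallF <- 12 * exp(-(z + 20)^2 / 2)
  wall <- porinflux:::.makeFES1D(z, wallF, 300, channel = c(-20, 20),
                                 bulkWindows = rbind(c(12, 20),
                                                     c(12, 20)))
  cfgW <- transportConfig(channel = c(-20, 20))
  tWall <- mfpt(wall, cfgW, zStart = 0)
  tRefl <- mfpt(wall, cfgW, zStart = 0, reflecting = "cis")
  expect_equal(tWall, tRefl, tolerance = 1e-3)
  expect_error(mfpt(p, cfgDefault, zStart = 99), "outside")
})

test_that("rates from a symmetric profile split escape evenly", {
  sym <- syntheticProfile(barrierHeight = 2, barrierWidth = 4,
                          wells = data.frame(depth = 2.5, z = 0,
                                             width = 2.5))
  r <- ratesFromFES(sym, cfgDefault)
  expect_equal(r@phiCis, 0.5, tolerance = 1e-9)
  expect_equal(r@phiTrans, 0.5, tolerance = 1e-9)
  expect_equal(r@koffCis, r@koffTrans, tolerance = 1e-9)
  expect_equal(r@tauB * (r@koffCis + r@koffTrans), 1, tolerance = 1e-12)
})

test_that("the dwell-time identity is plain rate arithmetic", {
  r <- new("RateSet", konCis = 1e9, konTrans = 1e9, koffCis = 6e6,
           koffTrans = 4e6, tauB = 1e-7, phiCis = 0.6, phiTrans = 0.4,
           metadata = list())
  expect_equal(dwellTime(r), 1 / (4e6 + 6e6))
  ## the validity method rejects an inconsistent tauB
  expect_error(new("RateSet", konCis = 1, konTrans = 1, koffCis = 6e6,
                   koffTrans = 4e6, tauB = 2e-7, phiCis = 0.6,
                   phiTrans = 0.4, metadata = list()), "tauB")
})

test_that("rate construction is validated by the CTMC oracle", {
  ## central well between two moderate shoulders: balanced splitting,
  ## cheap trajectories, small discretization bias
  p <- syntheticProfile(barrierHeight = 2, barrierWidth = 4,
                        wells = data.frame(depth = 2.5, z = 0,
                                           width = 2.5))
  r <- ratesFromFES(p, cfgDefault)
  set.seed(424)
  sim <- simulateEscape(p, cfgDefault, zStart = r@metadata$zWell,
                        nTraj = 3e4, nGrid = 101)
  expect_lt(abs(sim$meanTime - r@metadata$tauEscapeNs) /
              r@metadata$tauEscapeNs, 0.02)
  expect_lt(abs(sim$phiTrans - r@phiTrans), 0.02)
})

test_that("the Markov current has the correct limits and slope", {
  p <- syntheticProfile(barrierHeight = 3,
                        wells = data.frame(depth = 2, z = -6))
  r <- ratesFromFES(p, cfgDefault)
  P <- permeability(p, cfgDefault)
  ## the c -> 0 slope kon_cis koff_trans / (koff_cis + koff_trans) equals
  ## the Kramers permeability by construction
  slope0 <- r@konCis * r@koffTrans / (r@koffCis + r@koffTrans)
  expect_equal(slope0, P, tolerance = 1e-12)
  expect_equal(markovCurrent(r, 1e-12) / 1e-12, P, tolerance = 1e-9)
  ## saturation at koff_trans
  expect_equal(markovCurrent(r, 1e6), r@koffTrans, tolerance = 1e-6)
  ## equilibrium (equal concentrations) carries no current on any profile
  expect_equal(markovCurrent(r, 1e-3, 1e-3) / r@koffTrans, 0,
               tolerance = 1e-12)
  expect_equal(markovCurrent(r, 0, 0), 0)
  expect_error(markovCurrent(r, -1), ">= 0")
})

test_that("current curves saturate with the stated constants", {
  p <- syntheticProfile(barrierHeight = 3,
                        wells = data.frame(depth = 2.5, z = -5))
  cc <- currentCurve(p, cfgDefault)
  tab <- currentTable(cc)
  expect_true(all(diff(tab$current) > 0))          # monotone, trans empty
  expect_true(all(tab$current <= cc@Imax))
  expect_identical(cc@Imax, cc@rates@koffTrans)
  expect_equal(cc@cSat90, 9 * cc@Khalf)
  iHalf <- markovCurrent(cc@rates, cc@Khalf)
  expect_equal(iHalf / cc@Imax, 0.5, tolerance = 1e-9)
  ## a deeper well saturates at a lower concentration, same barrier
  shallow <- syntheticProfile(barrierHeight = 3,
                              wells = data.frame(depth = 1, z = -5))
  ccS <- currentCurve(shallow, cfgDefault)
  expect_lt(cc@Khalf, ccS@Khalf)
  expect_error(currentCurve(p, cfgDefault, cGrid = c(2, 1)), "ascending")
})

test_that("gauge shifts before referencing change nothing downstream", {
  g <- simulateFES(barrierHeight = 4, cv1Confinement = 0.7,
                   roughnessAmplitude = 0.2, seed = 31)
  f1 <- marginalizeFES(g$fes)
  shifted <- g$fes
  shifted@values <- shifted@values + 3.14
  f2 <- marginalizeFES(shifted)
  expect_equal(permeability(f1, cfgDefault), permeability(f2, cfgDefault),
               tolerance = 1e-12)
  r1 <- ratesFromFES(f1, cfgDefault)
  r2 <- ratesFromFES(f2, cfgDefault)
  expect_equal(r1@koffTrans, r2@koffTrans, tolerance = 1e-12)
})

test_that("permeability is Arrhenius in the barrier height", {
  cfg <- transportConfig()
  z <- seq(-30, 30, length.out = 1201)
  w <- 6
  heights <- 3:8
  lp <- vapply(heights, function(dF) {
    f <- ifelse(abs(z) <= w / 2, dF, 0)
    p <- porinflux:::.makeFES1D(z, f, 300)
    log(permeability(p, cfg))
  }, numeric(1))
  fit <- lm(lp ~ heights)
  expect_equal(unname(coef(fit)[2]), -1 / 0.59616, tolerance = 0.01)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # near-perfect fit
  expect_gt(r2, 0.999)
})
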