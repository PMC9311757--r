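test_that("projection area matches analytic and Monte-Carlo references", {
  ## single disk
  expect_equal(projectionArea(matrix(0, 1, 3), 2, c(0, 1, 1)),
               4 * pi, tolerance = 2e-3)
  ## two coincident disks along the projection axis
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(projectionArea(two, 1.7, c(1, 0, 0)),
               pi * 1.7^2, tolerance = 2e-3)
  ## two disjoint disks: analytic and MC point-in-union oracle
  aImpl <- projectionArea(two, 1.7, c(0, 0, 1))
  expect_equal(aImpl, 2 * pi * 1.7^2, tolerance = 2e-3)
  aMC <- mcDiskUnionArea(c(0, 10), c(0, 0), c(1.7, 1.7),
                         nPoints = 1e6, seed = 2)
  expect_equal(aImpl, aMC, tolerance = 1e-2)
  ## overlapping disks against the MC oracle
  cl <- randomCluster(6, seed = 4, spread = 2.5)
  d <- c(0.3, -0.5, 0.81)
  b <- porinflux:::.planeBasis(d / sqrt(sum(d^2)))
  aImpl <- projectionArea(cl$coords, cl$radii, d)
  aMC <- mcDiskUnionArea(as.vector(cl$coords %*% b$e1),
                         as.vector(cl$coords %*% b$e2), cl$radii,
                         nPoints = 2e6, seed = 3)
  expect_equal(aImpl, aMC, tolerance = 5e-3)
  ## sign invariance
  expect_equal(projectionArea(cl$coords, cl$radii, d),
               projectionArea(cl$coords, cl$radii, -d))
  expect_error(projectionArea(two[0, , drop = FALSE], 1.7, c(0, 0, 1)),
               "empty")
  expect_error(projectionArea(two, 1.7, c(0, 0, 0)), "non-zero")
})

test_that("minimal projection area finds the analytic optimum", {
  ## a long rod: MPA is a single disk, axis along the rod
  rod <- cbind(0, 0, seq(0, 18, by = 1.5))
  out <- minimalProjectionArea(rod, 1.7)
  expect_equal(out$mpa, pi * 1.7^2, tolerance = 0.01)
  expect_gt(abs(out$direction[3]), 0.999)
  ## single atom
  one <- minimalProjectionArea(matrix(0, 1, 3), 3.4)
  expect_equal(one$mpa, pi * 3.4^2, tolerance = 0.01)
  expect_equal(rminFromArea(one$mpa), 3.4, tolerance = 0.005)
  ## lower bound and pre-condition
  expect_gte(out$mpa, pi * 1.7^2 * (1 - 2e-3))
  expect_error(minimalProjectionArea(rod, 1.7, nDirs = 8), "nDirs")
  expect_error(minimalProjectionArea(rod, 0), "degenerate")
})

test_that("direction search matches a dense brute-force grid", {
  for (s in 1:3) {
    cl <- randomCluster(5, seed = s)
    fast <- minimalProjectionArea(cl$coords, cl$radii)$mpa
    brute <- bruteForceMPA(cl$coords, cl$radii)
    expect_lt(abs(fast - brute) / brute, 0.01)
    expect_lte(fast, brute * (1 + 2e-3))  # refinement never loses
  }
})

test_that("rmin is the equal-area circle radius", {
  expect_equal(rminFromArea(pi), 1.0)
  expect_equal(rminFromArea(0), 0.0)
  expect_equal(rminFromArea(pi * 3.4^2), 3.4)
  expect_error(rminFromArea(-1), "negative")
})

test_that("dipole moment follows the point-charge definition", {
  expect_equal(dipoleMoment(rbind(c(1, 0, 0), c(-1, 0, 0)), c(0.5, -0.5)),
               c(4.8032, 0, 0))
  ## neutral molecules: origin independent
  cl <- randomCluster(6, seed = 9)
  q <- rnorm(6); q <- q - mean(q)
  expect_equal(dipoleMoment(cl$coords, q, origin = "com"),
               dipoleMoment(cl$coords, q, origin = "zero"),
               tolerance = 1e-12)
  ## charged molecules: origins differ by exactly q_net * dr0 * 4.8032
  q1 <- q; q1[1] <- q1[1] - 1  # net charge -1 e
  m <- runif(6, 1, 16)
  muCom <- dipoleMoment(cl$coords, q1, masses = m, origin = "com")
  muGeo <- dipoleMoment(cl$coords, q1, origin = "geometric")
  r0com <- colSums(cl$coords * m) / sum(m)
  r0geo <- colMeans(cl$coords)
  expect_equal(muCom - muGeo, -(-1) * (r0com - r0geo) * 4.8032,
               tolerance = 1e-9)
  expect_error(dipoleMoment(cl$coords, q[1:3]), "lengths differ")
})

test_that("transversal dipole is the out-of-axis component", {
  expect_equal(transversalDipole(c(4.8, 0, 0), c(1, 0, 0)), 0)
  expect_equal(transversalDipole(c(0, 4.8, 0), c(1, 0, 0)), 4.8)
  expect_equal(transversalDipole(c(3, 4, 0), c(1, 0, 0)), 4)
  expect_error(transversalDipole(c(1, 0, 0), c(1, 0.1, 0)), "unit")
})

test_that("descriptors are invariant under rigid rotation", {
  ens <- simulateConformers("flexible_chain", nAtoms = 7,
                            charges = c(0.5, 0, 0, -1, 0, 0, 0.5),
                            netCharge = 0, flexibility = 0.25,
                            nFrames = 1, seed = 21)
  m <- frameCoords(ens, 1)
  R <- randomRotation(seed = 8)
  a <- minimalProjectionArea(m, vdwRadii(ens))
  b <- minimalProjectionArea(m %*% t(R), vdwRadii(ens))
  expect_equal(a$mpa, b$mpa, tolerance = 0.01)
  muA <- dipoleMoment(m, atomCharges(ens), atomMasses(ens))
  muB <- dipoleMoment(m %*% t(R), atomCharges(ens), atomMasses(ens))
  ## |mu| exactly invariant, mu rotates equivariantly
  expect_equal(sqrt(sum(muA^2)), sqrt(sum(muB^2)), tolerance = 1e-12)
  expect_equal(as.vector(R %*% muA), muB, tolerance = 1e-9)
  dxyA <- transversalDipole(muA, a$direction)
  dxyB <- transversalDipole(muB, b$direction)
  expect_equal(dxyA, dxyB, tolerance = 0.05 * sqrt(sum(muA^2)))
})

test_that("zero-flexibility ensembles have zero descriptor variance", {
  ens <- simulateConformers("rod", nAtoms = 6, flexibility = 0,
                            charges = c(0.5, 0, 0, 0, 0, -0.5),
                            nFrames = 4, seed = 2)
  rec <- computeDescriptors(ens, nDirs = 128)
  expect_equal(sd(rec$mpa), 0)
  expect_equal(sd(rec$dipoleTotal), 0)
  expect_equal(sd(rec$dipoleXY), 0)
})

test_that("elongated rods align the MPA axis and kill the axial dipole", {
  ## axis-aligned dipole on a long rod: transversal component vanishes
  n <- 16
  ens <- simulateConformers("rod", nAtoms = n,
                            charges = c(0.5, rep(0, n - 2), -0.5),
                            netCharge = 0, nFrames = 1)
  rec <- computeDescriptors(ens, nDirs = 256)
  expect_gt(abs(rec$nz), 0.999)
  expect_lt(rec$dipoleXY / rec$dipoleTotal, 0.05)
  expect_true(all(rec$dipoleXY <= rec$dipoleTotal + 1e-12))
})

test_that("descriptor summaries report means, modes and unit mass", {
  s <- summarizeDescriptor(rep(4.2, 50), binWidth = 0.1)
  expect_equal(s@mean, 4.2)
  expect_length(s@modes, 1)
  expect_lt(abs(s@modes - 4.2), 0.1)  # within one bin of the constant
  ## two delta-like clusters: both modes reported
  set.seed(31)
  x <- c(rnorm(400, 4.0, 0.02), rnorm(300, 4.7, 0.02))
  s2 <- summarizeDescriptor(x, binWidth = 0.1)
  expect_length(s2@modes, 2)
  expect_lt(abs(s2@modes[1] - 4.0), 0.08)
  expect_lt(abs(s2@modes[2] - 4.7), 0.08)
  ## normalization
  s3 <- summarizeDescriptor(runif(1000, 0, 3), binWidth = 0.25)
  expect_equal(sum(s3@density * diff(s3@breaks)), 1, tolerance = 1e-9)
  expect_error(summarizeDescriptor(numeric(0)), "empty")
})

test_that("distribution overlap behaves as an overlap coefficient", {
  a <- summarizeDescriptor(runif(5000, 0, 1), binWidth = 0.05)
  expect_equal(distributionOverlap(a, a), 1, tolerance = 1e-6)
  b <- summarizeDescriptor(runif(5000, 5, 6), binWidth = 0.05)
  expect_equal(distributionOverlap(a, b), 0)
  ## two unit boxes overlapping by half (ideal densities, built directly)
  boxA <- new("DescriptorSummary", mean = 0.5, modes = 0.5,
              breaks = c(0, 1), density = 1, binWidth = 1,
              metadata = list())
  boxB <- new("DescriptorSummary", mean = 1.0, modes = 1.0,
              breaks = c(0.5, 1.5), density = 1, binWidth = 1,
              metadata = list())
  expect_equal(distributionOverlap(boxA, boxB), 0.5, tolerance = 1e-6)
})

test_that("pore profile recovers the accessible radius of a ring", {
  nr <- 32
  ang <- 2 * pi * (seq_len(nr) - 1) / nr
  ring <- cbind(10 * cos(ang), 10 * sin(ang), 0)
  pp <- poreProfile(ring, 1.7, probeRadius = 1.4, zSlices = 0,
                    slabHalfWidth = 1)
  expect_equal(pp$rmin, 10 - 1.7 - 1.4, tolerance = 0.02)
  ## MC rasterization oracle for the same free area
  set.seed(6)
  xs <- runif(4e5, -10, 10); ys <- runif(4e5, -10, 10)
  inBox <- xs^2 + ys^2 <= 100
  blocked <- rep(FALSE, 4e5)
  for (i in seq_len(nr))
    blocked <- blocked | ((xs - ring[i, 1])^2 + (ys - ring[i, 2])^2 <= 3.1^2)
  aMC <- mean(inBox & !blocked) * 400
  expect_equal(pp$area, aMC, tolerance = 0.01)
  ## empty slab is flagged wide open
  pp2 <- poreProfile(ring, 1.7, zSlices = c(-3, 0, 3),
                     slabHalfWidth = 0.1, boxRadius = 12)
  expect_equal(pp2$flagged, c(TRUE, FALSE, TRUE))
  expect_equal(pp2$area[1], pi * 144, tolerance = 1e-9)
  ## probe monotonicity
  pp0 <- poreProfile(ring, 1.7, probeRadius = 0, zSlices = 0,
                     slabHalfWidth = 1)
  expect_gt(pp0$rmin, pp$rmin)
  expect_error(poreProfile(ring, 1.7, probeRadius = -1), "probeRadius")
})
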