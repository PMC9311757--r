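test_that("separable surfaces marginalize to the exact analytic profile", {
  g <- simulateFES(barrierHeight = 5, separable = TRUE,
                   cv1Confinement = 1.2, roughnessAmplitude = 0.2,
                   seed = 17)
  f1 <- marginalizeFES(g$fes)
  expect_lt(max(abs(fesValues(f1) - g$truth$marginal)), 0.05)
  ## flat surface marginalizes to identically zero
  flat <- simulateFES(barrierHeight = 0, seed = 1)
  expect_lt(max(abs(fesValues(marginalizeFES(flat$fes)))), 1e-12)
  ## bulk referencing: declared windows average exactly zero
  idx <- porinflux:::.bulkIndex(zGrid(f1), f1@bulkWindows)
  expect_lt(abs(mean(fesValues(f1)[idx])), 1e-9)
})

test_that("marginalization is gauge invariant and bounded by the minimum", {
  g <- simulateFES(separable = FALSE, barrierHeight = 4,
                   roughnessAmplitude = 0.5, seed = 23)
  f1 <- marginalizeFES(g$fes)
  shifted <- g$fes
  shifted@values <- shifted@values + 7.31
  f2 <- marginalizeFES(shifted)
  expect_equal(fesValues(f1), fesValues(f2), tolerance = 1e-12)

  ## column-wise sandwich of the unreferenced Boltzmann average:
  ## min - kT log W <= F1 <= max - kT log W
  kT <- porinflux:::.kT(300)
  w <- porinflux:::.trapWeights(cv1Grid(g$fes))
  W <- sum(w)
  v <- fesValues(g$fes)
  for (j in seq_along(zGrid(g$fes))) {
    f1j <- porinflux:::.boltzmannAverage(v[, j], w, kT)
    expect_lte(f1j, max(v[, j]) - kT * log(W) + 1e-9)
    expect_gte(f1j, min(v[, j]) - kT * log(W) - 1e-9)
  }
})

test_that("the low-temperature marginal approaches the CV1 minimum", {
  cv1 <- seq(-1, 1, length.out = 21)
  z <- seq(-25, 25, length.out = 101)
  win <- porinflux:::.bulkWindow(z, c(-25, 25), 10)
  mk <- function(temp) {
    ## non-separable: barrier height grows away from cv1 = 0
    vals <- outer(1 + 2 * cv1^2, win * 3 * exp(-z^2 / 18))
    new("FES2D", cv1 = cv1, z = z, values = vals,
        mask = matrix(FALSE, 21, 101), temperature = temp)
  }
  colMin <- apply(fesValues(mk(300)), 2, min)
  refMin <- colMin - mean(colMin[z <= -15 | z >= 15])
  coldErr <- max(abs(fesValues(marginalizeFES(mk(3))) - refMin))
  warmErr <- max(abs(fesValues(marginalizeFES(mk(300))) - refMin))
  expect_lt(coldErr, 0.05)
  expect_gt(warmErr, coldErr)  # the 300 K marginal is a genuine average
})

test_that("CV1 grid refinement barely changes a smooth marginal", {
  a <- simulateFES(separable = FALSE, barrierHeight = 4,
                   roughnessAmplitude = 0.3, dims = c(41L, 121L),
                   seed = 5)
  b <- simulateFES(separable = FALSE, barrierHeight = 4,
                   roughnessAmplitude = 0.3, dims = c(81L, 121L),
                   seed = 5)
  expect_lt(max(abs(fesValues(marginalizeFES(a$fes)) -
                      fesValues(marginalizeFES(b$fes)))), 0.02)
})

test_that("masked cells are renormalized and flagged", {
  g <- simulateFES(barrierHeight = 3, cv1Confinement = 0.5, seed = 9,
                   dims = c(21L, 61L))
  fes <- g$fes
  ## masking a few cells in one column barely moves a smooth marginal
  fes@mask[2:4, 30] <- TRUE
  fes@values[2:4, 30] <- NA
  f1 <- marginalizeFES(fes)
  f0 <- marginalizeFES(g$fes)
  expect_lt(abs(fesValues(f1)[30] - fesValues(f0)[30]), 0.2)
  ## a mostly-masked column is flagged; a fully masked one is an error
  fes@mask[1:15, 40] <- TRUE
  fes@values[1:15, 40] <- NA
  f2 <- marginalizeFES(fes)
  expect_true(40 %in% f2@metadata$flaggedColumns)
  fes@mask[, 50] <- TRUE
  fes@values[, 50] <- NA
  expect_error(marginalizeFES(fes), "fully masked")
})

test_that("1D features report wells and the channel barrier", {
  ## single Gaussian barrier: one barrier feature at (0, 5)
  p <- syntheticProfile(barrierHeight = 5)
  ft <- fesFeatures(p)
  expect_equal(ft$type, "barrier")
  expect_equal(ft$z, 0, tolerance = 1e-9)
  expect_equal(ft$F, 5, tolerance = 1e-3)
  ## double-well profile: two wells and one barrier between them
  p2 <- syntheticProfile(barrierHeight = 4,
                         wells = data.frame(depth = c(2, 1.5),
                                            z = c(-8, 8)))
  ft2 <- fesFeatures(p2)
  expect_equal(sum(ft2$type == "well"), 2)
  expect_equal(sum(ft2$type == "barrier"), 1)
  ## sub-tolerance wiggles are not reported
  p3 <- syntheticProfile(barrierHeight = 4, roughnessAmplitude = 0.05,
                         seed = 3)
  ft3 <- findFeatures(p3, levelTol = 0.3)
  expect_equal(sum(ft3$type == "well"), 0)
})

test_that("2D feature detection finds wells and saddles", {
  cv1 <- seq(-1, 1, length.out = 41)
  z <- seq(-10, 10, length.out = 41)
  ## two basins separated in cv1 create a saddle between them at cv1 = 0
  vals <- outer(4 * (cv1^2 - 0.36)^2, rep(1, 41)) +
    outer(rep(1, 41), 0.05 * z^2)
  fes <- new("FES2D", cv1 = cv1, z = z, values = vals,
             mask = matrix(FALSE, 41, 41), temperature = 300)
  ft <- findFeatures(fes, levelTol = 0.05)
  expect_gt(sum(ft$type == "well"), 0)
  expect_gt(sum(ft$type == "saddle"), 0)
})

test_that("asymmetric bulk plateaus trigger a warning, not an error", {
  z <- seq(-25, 25, length.out = 101)
  f <- 2 * exp(-z^2 / 8) + 0.8 * plogis(z)  # offset between the two bulks
  expect_warning(porinflux:::.makeFES1D(z, f, 300), "plateaus differ")
})
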