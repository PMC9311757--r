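# Independent brute-force oracles used across the suite.

# Monte-Carlo point-in-union area of disks (independent of the chord-slicing
# kernel): uniform points in the bounding box, fraction covered.
mcDiskUnionArea <- function(px, py, r, nPoints = 1e6, seed = 1) {
  set.seed(seed)
  xmin <- min(px - r); xmax <- max(px + r)
  ymin <- min(py - r); ymax <- max(py + r)
  xs <- runif(nPoints, xmin, xmax)
  ys <- runif(nPoints, ymin, ymax)
  inside <- rep(FALSE, nPoints)
  for (i in seq_along(px))
    inside <- inside | ((xs - px[i])^2 + (ys - py[i])^2 <= r[i]^2)
  mean(inside) * (xmax - xmin) * (ymax - ymin)
}

# Dense-grid direction search: regular grid in (cos(theta), phi) over the
# hemisphere, no refinement.
bruteForceMPA <- function(coords, radii, nTheta = 100, nPhi = 100,
                          nSlices = 512) {
  ## upper hemisphere (antipodes identified): uniform in cos(theta), full
  ## azimuth range
  ct <- seq(0, 1, length.out = nTheta)
  ph <- seq(0, 2 * pi, length.out = nPhi + 1)[-(nPhi + 1)]
  best <- Inf
  for (c1 in ct) {
    st <- sqrt(1 - c1^2)
    for (p in ph) {
      a <- projectionArea(coords, radii, c(st * cos(p), st * sin(p), c1),
                          nSlices = nSlices)
      if (a < best) best <- a
    }
  }
  best
}

randomRotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

randomCluster <- function(nAtoms, seed = 1, spread = 4,
                          radii = c(1.2, 2.0)) {
  set.seed(seed)
  list(coords = matrix(runif(nAtoms * 3, -spread, spread), nAtoms, 3),
       radii = runif(nAtoms, radii[1], radii[2]))
}

# random smooth 1D profile with a stated barrier height
randomSmoothProfile <- function(barrier, seed) {
  wells <- if (barrier > 1 && seed %% 2 == 0)
    data.frame(depth = barrier / 3, z = -6) else NULL
  syntheticProfile(barrierHeight = barrier, barrierWidth = 3.5,
                   wells = wells, roughnessAmplitude = 0.15, seed = seed)
}
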