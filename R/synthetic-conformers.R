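## Synthetic conformer ensembles with known geometry, so every descriptor
## has an analytic or brute-force reference.  Templates:
##   rod            — straight chain at rest (a chain with zero rest bend)
##   flexible_chain — chain whose inter-bond angles fluctuate frame to frame
##   sphere_cluster — compact blob with per-frame positional jitter
## Frames are generated in the body frame (no global rotation): every
## descriptor downstream is rotation invariant, which is itself tested.

# evaluate expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic conformer ensemble
#'
#' Builds an ensemble of conformers for an idealized molecule with
#' controllable elongation, flexibility, net charge and dipole.  The `rod`
#' template places atoms collinearly along z at spacing `bondLength`; the
#' `flexible_chain` template perturbs each internal bond direction
#' frame-to-frame by a Gaussian bend of rms `flexibility` radians (a rod is
#' the zero-flexibility limit); `sphere_cluster` draws rest positions once
#' inside a compact ball and jitters them per frame with positional rms
#' `flexibility * bondLength`.
#'
#' @param template one of `"rod"`, `"flexible_chain"`, `"sphere_cluster"`.
#' @param nAtoms number of atoms (>= 1).
#' @param bondLength bond length / cluster scale, Å (> 0).
#' @param atomRadius common van der Waals radius, Å (> 0).
#' @param charges per-atom partial charges, e; recycled scalar allowed.
#'   Must sum to `netCharge` within 1e-9 e.
#' @param netCharge declared net charge, e.
#' @param flexibility rms angular fluctuation, radians (chains) or relative
#'   positional jitter (clusters); 0 gives identical frames.
#' @param nFrames number of frames (>= 1).
#' @param seed integer seed; identical seed and arguments give bitwise
#'   identical ensembles.
#' @param elements per-atom element labels (default `"C"`).
#' @param masses per-atom masses, amu (default 12.011).
#' @return A [ConformerEnsemble-class].
#' @examples
#' ens <- simulateConformers("rod", nAtoms = 5, nFrames = 3)
#' nFrames(ens)
#' @export
simulateConformers <- function(template = c("rod", "flexible_chain",
                                            "sphere_cluster"),
                               nAtoms = 10L, bondLength = 1.5,
                               atomRadius = 1.7, charges = 0,
                               netCharge = NULL, flexibility = 0,
                               nFrames = 100L, seed = 1L,
                               elements = "C", masses = 12.011) {
  template <- match.arg(template)
  nAtoms <- as.integer(nAtoms); nFrames <- as.integer(nFrames)
  if (nAtoms < 1L) stop("nAtoms must be >= 1")
  if (nFrames < 1L) stop("nFrames must be >= 1")
  if (bondLength <= 0 || atomRadius <= 0)
    stop("bondLength and atomRadius must be positive")
  if (flexibility < 0) stop("flexibility must be >= 0")
  charges <- rep_len(charges, nAtoms)
  if (is.null(netCharge)) netCharge <- sum(charges)
  if (abs(sum(charges) - netCharge) > 1e-9)
    stop(sprintf("charges sum to %.6g e but netCharge is %.6g e",
                 sum(charges), netCharge))
  elements <- rep_len(elements, nAtoms)
  masses <- rep_len(masses, nAtoms)

  coords <- .withSeed(seed, {
    arr <- array(0, dim = c(nAtoms, 3L, nFrames))
    if (template %in% c("rod", "flexible_chain")) {
      for (f in seq_len(nFrames)) {
        arr[, , f] <- .buildChain(nAtoms, bondLength, flexibility)
      }
    } else {  # sphere_cluster
      rest <- matrix(0, nAtoms, 3L)
      if (nAtoms > 1L) {
        rad <- bondLength * nAtoms^(1 / 3)
        for (i in 2:nAtoms) {
          repeat {
            p <- runif(3, -rad, rad)
            if (sum(p^2) <= rad^2) break
          }
          rest[i, ] <- p
        }
      }
      for (f in seq_len(nFrames)) {
        arr[, , f] <- rest +
          matrix(rnorm(nAtoms * 3L, sd = flexibility * bondLength),
                 nAtoms, 3L)
      }
    }
    arr
  })

  new("ConformerEnsemble", coords = coords, charges = charges,
      radii = rep(atomRadius, nAtoms), masses = masses,
      elements = elements,
      metadata = list(template = template, bondLength = bondLength,
                      flexibility = flexibility, seed = seed))
}

# one chain conformation: successive unit bond vectors, each bent away from
# the previous by a Gaussian angle (rms `flex`) about a uniform azimuth
.buildChain <- function(nAtoms, bondLength, flex) {
  pos <- matrix(0, nAtoms, 3L)
  if (nAtoms == 1L) return(pos)
  d <- c(0, 0, 1)
  for (i in 2:nAtoms) {
    if (flex > 0) {
      theta <- rnorm(1, sd = flex)
      phi <- runif(1, 0, 2 * pi)
      d <- .bendDirection(d, theta, phi)
    }
    pos[i, ] <- pos[i - 1, ] + bondLength * d
  }
  pos
}

# rotate unit vector d by polar angle theta about an azimuth phi in the
# plane perpendicular to d
.bendDirection <- function(d, theta, phi) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  dn <- cos(theta) * d + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
  dn / sqrt(sum(dn^2))
}
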