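## S4 containers for the pipeline.  All validity checks encode the contracts
## the downstream numerics rely on (rectangular grids, matching atom counts,
## rate identities), so malformed objects fail at construction, not mid-run.

#' ConformerEnsemble: frames of atomic coordinates with per-atom properties
#'
#' Holds a solution-phase conformational ensemble of one molecule: an
#' `n_atoms x 3 x n_frames` coordinate array (Å) plus per-atom partial
#' charges (e), van der Waals radii (Å), masses (amu) and element labels.
#'
#' @slot coords numeric array, `n_atoms x 3 x n_frames`, Å.
#' @slot charges numeric, per-atom partial charge, e.
#' @slot radii numeric, per-atom van der Waals radius, Å (> 0).
#' @slot masses numeric, per-atom mass, amu.
#' @slot elements character, per-atom element label.
#' @slot metadata list, free-form provenance (generator settings, seeds,
#'   source files).
#'
#' @seealso [simulateConformers()], [readConformers()], [computeDescriptors()]
#' @export
setClass("ConformerEnsemble",
  representation(coords = "array", charges = "numeric", radii = "numeric",
                 masses = "numeric", elements = "character",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("ConformerEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  n <- d[1]
  if (n < 1L || d[3] < 1L)
    return("need at least one atom and one frame")
  for (nm in c("charges", "radii", "masses")) {
    if (length(slot(object, nm)) != n)
      return(sprintf("%s must have one entry per atom (%d)", nm, n))
  }
  if (length(object@elements) != n)
    return("elements must have one entry per atom")
  if (any(!is.finite(object@coords))) return("non-finite coordinates")
  if (any(object@radii <= 0)) return("vdW radii must be positive")
  TRUE
})

#' FES2D: two-dimensional free-energy surface on a regular grid
#'
#' A metadynamics-style free-energy surface F(CV1, z): CV1 is the
#' (dimensionless) orientation variable, z the position along the channel
#' diffusion axis (Å), values in kcal/mol.  Non-finite cells are carried as
#' an explicit mask.
#'
#' @slot cv1 numeric, strictly monotone CV1 grid.
#' @slot z numeric, strictly monotone z grid, Å.
#' @slot values numeric matrix, `length(cv1) x length(z)`, kcal/mol;
#'   masked cells hold `NA`.
#' @slot mask logical matrix, same shape, `TRUE` where the cell is masked.
#' @slot temperature numeric, simulation temperature, K.
#' @slot metadata list.
#'
#' @seealso [simulateFES()], [readFES2D()], [marginalizeFES()]
#' @export
setClass("FES2D",
  representation(cv1 = "numeric", z = "numeric", values = "matrix",
                 mask = "matrix", temperature = "numeric",
                 metadata = "list"),
  prototype(temperature = 300, metadata = list()))

.strictlyMonotone <- function(x) {
  d <- diff(x)
  length(x) >= 2L && (all(d > 0) || all(d < 0))
}

setValidity("FES2D", function(object) {
  if (!.strictlyMonotone(object@cv1)) return("cv1 grid not strictly monotone")
  if (!.strictlyMonotone(object@z)) return("z grid not strictly monotone")
  if (!identical(dim(object@values),
                 c(length(object@cv1), length(object@z))))
    return("values must be a length(cv1) x length(z) matrix")
  if (!identical(dim(object@mask), dim(object@values)))
    return("mask shape must match values")
  if (any(!is.finite(object@values[!object@mask])))
    return("unmasked cells must be finite")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    return("temperature must be a positive scalar (K)")
  TRUE
})

#' FES1D: one-dimensional free-energy profile along the diffusion axis
#'
#' A referenced potential of mean force F(z) (kcal/mol): the declared bulk
#' windows average exactly zero, and the channel interval
#' `[z_cis, z_trans]` plus detected features (wells, barrier top) are
#' carried along for the transport stage.
#'
#' @slot z numeric, strictly increasing z grid, Å.
#' @slot values numeric, F(z), kcal/mol, bulk-referenced.
#' @slot temperature numeric, K.
#' @slot bulkWindows 2x2 numeric matrix, rows `(lo, hi)` of the cis- and
#'   trans-side bulk windows used for referencing.
#' @slot channel numeric length 2, `c(z_cis, z_trans)`, Å.
#' @slot features data.frame with columns `type` ("well"/"barrier"), `z`,
#'   `F` (may have zero rows).
#' @slot metadata list.
#'
#' @seealso [marginalizeFES()], [permeability()], [currentCurve()]
#' @export
setClass("FES1D",
  representation(z = "numeric", values = "numeric", temperature = "numeric",
                 bulkWindows = "matrix", channel = "numeric",
                 features = "data.frame", metadata = "list"),
  prototype(temperature = 300, metadata = list(),
            features = data.frame(type = character(), z = numeric(),
                                  F = numeric())))

setValidity("FES1D", function(object) {
  if (!.strictlyMonotone(object@z) || any(diff(object@z) < 0))
    return("z grid must be strictly increasing")
  if (length(object@values) != length(object@z))
    return("values must match the z grid")
  if (any(!is.finite(object@values))) return("non-finite profile values")
  if (!identical(dim(object@bulkWindows), c(2L, 2L)))
    return("bulkWindows must be a 2x2 matrix of (lo, hi) rows")
  if (length(object@channel) != 2L || object@channel[1] >= object@channel[2])
    return("channel must be c(z_cis, z_trans) with z_cis < z_trans")
  inBulk <- .bulkIndex(object@z, object@bulkWindows)
  if (!any(inBulk)) return("bulk windows contain no grid points")
  if (abs(mean(object@values[inBulk])) > 1e-9)
    return("bulk windows must average 0 after referencing")
  TRUE
})

.bulkIndex <- function(z, windows) {
  (z >= windows[1, 1] & z <= windows[1, 2]) |
    (z >= windows[2, 1] & z <= windows[2, 2])
}

#' TransportConfig: parameters of the transport stage
#'
#' @slot D numeric, effective diffusion constant, nm^2/ns (literature effective value 1.0).
#' @slot temperature numeric, K.
#' @slot sigmaRef numeric, reference cross-section area converting bulk
#'   concentration to 1D boundary density, Å^2; defaults to the area of the
#'   17 Å restraint cylinder, `pi * 17^2`.
#' @slot channel numeric, optional `c(z_cis, z_trans)` override (length 0 to
#'   use the profile's own channel interval).
#'
#' @seealso [transportConfig()]
#' @export
setClass("TransportConfig",
  representation(D = "numeric", temperature = "numeric",
                 sigmaRef = "numeric", channel = "numeric"),
  prototype(D = 1.0, temperature = 300, sigmaRef = pi * 17^2,
            channel = numeric()))

setValidity("TransportConfig", function(object) {
  if (object@D <= 0) return("D must be positive")
  if (object@temperature <= 0) return("temperature must be positive")
  if (object@sigmaRef <= 0) return("sigmaRef must be positive")
  if (length(object@channel) %in% c(0L, 2L)) {
    if (length(object@channel) == 2L &&
        object@channel[1] >= object@channel[2])
      return("channel must satisfy z_cis < z_trans")
  } else return("channel must be empty or length 2")
  TRUE
})

#' RateSet: two-state Markov channel rates
#'
#' Entry rates (s^-1 M^-1), exit rates (s^-1), splitting probabilities and
#' the dwell time `tauB = 1 / (koffTrans + koffCis)` of the single-occupancy
#' channel model.
#'
#' @slot konCis,konTrans numeric, entry rate constants, s^-1 M^-1.
#' @slot koffCis,koffTrans numeric, exit rates, s^-1.
#' @slot tauB numeric, dwell time, s.
#' @slot phiCis,phiTrans numeric, splitting probabilities from the bound
#'   state (sum to 1).
#' @slot metadata list (occupied-state position, flags).
#'
#' @seealso [ratesFromFES()], [markovCurrent()]
#' @export
setClass("RateSet",
  representation(konCis = "numeric", konTrans = "numeric",
                 koffCis = "numeric", koffTrans = "numeric",
                 tauB = "numeric", phiCis = "numeric", phiTrans = "numeric",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("RateSet", function(object) {
  rt <- c(object@konCis, object@konTrans, object@koffCis, object@koffTrans)
  if (any(rt < 0)) return("rates must be non-negative")
  if (abs(object@phiCis + object@phiTrans - 1) > 1e-9)
    return("splitting probabilities must sum to 1")
  ksum <- object@koffCis + object@koffTrans
  if (ksum > 0 && abs(object@tauB * ksum - 1) > 1e-12)
    return("tauB must equal 1/(koffTrans + koffCis)")
  TRUE
})

#' CurrentCurve: predicted translocation current versus concentration
#'
#' @slot concentration numeric, cis-side concentration grid, M.
#' @slot current numeric, steady-state current, molecules/s.
#' @slot P numeric, linear-regime permeability, s^-1 M^-1.
#' @slot Imax numeric, saturated current (`koffTrans`), s^-1.
#' @slot Khalf numeric, half-saturation concentration, M.
#' @slot cSat90 numeric, concentration where the current reaches 90% of
#'   `Imax` (`9 * Khalf`), M.
#' @slot rates [RateSet-class] behind the curve.
#' @slot metadata list.
#'
#' @seealso [currentCurve()]
#' @export
setClass("CurrentCurve",
  representation(concentration = "numeric", current = "numeric",
                 P = "numeric", Imax = "numeric", Khalf = "numeric",
                 cSat90 = "numeric", rates = "RateSet", metadata = "list"),
  prototype(metadata = list()))

setValidity("CurrentCurve", function(object) {
  if (length(object@current) != length(object@concentration))
    return("current and concentration grids must match")
  if (any(object@concentration < 0)) return("concentrations must be >= 0")
  TRUE
})

#' DescriptorSummary: distribution summary of one descriptor
#'
#' Mean, histogram (normalized density) and histogram modes of a
#' per-frame descriptor such as the minimum radius or the transversal
#' dipole moment; bimodal ensembles report every mode.
#'
#' @slot mean numeric scalar.
#' @slot modes numeric, bin centres of the histogram's (prominent) local
#'   maxima, sorted.
#' @slot breaks numeric, histogram bin edges.
#' @slot density numeric, normalized density per bin (integrates to 1).
#' @slot binWidth numeric scalar.
#' @slot metadata list.
#'
#' @seealso [summarizeDescriptor()], [distributionOverlap()]
#' @export
setClass("DescriptorSummary",
  representation(mean = "numeric", modes = "numeric", breaks = "numeric",
                 density = "numeric", binWidth = "numeric",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("DescriptorSummary", function(object) {
  if (length(object@breaks) != length(object@density) + 1L)
    return("breaks must have one more entry than density")
  tot <- sum(object@density * diff(object@breaks))
  if (abs(tot - 1) > 1e-6) return("histogram must integrate to 1")
  TRUE
})
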