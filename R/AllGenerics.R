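## Accessor generics and show methods.  Slot access stays internal; user
## code goes through these.

#' @name accessors
#' @title Accessors for porinflux S4 containers
#' @description Small accessor family: number of frames/atoms and per-atom
#'   tables of a [ConformerEnsemble-class]; grids, values, temperature,
#'   channel interval and feature table of a free-energy surface; rate
#'   constants and dwell time of a [RateSet-class]; the concentration/current
#'   table of a [CurrentCurve-class].
#' @param x object.
#' @param i frame index.
#' @return See each accessor's description.
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("atomCharges", function(x) standardGeneric("atomCharges"))
#' @rdname accessors
#' @export
setGeneric("vdwRadii", function(x) standardGeneric("vdwRadii"))
#' @rdname accessors
#' @export
setGeneric("atomMasses", function(x) standardGeneric("atomMasses"))
#' @rdname accessors
#' @export
setGeneric("zGrid", function(x) standardGeneric("zGrid"))
#' @rdname accessors
#' @export
setGeneric("cv1Grid", function(x) standardGeneric("cv1Grid"))
#' @rdname accessors
#' @export
setGeneric("fesValues", function(x) standardGeneric("fesValues"))
#' @rdname accessors
#' @export
setGeneric("fesTemperature", function(x) standardGeneric("fesTemperature"))
#' @rdname accessors
#' @export
setGeneric("channelInterval", function(x) standardGeneric("channelInterval"))
#' @rdname accessors
#' @export
setGeneric("fesFeatures", function(x) standardGeneric("fesFeatures"))
#' @rdname accessors
#' @export
setGeneric("rateConstants", function(x) standardGeneric("rateConstants"))
#' @rdname accessors
#' @export
setGeneric("dwellTime", function(x) standardGeneric("dwellTime"))
#' @rdname accessors
#' @export
setGeneric("currentTable", function(x) standardGeneric("currentTable"))

#' Locate wells, barrier top and saddle points of a free-energy surface
#'
#' For a [FES1D-class] profile: local minima (wells) inside the channel
#' interval whose topographic prominence exceeds `levelTol`, plus the
#' channel barrier top (global maximum inside the channel).  For a
#' [FES2D-class] surface: 2D local minima and saddle points by the
#' 4-neighbour criterion.
#'
#' @param x a [FES1D-class] or [FES2D-class].
#' @param levelTol numeric, kcal/mol; wiggles shallower than this are not
#'   reported (default 0.3).
#' @param channel optional `c(z_cis, z_trans)` override for FES1D.
#' @return data.frame with columns `type` ("well", "barrier" or "saddle"),
#'   coordinates and `F`.
#' @export
setGeneric("findFeatures",
           function(x, levelTol = 0.3, ...) standardGeneric("findFeatures"))

## ---- methods ----

#' @rdname accessors
setMethod("nFrames", "ConformerEnsemble", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("nAtoms", "ConformerEnsemble", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("frameCoords", "ConformerEnsemble", function(x, i) {
  stopifnot(i >= 1, i <= nFrames(x))
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})
#' @rdname accessors
setMethod("atomCharges", "ConformerEnsemble", function(x) x@charges)
#' @rdname accessors
setMethod("vdwRadii", "ConformerEnsemble", function(x) x@radii)
#' @rdname accessors
setMethod("atomMasses", "ConformerEnsemble", function(x) x@masses)

#' @rdname accessors
setMethod("zGrid", "FES2D", function(x) x@z)
#' @rdname accessors
setMethod("zGrid", "FES1D", function(x) x@z)
#' @rdname accessors
setMethod("cv1Grid", "FES2D", function(x) x@cv1)
#' @rdname accessors
setMethod("fesValues", "FES2D", function(x) x@values)
#' @rdname accessors
setMethod("fesValues", "FES1D", function(x) x@values)
#' @rdname accessors
setMethod("fesTemperature", "FES2D", function(x) x@temperature)
#' @rdname accessors
setMethod("fesTemperature", "FES1D", function(x) x@temperature)
#' @rdname accessors
setMethod("channelInterval", "FES1D", function(x) x@channel)
#' @rdname accessors
setMethod("fesFeatures", "FES1D", function(x) x@features)

#' @rdname accessors
setMethod("rateConstants", "RateSet", function(x) {
  c(konCis = x@konCis, konTrans = x@konTrans,
    koffCis = x@koffCis, koffTrans = x@koffTrans,
    phiCis = x@phiCis, phiTrans = x@phiTrans)
})
#' @rdname accessors
setMethod("dwellTime", "RateSet", function(x) x@tauB)
#' @rdname accessors
setMethod("rateConstants", "CurrentCurve", function(x) rateConstants(x@rates))
#' @rdname accessors
setMethod("dwellTime", "CurrentCurve", function(x) dwellTime(x@rates))
#' @rdname accessors
setMethod("currentTable", "CurrentCurve", function(x) {
  data.frame(concentration = x@concentration, current = x@current)
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d atoms x %d frames\n",
              nAtoms(object), nFrames(object)))
  cat(sprintf("  net charge %.4f e; elements: %s\n",
              sum(object@charges),
              paste(unique(object@elements), collapse = " ")))
})

setMethod("show", "FES2D", function(object) {
  cat(sprintf("FES2D: %d x %d grid (cv1 x z), T = %g K\n",
              length(object@cv1), length(object@z), object@temperature))
  cat(sprintf("  cv1 in [%g, %g]; z in [%g, %g] A; %d masked cell(s)\n",
              min(object@cv1), max(object@cv1), min(object@z),
              max(object@z), sum(object@mask)))
})

setMethod("show", "FES1D", function(object) {
  cat(sprintf("FES1D: %d z points in [%g, %g] A, T = %g K\n",
              length(object@z), min(object@z), max(object@z),
              object@temperature))
  cat(sprintf("  channel [%.2f, %.2f] A; max F in channel %.3f kcal/mol\n",
              object@channel[1], object@channel[2],
              max(object@values[object@z >= object@channel[1] &
                                  object@z <= object@channel[2]])))
  if (nrow(object@features))
    cat(sprintf("  features: %s\n",
                paste(sprintf("%s(%.1f A, %.2f)", object@features$type,
                              object@features$z, object@features$F),
                      collapse = ", ")))
})

setMethod("show", "RateSet", function(object) {
  cat("RateSet (two-state Markov channel)\n")
  cat(sprintf("  koff_cis %.4g /s, koff_trans %.4g /s, tau_b %.4g s\n",
              object@koffCis, object@koffTrans, object@tauB))
  cat(sprintf("  kon_cis %.4g /s/M, kon_trans %.4g /s/M, phi_trans %.3f\n",
              object@konCis, object@konTrans, object@phiTrans))
})

setMethod("show", "CurrentCurve", function(object) {
  cat(sprintf(
    "CurrentCurve: %d concentrations in [%.3g, %.3g] M\n",
    length(object@concentration), min(object@concentration),
    max(object@concentration)))
  cat(sprintf("  P = %.4g /s/M, Imax = %.4g /s, K_half = %.4g M\n",
              object@P, object@Imax, object@Khalf))
})

setMethod("show", "DescriptorSummary", function(object) {
  cat(sprintf("DescriptorSummary: mean %.4g, mode(s) %s (bin width %g)\n",
              object@mean, paste(signif(object@modes, 4), collapse = ", "),
              object@binWidth))
})
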