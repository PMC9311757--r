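## Reduction of 2D free-energy surfaces to 1D profiles along z.
##
## The marginal is the Boltzmann average over the orientation variable,
##   F1(z) = -kT log[ sum_cv1 exp(-F(cv1, z)/kT) w(cv1) ],
## evaluated with trapezoidal weights and log-sum-exp stabilization, then
## shifted so the declared bulk windows average exactly zero.  Masked cells
## are excluded with measure renormalization.

# stabilized -kT log sum w exp(-f/kT)
.boltzmannAverage <- function(f, w, kT) {
  a <- -f / kT + log(w)
  m <- max(a)
  -kT * (m + log(sum(exp(a - m))))
}

#' Marginalize a 2D free-energy surface to a 1D profile along z
#'
#' Boltzmann-averages `F(cv1, z)` over the orientation variable CV1 with
#' trapezoidal quadrature (log-sum-exp stabilized), then references the
#' result so the bulk windows (default: the outer `bulkFraction` of the z
#' range at each end) average exactly zero, and determines the channel
#' interval as the outermost z where `|F|` first exceeds
#' `channelThreshold` moving inward from each bulk window.
#'
#' Masked cells are excluded from the CV1 sum with measure renormalization;
#' a z column with more than half of its cells masked is flagged in the
#' metadata, and a fully masked column is an error.  An asymmetry between
#' the two bulk plateaus larger than `0.5 * kT` raises a warning (the two
#' windows are still averaged jointly).
#'
#' @param fes a [FES2D-class].
#' @param bulkFraction fraction of the z range used as bulk window at each
#'   end (default 0.2); ignored when `bulkWindows` is given.
#' @param bulkWindows optional 2x2 matrix, rows `(lo, hi)` of the two bulk
#'   windows, Å.
#' @param channelThreshold |F| level (kcal/mol) delimiting the channel;
#'   default `0.5 * kT`.
#' @param levelTol feature prominence tolerance passed to [findFeatures()].
#' @return A [FES1D-class] with channel interval and features attached.
#' @examples
#' g <- simulateFES(barrierHeight = 4, seed = 2)
#' f1 <- marginalizeFES(g$fes)
#' channelInterval(f1)
#' @export
marginalizeFES <- function(fes, bulkFraction = 0.2, bulkWindows = NULL,
                           channelThreshold = NULL, levelTol = 0.3) {
  stopifnot(is(fes, "FES2D"))
  kT <- .kT(fes@temperature)
  w <- .trapWeights(fes@cv1)
  W <- sum(w)
  nZ <- length(fes@z)
  f1 <- numeric(nZ)
  flagged <- integer()
  for (j in seq_len(nZ)) {
    ok <- !fes@mask[, j]
    if (!any(ok))
      stop(sprintf("z column %d (z = %g) is fully masked", j, fes@z[j]))
    if (mean(ok) < 0.5) flagged <- c(flagged, j)
    wj <- w[ok] * (W / sum(w[ok]))  # measure renormalization
    f1[j] <- .boltzmannAverage(fes@values[ok, j], wj, kT)
  }
  .makeFES1D(fes@z, f1, fes@temperature, bulkWindows = bulkWindows,
             bulkFraction = bulkFraction,
             channelThreshold = channelThreshold, levelTol = levelTol,
             metadata = list(flaggedColumns = flagged,
                             cv1Width = W, source = "marginalizeFES"))
}

# build a referenced FES1D: bulk shift, asymmetry warning, channel
# detection, feature extraction
.makeFES1D <- function(z, f, temperature, bulkWindows = NULL,
                       bulkFraction = 0.2, channel = NULL,
                       channelThreshold = NULL, levelTol = 0.3,
                       metadata = list()) {
  kT <- .kT(temperature)
  if (is.null(bulkWindows)) {
    bw <- bulkFraction * diff(range(z))
    bulkWindows <- rbind(c(min(z), min(z) + bw),
                         c(max(z) - bw, max(z)))
  }
  idx <- .bulkIndex(z, bulkWindows)
  if (!any(idx)) stop("bulk windows contain no grid points")
  f <- f - mean(f[idx])
  loIdx <- z >= bulkWindows[1, 1] & z <= bulkWindows[1, 2]
  hiIdx <- z >= bulkWindows[2, 1] & z <= bulkWindows[2, 2]
  if (any(loIdx) && any(hiIdx)) {
    asym <- abs(mean(f[loIdx]) - mean(f[hiIdx]))
    if (asym > 0.5 * kT)
      warning(sprintf(
        "bulk plateaus differ by %.3f kcal/mol; referencing to their joint mean",
        asym))
  }
  if (is.null(channelThreshold)) channelThreshold <- 0.5 * kT
  if (is.null(channel))
    channel <- .detectChannel(z, f, bulkWindows, channelThreshold)
  obj <- new("FES1D", z = z, values = f, temperature = temperature,
             bulkWindows = bulkWindows, channel = channel,
             metadata = metadata)
  obj@features <- findFeatures(obj, levelTol = levelTol)
  obj
}

# outermost z where |F| first exceeds the threshold moving inward from
# each bulk window; falls back to the inner bulk edges for flat profiles
.detectChannel <- function(z, f, bulkWindows, threshold) {
  interior <- which(z > bulkWindows[1, 2] & z < bulkWindows[2, 1])
  exceeds <- which(abs(f) > threshold)
  exceeds <- exceeds[exceeds %in% interior]
  if (!length(exceeds)) {
    if (!length(interior)) interior <- seq_along(z)
    return(c(z[min(interior)], z[max(interior)]))
  }
  c(z[min(exceeds)], z[max(exceeds)])
}

#' @rdname findFeatures
setMethod("findFeatures", "FES1D", function(x, levelTol = 0.3,
                                            channel = NULL) {
  z <- x@z; f <- x@values
  if (is.null(channel)) channel <- x@channel
  inside <- which(z >= channel[1] & z <= channel[2])
  if (!length(inside)) stop("empty channel interval")
  feats <- data.frame(type = character(), z = numeric(), F = numeric())
  ## wells: prominent interior local minima
  mins <- .localExtrema(f, minima = TRUE)
  mins <- mins[mins %in% inside]
  for (i in mins) {
    if (.prominence(f, i, minima = TRUE) >= levelTol)
      feats <- rbind(feats, data.frame(type = "well", z = z[i], F = f[i]))
  }
  ## barrier top: global maximum inside the channel
  ib <- inside[which.max(f[inside])]
  if (f[ib] > levelTol)
    feats <- rbind(feats, data.frame(type = "barrier", z = z[ib],
                                     F = f[ib]))
  rownames(feats) <- NULL
  feats
})

#' @rdname findFeatures
setMethod("findFeatures", "FES2D", function(x, levelTol = 0.3) {
  v <- x@values
  v[x@mask] <- NA
  nc <- nrow(v); nz <- ncol(v)
  feats <- data.frame(type = character(), cv1 = numeric(), z = numeric(),
                      F = numeric())
  eps <- levelTol / 10
  for (i in 2:(nc - 1)) {
    for (j in 2:(nz - 1)) {
      nb <- c(v[i - 1, j], v[i + 1, j], v[i, j - 1], v[i, j + 1])
      if (any(is.na(nb)) || is.na(v[i, j])) next
      dcv <- c(v[i - 1, j], v[i + 1, j]) - v[i, j]
      dz <- c(v[i, j - 1], v[i, j + 1]) - v[i, j]
      if (all(nb - v[i, j] > eps)) {
        feats <- rbind(feats, data.frame(type = "well", cv1 = x@cv1[i],
                                         z = x@z[j], F = v[i, j]))
      } else if ((all(dcv > eps) && all(dz < -eps)) ||
                 (all(dcv < -eps) && all(dz > eps))) {
        ## 4-neighbour saddle: minimum along one axis, maximum along the
        ## other
        feats <- rbind(feats, data.frame(type = "saddle", cv1 = x@cv1[i],
                                         z = x@z[j], F = v[i, j]))
      }
    }
  }
  rownames(feats) <- NULL
  feats
})

.localExtrema <- function(f, minima = TRUE) {
  s <- if (minima) -f else f
  n <- length(s)
  if (n < 3L) return(integer())
  which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
}

# topographic prominence of a 1D extremum: height above the lower of the
# two enclosing saddles (range edges count as saddles)
.prominence <- function(f, i, minima = TRUE) {
  s <- if (minima) -f else f
  n <- length(s)
  left <- if (i > 1) min(s[1:(i - 1)]) else s[i]
  right <- if (i < n) min(s[(i + 1):n]) else s[i]
  ## climb out each side until a higher peak or the edge; the barrier to
  ## cross is the minimum along the way
  hl <- s[i] - left
  hr <- s[i] - right
  min(hl, hr)
}
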