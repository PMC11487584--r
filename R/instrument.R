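#' Default TRS time grid
#'
#' 0-10 ns covered by 4096 uniform bins (~2.44 ps each), returned as bin
#' centers so every point is strictly positive. Resolves sub-100-ps response
#' functions while keeping the convolution cheap.
#'
#' @param tMax upper edge (ns).
#' @param nBins number of bins.
#' @return numeric vector of bin centers (ns).
#' @export
defaultTimeGrid <- function(tMax = 10, nBins = 4096) {
  dt <- tMax / nBins
  (seq_len(nBins) - 0.5) * dt
}

#' Default DCS delay grid
#'
#' 60 log-spaced delays from 1e-7 to 1e-2 s, emulating the output of a
#' multi-tau correlator.
#'
#' @param tauMin shortest delay (s).
#' @param tauMax longest delay (s).
#' @param n number of points.
#' @return numeric vector of delays (s).
#' @export
defaultDelayGrid <- function(tauMin = 1e-7, tauMax = 1e-2, n = 60) {
  10^seq(log10(tauMin), log10(tauMax), length.out = n)
}

#' Generate a synthetic instrument response function
#'
#' A unimodal symmetric bell (Gaussian) of prescribed FWHM centered at t0,
#' sampled on the given uniform grid and normalized to unit area. The device
#' response is never tabulated for this instrument class, so a smooth bell of
#' realistic width (default 0.4 ns elsewhere in the package) stands in.
#'
#' @param fwhm requested full width at half maximum (ns); must span at least
#'   2 grid bins, otherwise a resolution error is raised.
#' @param t0 peak position (ns); must lie inside the grid.
#' @param tGrid uniform time grid (ns).
#' @return an \linkS4class{IRF}.
#' @examples
#' irf <- makeIRF(fwhm = 0.4, t0 = 2.5, tGrid = defaultTimeGrid())
#' @export
makeIRF <- function(fwhm = 0.4, t0 = 2.5, tGrid = defaultTimeGrid()) {
  tGrid <- as.numeric(tGrid)
  if (fwhm <= 0) stop("'fwhm' must be positive")
  dt <- tGrid[2L] - tGrid[1L]
  if (fwhm < 2 * dt)
    stop("resolution error: requested IRF FWHM (", fwhm,
         " ns) is narrower than 2 bins (", signif(2 * dt, 3), " ns)")
  if (t0 < tGrid[1L] || t0 > tGrid[length(tGrid)])
    stop("'t0' must lie inside the time grid")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  vals <- exp(-(tGrid - t0)^2 / (2 * sigma^2))
  vals <- vals / (sum(vals) * dt)
  new("IRF", tGrid = tGrid, values = vals, fwhm = fwhm)
}

# Discrete linear convolution of a model curve with the IRF on the shared
# uniform grid, truncated to the grid length. Circular wrap-around is
# forbidden by construction (zero-padded open convolution, first N samples).
.convolve_irf <- function(modelVals, irfVals, dt) {
  n <- length(modelVals)
  stopifnot(length(irfVals) == n)
  out <- convolve(c(modelVals, numeric(n)), rev(c(irfVals, numeric(n))),
                  type = "open")[seq_len(n)]
  pmax(out * dt, 0)
}

#' Convolve a reflectance model curve with an instrument response
#'
#' @param model a \linkS4class{ModelCurve} of kind \code{"reflectance"} on the
#'   same uniform grid as the IRF.
#' @param irf an \linkS4class{IRF}.
#' @return a \linkS4class{ModelCurve} of kind \code{"reflectance"}: the
#'   instrument-blurred curve. The total area is preserved up to truncation.
#' @export
convolveWithIRF <- function(model, irf) {
  stopifnot(is(model, "ModelCurve"), is(irf, "IRF"))
  if (length(model@abscissa) != length(irf@tGrid) ||
      max(abs(model@abscissa - irf@tGrid)) > 1e-9)
    stop("model and IRF must share the same time grid")
  dt <- irf@tGrid[2L] - irf@tGrid[1L]
  new("ModelCurve", abscissa = model@abscissa,
      values = .convolve_irf(model@values, irf@values, dt),
      kind = "reflectance")
}

#' Simulate a measured DTOF histogram
#'
#' Builds the expected curve as (semi-infinite reflectance convolved with the
#' IRF), rescales it so the expected signal counts sum to \code{totalCounts},
#' adds a flat expected background of \code{backgroundRate} counts per bin,
#' and draws each bin independently from a Poisson law. Identical seeds give
#' identical histograms.
#'
#' @param props \linkS4class{OpticalProperties}.
#' @param geom \linkS4class{ProbeGeometry}.
#' @param irf \linkS4class{IRF}; its grid is the histogram grid.
#' @param totalCounts expected detected signal photons (> 0).
#' @param backgroundRate expected background counts per bin (>= 0).
#' @param seed integer seed; NULL leaves the RNG stream untouched.
#' @param noise draw Poisson counts (TRUE) or return the expected curve
#'   rounded to nothing, i.e., the noise-free expectation (FALSE).
#' @param nAveraged bookkeeping: acquisitions averaged.
#' @return a \linkS4class{DTOFHistogram}.
#' @examples
#' irf <- makeIRF(0.4, 2.5, defaultTimeGrid())
#' d <- simulateDTOF(opticalProperties(0.14, 11, 687), probeGeometry(),
#'                   irf, totalCounts = 1e6, backgroundRate = 1, seed = 1)
#' @export
simulateDTOF <- function(props, geom, irf, totalCounts, backgroundRate = 0,
                         seed = NULL, noise = TRUE, nAveraged = 100) {
  stopifnot(is(irf, "IRF"))
  if (totalCounts <= 0) stop("'totalCounts' must be positive")
  if (backgroundRate < 0) stop("'backgroundRate' must be nonnegative")
  refl <- trsReflectance(irf@tGrid, props, geom)
  dt <- irf@tGrid[2L] - irf@tGrid[1L]
  expected <- .convolve_irf(refl@values, irf@values, dt)
  expected <- expected / sum(expected) * totalCounts + backgroundRate
  counts <- if (noise) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    rpois(length(expected), expected)
  } else expected
  new("DTOFHistogram", tGrid = irf@tGrid, counts = as.numeric(counts),
      wavelength = props@wavelength, nAveraged = as.numeric(nAveraged),
      backgroundLevel = as.numeric(backgroundRate))
}

#' Simulate a measured g2 curve
#'
#' Adds detector afterpulsing and photon-counting noise to an ideal g2 model
#' curve: \code{g2_ideal + amp * exp(-tau/tau_ap) + noise}, with zero-mean
#' Gaussian noise whose per-point standard deviation scales as
#' \eqn{1/\sqrt{countRate \cdot duration}} (a simplified stand-in for the
#' full correlation-noise statistics, adequate for exercising QC thresholds).
#' Afterpulsing adds artificial correlation at short delays and inflates the
#' apparent beta.
#'
#' @param g2Ideal a \linkS4class{ModelCurve} of kind \code{"g2"}.
#' @param countRate detected intensity (kHz), >= 0.
#' @param duration integration time (s), > 0.
#' @param afterpulsingAmp amplitude of the afterpulsing term (>= 0).
#' @param afterpulsingTau decay time of the afterpulsing term (s).
#' @param seed integer seed; NULL leaves the RNG stream untouched.
#' @param nChannels bookkeeping: detection channels averaged.
#' @param noiseScale dimensionless prefactor of the noise model (default 1;
#'   the per-point sd is noiseScale / sqrt(1000 * countRate * duration),
#'   countRate in kHz).
#' @return a \linkS4class{G2Curve}.
#' @export
simulateG2 <- function(g2Ideal, countRate, duration, afterpulsingAmp = 0,
                       afterpulsingTau = 1e-6, seed = NULL, nChannels = 4,
                       noiseScale = 1) {
  stopifnot(is(g2Ideal, "ModelCurve"))
  if (!identical(g2Ideal@kind, "g2")) stop("'g2Ideal' must be of kind 'g2'")
  if (countRate < 0) stop("'countRate' must be >= 0 (kHz)")
  if (duration <= 0) stop("'duration' must be positive (s)")
  if (afterpulsingAmp < 0) stop("'afterpulsingAmp' must be >= 0")
  tau <- g2Ideal@abscissa
  vals <- g2Ideal@values + afterpulsingAmp * exp(-tau / afterpulsingTau)
  sdPt <- if (countRate > 0) noiseScale / sqrt(1000 * countRate * duration)
          else noiseScale  # no signal: noise dominates at unit scale
  if (!is.null(seed)) set.seed(as.integer(seed))
  vals <- vals + rnorm(length(vals), sd = sdPt)
  new("G2Curve", tauGrid = tau, values = as.numeric(vals),
      countRate = as.numeric(countRate), nChannels = as.numeric(nChannels),
      duration = as.numeric(duration))
}

.same_grid <- function(a, b) length(a) == length(b) && max(abs(a - b)) <= 0

#' @rdname averageCurves
#' @export
setMethod("averageCurves", "list", function(curves) {
  if (!length(curves)) stop("cannot average an empty list of curves")
  if (all(vapply(curves, is, logical(1), "DTOFHistogram"))) {
    grid <- curves[[1L]]@tGrid
    wl <- curves[[1L]]@wavelength
    for (cu in curves[-1L]) {
      if (!.same_grid(cu@tGrid, grid))
        stop("grid error: DTOF histograms are on different time grids")
      if (cu@wavelength != wl)
        stop("cannot average DTOFs from different wavelengths")
    }
    mean_counts <- Reduce(`+`, lapply(curves, slot, "counts")) / length(curves)
    new("DTOFHistogram", tGrid = grid, counts = mean_counts, wavelength = wl,
        nAveraged = sum(vapply(curves, slot, numeric(1), "nAveraged")),
        backgroundLevel = mean(vapply(curves, slot, numeric(1),
                                      "backgroundLevel")))
  } else if (all(vapply(curves, is, logical(1), "G2Curve"))) {
    grid <- curves[[1L]]@tauGrid
    for (cu in curves[-1L])
      if (!.same_grid(cu@tauGrid, grid))
        stop("grid error: g2 curves are on different delay grids")
    mean_vals <- Reduce(`+`, lapply(curves, slot, "values")) / length(curves)
    new("G2Curve", tauGrid = grid, values = mean_vals,
        countRate = mean(vapply(curves, slot, numeric(1), "countRate")),
        nChannels = sum(vapply(curves, slot, numeric(1), "nChannels")),
        duration = mean(vapply(curves, slot, numeric(1), "duration")))
  } else stop("'curves' must be all DTOFHistogram or all G2Curve objects")
})

#' @rdname normalizeToPeak
#' @export
setMethod("normalizeToPeak", "ModelCurve", function(x) {
  m <- max(x@values)
  if (m <= 0) stop("cannot normalize a curve with nonpositive maximum")
  new("ModelCurve", abscissa = x@abscissa, values = x@values / m, kind = x@kind)
})

#' @rdname normalizeToPeak
#' @export
setMethod("normalizeToPeak", "DTOFHistogram", function(x) {
  m <- max(x@counts)
  if (m <= 0) stop("cannot normalize a curve with nonpositive maximum")
  new("DTOFHistogram", tGrid = x@tGrid, counts = x@counts / m,
      wavelength = x@wavelength, nAveraged = x@nAveraged,
      backgroundLevel = x@backgroundLevel / m)
})
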