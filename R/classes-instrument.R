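#' Instrument response function
#'
#' The temporal response of the TRS device to a zero-width light pulse. Its
#' FWHM sets the temporal resolution; the DTOF measured on tissue is the
#' convolution of the medium's reflectance with this response.
#'
#' @slot tGrid uniform time grid (ns).
#' @slot values nonnegative response, normalized to unit area (sum * bin = 1).
#' @slot fwhm full width at half maximum (ns).
#' @export
setClass("IRF",
  representation(tGrid = "numeric", values = "numeric", fwhm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tGrid) < 4L || any(diff(object@tGrid) <= 0))
      msg <- c(msg, "'tGrid' must be strictly increasing")
    if (length(object@values) != length(object@tGrid))
      msg <- c(msg, "'values' and 'tGrid' lengths differ")
    if (any(object@values < 0)) msg <- c(msg, "'values' must be nonnegative")
    dt <- diff(object@tGrid)
    # tolerance admits 12-significant-digit text round trips
    if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
      msg <- c(msg, "'tGrid' must be uniform")
    if (abs(sum(object@values) * dt[1L] - 1) > 1e-9)
      msg <- c(msg, "IRF must have unit area")
    if (length(object@fwhm) != 1L || !is.finite(object@fwhm) || object@fwhm <= 0)
      msg <- c(msg, "'fwhm' must be a positive number (ns)")
    if (length(msg)) msg else TRUE
  }
)

#' Distribution of photon times of flight (DTOF)
#'
#' Binned photon arrival-time counts measured by TRS at one wavelength, on a
#' uniform grid, with bookkeeping for averaging and the flat pre-pulse
#' background expected from detector noise and ambient light.
#'
#' @slot tGrid uniform time grid (ns).
#' @slot counts nonnegative counts per bin.
#' @slot wavelength nm.
#' @slot nAveraged number of 1-s acquisitions averaged into the histogram.
#' @slot backgroundLevel expected background counts per bin.
#' @export
setClass("DTOFHistogram",
  representation(tGrid = "numeric", counts = "numeric", wavelength = "numeric",
                 nAveraged = "numeric", backgroundLevel = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tGrid) < 4L || any(diff(object@tGrid) <= 0))
      msg <- c(msg, "'tGrid' must be strictly increasing")
    dt <- diff(object@tGrid)
    if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
      msg <- c(msg, "'tGrid' must be uniform")
    if (length(object@counts) != length(object@tGrid))
      msg <- c(msg, "'counts' and 'tGrid' lengths differ")
    if (any(!is.finite(object@counts)) || any(object@counts < 0))
      msg <- c(msg, "'counts' must be finite and nonnegative")
    if (length(object@nAveraged) != 1L || object@nAveraged < 1)
      msg <- c(msg, "'nAveraged' must be >= 1")
    if (length(object@backgroundLevel) != 1L || object@backgroundLevel < 0)
      msg <- c(msg, "'backgroundLevel' must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Measured intensity autocorrelation curve
#'
#' A DCS g2 curve on a log-spaced delay grid (emulating a multi-tau
#' correlator), with the detected count rate, the number of detection channels
#' averaged, and the integration time.
#'
#' @slot tauGrid strictly increasing delay times (s).
#' @slot values intensity autocorrelation values (dimensionless).
#' @slot countRate detected intensity (kHz), >= 0.
#' @slot nChannels number of detection channels averaged.
#' @slot duration integration time (s).
#' @export
setClass("G2Curve",
  representation(tauGrid = "numeric", values = "numeric", countRate = "numeric",
                 nChannels = "numeric", duration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tauGrid) < 4L || any(diff(object@tauGrid) <= 0))
      msg <- c(msg, "'tauGrid' must be strictly increasing")
    if (length(object@values) != length(object@tauGrid))
      msg <- c(msg, "'values' and 'tauGrid' lengths differ")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "'values' must be finite")
    if (length(object@countRate) != 1L || object@countRate < 0)
      msg <- c(msg, "'countRate' must be >= 0 (kHz)")
    if (length(object@nChannels) != 1L || object@nChannels < 1)
      msg <- c(msg, "'nChannels' must be >= 1")
    if (length(object@duration) != 1L || object@duration <= 0)
      msg <- c(msg, "'duration' must be positive (s)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a DTOF histogram
#' @param tGrid uniform time grid (ns).
#' @param counts counts per bin.
#' @param wavelength nm.
#' @param nAveraged acquisitions averaged.
#' @param backgroundLevel expected background counts per bin.
#' @return a \linkS4class{DTOFHistogram}.
#' @export
dtofHistogram <- function(tGrid, counts, wavelength, nAveraged = 1,
                          backgroundLevel = 0) {
  new("DTOFHistogram", tGrid = as.numeric(tGrid), counts = as.numeric(counts),
      wavelength = as.numeric(wavelength), nAveraged = as.numeric(nAveraged),
      backgroundLevel = as.numeric(backgroundLevel))
}

#' Construct a g2 curve object
#' @param tauGrid strictly increasing delays (s).
#' @param values g2 values.
#' @param countRate detected intensity (kHz).
#' @param nChannels channels averaged.
#' @param duration integration time (s).
#' @return a \linkS4class{G2Curve}.
#' @export
g2Curve <- function(tauGrid, values, countRate, nChannels = 1, duration = 1) {
  new("G2Curve", tauGrid = as.numeric(tauGrid), values = as.numeric(values),
      countRate = as.numeric(countRate), nChannels = as.numeric(nChannels),
      duration = as.numeric(duration))
}

#' @rdname curveAbscissa
#' @export
setMethod("curveAbscissa", "IRF", function(x) x@tGrid)
#' @rdname curveValues
#' @export
setMethod("curveValues", "IRF", function(x) x@values)
#' @rdname curveAbscissa
#' @export
setMethod("curveAbscissa", "DTOFHistogram", function(x) x@tGrid)
#' @rdname curveValues
#' @export
setMethod("curveValues", "DTOFHistogram", function(x) x@counts)
#' @rdname curveAbscissa
#' @export
setMethod("curveAbscissa", "G2Curve", function(x) x@tauGrid)
#' @rdname curveValues
#' @export
setMethod("curveValues", "G2Curve", function(x) x@values)

setMethod("show", "IRF", function(object) {
  cat(sprintf("IRF: %d bins, FWHM = %.3g ns, peak at %.3g ns\n",
              length(object@tGrid), object@fwhm,
              object@tGrid[which.max(object@values)]))
})

setMethod("show", "DTOFHistogram", function(object) {
  cat(sprintf(
    "DTOFHistogram @ %g nm: %d bins, %.3g total counts, peak %.3g, n_avg %g\n",
    object@wavelength, length(object@tGrid), sum(object@counts),
    max(object@counts), object@nAveraged))
})

setMethod("show", "G2Curve", function(object) {
  cat(sprintf(
    "G2Curve: %d delays on [%.2g, %.2g] s, count rate %.3g kHz, %g ch, %g s\n",
    length(object@tauGrid), object@tauGrid[1L],
    object@tauGrid[length(object@tauGrid)], object@countRate,
    object@nChannels, object@duration))
})
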