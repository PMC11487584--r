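#' @import methods
#' @importFrom stats approx convolve optimize rnorm rpois runif sd setNames uniroot
#' @importFrom utils read.csv write.csv
NULL

#' Abscissa of a curve object
#'
#' Returns the ordered grid a curve is sampled on: photon arrival time in
#' nanoseconds for DTOF/IRF objects, correlation delay time in seconds for
#' g1/g2 objects.
#'
#' @param x a curve object (\linkS4class{ModelCurve}, \linkS4class{IRF},
#'   \linkS4class{DTOFHistogram} or \linkS4class{G2Curve}).
#' @return numeric vector, strictly increasing.
#' @export
setGeneric("curveAbscissa", function(x) standardGeneric("curveAbscissa"))

#' Ordinate values of a curve object
#'
#' @param x a curve object.
#' @return numeric vector of amplitudes, counts, or correlation values.
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' Absorption coefficient accessor (1/cm)
#' @param x an object carrying an absorption coefficient.
#' @return numeric scalar, 1/cm.
#' @export
setGeneric("mua", function(x) standardGeneric("mua"))

#' Reduced scattering coefficient accessor (1/cm)
#' @param x an object carrying a reduced scattering coefficient.
#' @return numeric scalar, 1/cm.
#' @export
setGeneric("musp", function(x) standardGeneric("musp"))

#' Blood-flow index accessor (cm^2/s)
#' @param x an object carrying a blood-flow index.
#' @return numeric scalar, cm^2/s.
#' @export
setGeneric("bfi", function(x) standardGeneric("bfi"))

#' Coherence (Siegert beta) parameter accessor
#' @param x an object carrying a fitted or configured beta.
#' @return numeric scalar in (0, 1].
#' @export
setGeneric("coherenceBeta", function(x) standardGeneric("coherenceBeta"))

#' Pointwise average of repeated curve acquisitions
#'
#' Averages repeated acquisitions of the same measurement: DTOF histograms are
#' averaged count-by-count and their acquisition counters summed; g2 curves are
#' averaged point-by-point and their channel counters summed. All curves must
#' share the same grid.
#'
#' @param curves a list of \linkS4class{DTOFHistogram} or all
#'   \linkS4class{G2Curve} objects on identical grids.
#' @return a single object of the same class as the inputs.
#' @export
setGeneric("averageCurves", function(curves) standardGeneric("averageCurves"))

#' Normalize a curve to unit maximum
#'
#' Divides the curve by its maximum, the convention used to display DTOFs.
#' The shape (all pointwise ratios) is unchanged.
#'
#' @param x a curve object with a strictly positive maximum.
#' @return the same class of object with maximum value 1.
#' @export
setGeneric("normalizeToPeak", function(x) standardGeneric("normalizeToPeak"))

#' Full width at half maximum of a peaked curve
#'
#' Width between the two half-maximum crossings, found by linear interpolation
#' between samples. The curve must rise above and fall below half of its
#' maximum on both sides; otherwise the width is undefined and an error of
#' class \code{"diffuseQC_width_error"} is raised.
#'
#' @param x a curve object or numeric vector of ordinates (with \code{abscissa}).
#' @param ... further arguments for methods.
#' @return width in the units of the abscissa.
#' @export
setGeneric("fwhm", function(x, ...) standardGeneric("fwhm"))
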