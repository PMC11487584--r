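#' Optical properties of a homogeneous medium
#'
#' Absorption coefficient \eqn{\mu_a} and reduced scattering coefficient
#' \eqn{\mu_s'} (both 1/cm) of a tissue-like medium at a given wavelength.
#' The photon-diffusion models used throughout assume a weakly absorbing,
#' highly scattering medium (\eqn{\mu_s' \gg \mu_a}); when \eqn{\mu_s' \le
#' \mu_a} the object is still constructed but \code{diffusionValid} is FALSE
#' and downstream forward models attach a warning.
#'
#' @slot mua absorption coefficient (1/cm), > 0.
#' @slot musp reduced scattering coefficient (1/cm), > 0.
#' @slot wavelength light wavelength (nm), > 0. The device emulated here uses
#'   687 and 830 nm for TRS and 785 nm for DCS.
#' @export
setClass("OpticalProperties",
  representation(mua = "numeric", musp = "numeric", wavelength = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mua) != 1L || !is.finite(object@mua) || object@mua <= 0)
      msg <- c(msg, "'mua' must be a single positive finite number (1/cm)")
    if (length(object@musp) != 1L || !is.finite(object@musp) || object@musp <= 0)
      msg <- c(msg, "'musp' must be a single positive finite number (1/cm)")
    if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
        object@wavelength <= 0)
      msg <- c(msg, "'wavelength' must be a single positive number (nm)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct optical properties
#'
#' @param mua absorption coefficient (1/cm).
#' @param musp reduced scattering coefficient (1/cm).
#' @param wavelength wavelength (nm); defaults to 785 (the DCS source).
#' @return an \linkS4class{OpticalProperties} object.
#' @examples
#' opticalProperties(mua = 0.14, musp = 11, wavelength = 687)
#' @export
opticalProperties <- function(mua, musp, wavelength = 785) {
  new("OpticalProperties", mua = as.numeric(mua), musp = as.numeric(musp),
      wavelength = as.numeric(wavelength))
}

#' Is the diffusion approximation plausible for these properties?
#' @param props an \linkS4class{OpticalProperties} object.
#' @return logical; FALSE when scattering does not dominate absorption.
#' @export
diffusionValid <- function(props) props@musp > props@mua

#' Source-detector probe geometry
#'
#' @slot rho source-detector separation on the tissue surface (cm).
#' @slot nTissue refractive index of the tissue (>= 1).
#' @slot nOutside refractive index of the external medium.
#' @export
setClass("ProbeGeometry",
  representation(rho = "numeric", nTissue = "numeric", nOutside = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rho) != 1L || !is.finite(object@rho) || object@rho <= 0)
      msg <- c(msg, "'rho' must be a single positive number (cm)")
    if (length(object@nTissue) != 1L || object@nTissue < 1)
      msg <- c(msg, "'nTissue' must be >= 1")
    if (length(object@nOutside) != 1L || object@nOutside <= 0)
      msg <- c(msg, "'nOutside' must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a probe geometry
#'
#' Defaults reflect the emulated device: a 30 mm (3.0 cm) separation for TRS.
#' For DCS use \code{rho = 2.5}. Tissue refractive index defaults to 1.4,
#' external medium to air.
#'
#' @param rho source-detector separation (cm).
#' @param nTissue tissue refractive index.
#' @param nOutside external refractive index.
#' @return a \linkS4class{ProbeGeometry} object.
#' @export
probeGeometry <- function(rho = 3.0, nTissue = 1.4, nOutside = 1.0) {
  new("ProbeGeometry", rho = as.numeric(rho), nTissue = as.numeric(nTissue),
      nOutside = as.numeric(nOutside))
}

#' Scatterer-dynamics specification for DCS
#'
#' Only Brownian dynamics are implemented: the mean-square displacement of the
#' moving scatterers is \eqn{\langle\Delta r^2(\tau)\rangle = 6 \cdot BFI \cdot
#' \tau}, with the blood-flow index BFI in cm^2/s playing the role of an
#' effective diffusion coefficient of red blood cells.
#'
#' @slot bfi blood-flow index (cm^2/s), >= 0.
#' @slot model dynamics model tag; only \code{"brownian"}.
#' @export
setClass("FlowSpec",
  representation(bfi = "numeric", model = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@bfi) != 1L || !is.finite(object@bfi) || object@bfi < 0)
      msg <- c(msg, "'bfi' must be a single nonnegative number (cm^2/s)")
    if (!identical(object@model, "brownian"))
      msg <- c(msg, "only the 'brownian' dynamics model is implemented")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a flow specification
#' @param bfi blood-flow index (cm^2/s).
#' @param model dynamics model; only \code{"brownian"}.
#' @return a \linkS4class{FlowSpec} object.
#' @export
flowSpec <- function(bfi, model = "brownian") {
  new("FlowSpec", bfi = as.numeric(bfi), model = model)
}

.curve_kinds <- c("reflectance", "g1", "g2")

#' A noise-free model curve
#'
#' A sampled forward-model curve: TRS reflectance vs. time of flight (ns), or
#' a field (g1) / intensity (g2) autocorrelation vs. delay time (s).
#'
#' @slot abscissa strictly increasing grid (ns for reflectance, s for g1/g2).
#' @slot values finite nonnegative model values; for \code{kind = "g1"} values
#'   lie in [0, 1] with value 1 at the first grid point.
#' @slot kind one of \code{"reflectance"}, \code{"g1"}, \code{"g2"}.
#' @export
setClass("ModelCurve",
  representation(abscissa = "numeric", values = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@abscissa) < 2L || any(diff(object@abscissa) <= 0))
      msg <- c(msg, "'abscissa' must be strictly increasing with >= 2 points")
    if (length(object@values) != length(object@abscissa))
      msg <- c(msg, "'values' and 'abscissa' lengths differ")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "'values' must all be finite")
    if (!(length(object@kind) == 1L && object@kind %in% .curve_kinds))
      msg <- c(msg, "'kind' must be one of reflectance/g1/g2")
    if (identical(object@kind, "g1") && length(object@values) &&
        all(is.finite(object@values))) {
      if (length(object@abscissa) && object@abscissa[1L] == 0 &&
          abs(object@values[1L] - 1) > 1e-9)
        msg <- c(msg, "g1 curve must equal 1 at zero delay")
      if (any(object@values < -1e-12) || any(object@values > 1 + 1e-9))
        msg <- c(msg, "g1 values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a model curve
#' @param abscissa strictly increasing grid.
#' @param values curve values.
#' @param kind curve kind tag.
#' @return a \linkS4class{ModelCurve}.
#' @export
modelCurve <- function(abscissa, values, kind) {
  new("ModelCurve", abscissa = as.numeric(abscissa),
      values = as.numeric(values), kind = kind)
}

#' @rdname curveAbscissa
#' @export
setMethod("curveAbscissa", "ModelCurve", function(x) x@abscissa)

#' @rdname curveValues
#' @export
setMethod("curveValues", "ModelCurve", function(x) x@values)

#' @rdname mua
#' @export
setMethod("mua", "OpticalProperties", function(x) x@mua)

#' @rdname musp
#' @export
setMethod("musp", "OpticalProperties", function(x) x@musp)

#' @rdname bfi
#' @export
setMethod("bfi", "FlowSpec", function(x) x@bfi)

setMethod("show", "OpticalProperties", function(object) {
  cat(sprintf("OpticalProperties: mua = %.4g 1/cm, musp = %.4g 1/cm @ %g nm%s\n",
              object@mua, object@musp, object@wavelength,
              if (diffusionValid(object)) "" else " [diffusion regime invalid]"))
})

setMethod("show", "ProbeGeometry", function(object) {
  cat(sprintf("ProbeGeometry: rho = %.3g cm, n = %.3g / %.3g (tissue/outside)\n",
              object@rho, object@nTissue, object@nOutside))
})

setMethod("show", "FlowSpec", function(object) {
  cat(sprintf("FlowSpec (%s): BFI = %.3g cm^2/s\n", object@model, object@bfi))
})

setMethod("show", "ModelCurve", function(object) {
  cat(sprintf("ModelCurve <%s>: %d points on [%.3g, %.3g], range [%.3g, %.3g]\n",
              object@kind, length(object@abscissa), object@abscissa[1L],
              object@abscissa[length(object@abscissa)],
              min(object@values), max(object@values)))
})
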