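# speed of light in vacuum, cm/ns
.c_cm_ns <- 29.9792458

# Effective reflection coefficient for the tissue/outside refractive-index
# mismatch (polynomial approximation in the relative index), and the
# extrapolated-boundary coefficient A = (1 + Reff) / (1 - Reff).
.reff <- function(nrel) -1.440 / nrel^2 + 0.710 / nrel + 0.668 + 0.0636 * nrel

.boundaryA <- function(geom) {
  nrel <- geom@nTissue / geom@nOutside
  if (nrel <= 1) return(1)  # matched boundary
  r <- .reff(nrel)
  (1 + r) / (1 - r)
}

#' Derived diffusion-theory constants
#'
#' Deterministic quantities derived from optical properties and probe
#' geometry: the photon diffusion coefficient D = 1/(3 mu_s') (cm), the
#' isotropic source depth z0 = 1/mu_s' (cm), the extrapolated-boundary
#' distance zb = 2 A D (cm) with A the internal-reflection boundary
#' coefficient for the refractive-index mismatch, the speed of light in the
#' medium v = c/n (cm/ns), and the in-medium optical wavenumber
#' k0 = 2 pi n / lambda (1/cm).
#'
#' @param props an \linkS4class{OpticalProperties} object.
#' @param geom a \linkS4class{ProbeGeometry} object.
#' @return a named list with elements \code{D}, \code{z0}, \code{zb},
#'   \code{v}, \code{k0}, \code{A}, \code{r1}, \code{rb} (the source and
#'   image-source distances to the detector, cm).
#' @export
diffusionConstants <- function(props, geom) {
  stopifnot(is(props, "OpticalProperties"), is(geom, "ProbeGeometry"))
  D <- 1 / (3 * props@musp)
  z0 <- 1 / props@musp
  A <- .boundaryA(geom)
  zb <- 2 * A * D
  v <- .c_cm_ns / geom@nTissue
  k0 <- 2 * pi * geom@nTissue / (props@wavelength * 1e-7)  # nm -> cm
  r1 <- sqrt(geom@rho^2 + z0^2)
  rb <- sqrt(geom@rho^2 + (z0 + 2 * zb)^2)
  list(D = D, z0 = z0, zb = zb, v = v, k0 = k0, A = A, r1 = r1, rb = rb)
}

#' Correlation decay wavenumber K(tau)
#'
#' \eqn{K(\tau)^2 = 3 \mu_a \mu_s' + \mu_s'^2 k_0^2 \langle\Delta
#' r^2(\tau)\rangle}, with Brownian scatterer dynamics
#' \eqn{\langle\Delta r^2(\tau)\rangle = 6 \cdot BFI \cdot \tau}.
#'
#' @param tau delay times (s), >= 0.
#' @param props \linkS4class{OpticalProperties}.
#' @param flow \linkS4class{FlowSpec}.
#' @param geom \linkS4class{ProbeGeometry}.
#' @return numeric vector K(tau) in 1/cm.
#' @export
correlationWavenumber <- function(tau, props, flow, geom) {
  stopifnot(is(flow, "FlowSpec"))
  dc <- diffusionConstants(props, geom)
  msd <- 6 * flow@bfi * tau
  sqrt(3 * props@mua * props@musp + props@musp^2 * dc$k0^2 * msd)
}
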