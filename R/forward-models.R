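#' Time-resolved reflectance of a semi-infinite homogeneous medium
#'
#' Closed-form extrapolated-boundary (image-source) solution of the photon
#' diffusion equation for reflectance at source-detector separation rho on a
#' semi-infinite medium:
#' \deqn{R(\rho, t) \propto t^{-5/2} \exp(-\mu_a v t - \rho^2 / (4 D v t))
#'   [z_0 e^{-z_0^2/(4 D v t)} + (z_0 + 2 z_b) e^{-(z_0+2z_b)^2/(4 D v t)}]}
#' The absolute amplitude is a free scale (fits carry their own scale factor),
#' so the returned curve is unnormalized. Absorption enters only through the
#' Beer-Lambert factor \eqn{e^{-\mu_a v t}}.
#'
#' @param tGrid time grid in ns, all > 0, strictly increasing.
#' @param props \linkS4class{OpticalProperties}.
#' @param geom \linkS4class{ProbeGeometry}; default 3.0 cm TRS separation.
#' @return a \linkS4class{ModelCurve} of kind \code{"reflectance"}. When
#'   scattering does not dominate absorption a diffusion-validity warning is
#'   emitted.
#' @examples
#' t <- seq(0.01, 10, by = 0.01)
#' r <- trsReflectance(t, opticalProperties(0.1, 10, 687))
#' @export
trsReflectance <- function(tGrid, props, geom = probeGeometry()) {
  stopifnot(is(props, "OpticalProperties"), is(geom, "ProbeGeometry"))
  tGrid <- as.numeric(tGrid)
  if (any(tGrid <= 0)) stop("'tGrid' must be strictly positive (ns)")
  if (any(diff(tGrid) <= 0)) stop("'tGrid' must be strictly increasing")
  dc <- diffusionConstants(props, geom)
  warn <- !diffusionValid(props)
  if (warn)
    warning("diffusion-regime validity: musp <= mua; the semi-infinite ",
            "diffusion solution may not describe this medium")
  u <- 4 * dc$D * dc$v * tGrid
  vals <- tGrid^(-2.5) * exp(-props@mua * dc$v * tGrid - geom@rho^2 / u) *
    (dc$z0 * exp(-dc$z0^2 / u) +
     (dc$z0 + 2 * dc$zb) * exp(-(dc$z0 + 2 * dc$zb)^2 / u))
  vals[!is.finite(vals)] <- 0
  new("ModelCurve", abscissa = tGrid, values = as.numeric(vals),
      kind = "reflectance")
}

#' Normalized field autocorrelation g1 of a semi-infinite medium
#'
#' Correlation-diffusion solution with Brownian scatterer dynamics:
#' \deqn{G_1(\tau) \propto e^{-K(\tau) r_1}/r_1 - e^{-K(\tau) r_b}/r_b}
#' with \eqn{r_1 = \sqrt{\rho^2 + z_0^2}}, \eqn{r_b = \sqrt{\rho^2 +
#' (z_0 + 2 z_b)^2}}, normalized so that \eqn{g_1(\tau) = G_1(\tau)/G_1(0)}.
#' With BFI = 0 the decay wavenumber is independent of tau and g1 is
#' identically 1.
#'
#' @param tauGrid delay times in s, >= 0, strictly increasing.
#' @param props \linkS4class{OpticalProperties} (wavelength is the DCS source,
#'   785 nm by default in the presets).
#' @param flow \linkS4class{FlowSpec}.
#' @param geom \linkS4class{ProbeGeometry}; use rho = 2.5 cm for the DCS
#'   channel of the emulated device.
#' @return a \linkS4class{ModelCurve} of kind \code{"g1"}.
#' @examples
#' tau <- c(0, 10^seq(-7, -2, length.out = 50))
#' g1 <- dcsG1(tau, opticalProperties(0.1, 10, 785), flowSpec(1e-8),
#'             probeGeometry(rho = 2.5, nTissue = 1.37))
#' @export
dcsG1 <- function(tauGrid, props, flow, geom = probeGeometry(rho = 2.5)) {
  stopifnot(is(props, "OpticalProperties"), is(flow, "FlowSpec"),
            is(geom, "ProbeGeometry"))
  tauGrid <- as.numeric(tauGrid)
  if (any(tauGrid < 0)) stop("delay times must be nonnegative")
  if (any(diff(tauGrid) <= 0)) stop("'tauGrid' must be strictly increasing")
  dc <- diffusionConstants(props, geom)
  K <- correlationWavenumber(tauGrid, props, flow, geom)
  G1 <- exp(-K * dc$r1) / dc$r1 - exp(-K * dc$rb) / dc$rb
  K0 <- sqrt(3 * props@mua * props@musp)
  G10 <- exp(-K0 * dc$r1) / dc$r1 - exp(-K0 * dc$rb) / dc$rb
  vals <- pmin(pmax(G1 / G10, 0), 1)
  # grid may not include tau = 0; normalization is to G1(0) regardless
  new("ModelCurve", abscissa = tauGrid, values = as.numeric(vals), kind = "g1")
}

#' Siegert relation: intensity from field autocorrelation
#'
#' \eqn{g_2(\tau) = 1 + \beta |g_1(\tau)|^2}, with the coherence parameter
#' beta in (0, 1] (near 0.5 for unpolarized detection in this device class).
#'
#' @param g1 a \linkS4class{ModelCurve} of kind \code{"g1"}.
#' @param beta coherence parameter, 0 < beta <= 1.
#' @return a \linkS4class{ModelCurve} of kind \code{"g2"} with values in
#'   [1, 1 + beta].
#' @examples
#' tau <- c(0, 10^seq(-7, -2, length.out = 50))
#' g1 <- dcsG1(tau, opticalProperties(0.1, 10, 785), flowSpec(1e-8),
#'             probeGeometry(rho = 2.5))
#' g2 <- siegertG2(g1, beta = 0.49)
#' @export
siegertG2 <- function(g1, beta) {
  stopifnot(is(g1, "ModelCurve"))
  if (!identical(g1@kind, "g1")) stop("'g1' must be a curve of kind 'g1'")
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0 || beta > 1)
    stop("'beta' must lie in (0, 1]")
  new("ModelCurve", abscissa = g1@abscissa,
      values = 1 + beta * abs(g1@values)^2, kind = "g2")
}

#' Intensity-weighted mixture of field autocorrelation curves
#'
#' Mimics a heterogeneous probed volume (e.g., a shallow low-flow hematoma
#' over perfused cortex) as a convex combination of homogeneous g1 curves:
#' \eqn{g_{1,mix}(\tau) = \sum_i w_i g_{1,i}(\tau)} with nonnegative weights
#' summing to 1. A slow component produces the characteristic secondary decay
#' and a non-zero tail plateau.
#'
#' @param components a list of \code{list(curve = <ModelCurve g1>, weight =
#'   <numeric>)} entries, all on the same delay grid.
#' @return a \linkS4class{ModelCurve} of kind \code{"g1"}.
#' @examples
#' tau <- c(0, 10^seq(-7, -2, length.out = 50))
#' p <- opticalProperties(0.1, 10, 785); g <- probeGeometry(rho = 2.5)
#' fast <- dcsG1(tau, p, flowSpec(1e-8), g)
#' slow <- dcsG1(tau, p, flowSpec(1e-10), g)
#' mixed <- mixG1(list(list(curve = fast, weight = 0.75),
#'                     list(curve = slow, weight = 0.25)))
#' @export
mixG1 <- function(components) {
  if (!length(components)) stop("need at least one component")
  curves <- lapply(components, `[[`, "curve")
  weights <- vapply(components, function(x) as.numeric(x[["weight"]]),
                    numeric(1))
  if (any(!vapply(curves, function(cu) is(cu, "ModelCurve") &&
                  identical(cu@kind, "g1"), logical(1))))
    stop("all components must be ModelCurve objects of kind 'g1'")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  grid <- curves[[1L]]@abscissa
  for (cu in curves[-1L])
    if (length(cu@abscissa) != length(grid) ||
        max(abs(cu@abscissa - grid)) > 0)
      stop("component curves must share the same delay grid")
  vals <- Reduce(`+`, Map(function(cu, w) w * cu@values, curves,
                          as.list(weights)))
  new("ModelCurve", abscissa = grid, values = as.numeric(vals), kind = "g1")
}
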