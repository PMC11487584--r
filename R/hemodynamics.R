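#' Molar extinction coefficients of hemoglobin
#'
#' Loads the packaged extinction-coefficient table (a versioned snapshot of a
#' standard literature compilation; units 1/(cm * mol/L), decadic). The table
#' must contain both device wavelengths (687 and 830 nm).
#'
#' @param path optional path to a CSV with columns \code{wavelength_nm},
#'   \code{eps_hbo2}, \code{eps_hhb}; default is the packaged table.
#' @return a data.frame with one row per wavelength.
#' @export
extinctionTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_hemoglobin.csv",
                        package = "diffuseQC", mustWork = TRUE)
  tab <- read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "eps_hbo2", "eps_hhb")
  if (!all(need %in% names(tab)))
    stop("extinction table must have columns ", paste(need, collapse = ", "))
  if (any(tab$eps_hbo2 <= 0) || any(tab$eps_hhb <= 0))
    stop("extinction coefficients must be positive")
  tab
}

.eps_at <- function(eps, wl) {
  i <- which(eps$wavelength_nm == wl)
  if (!length(i))
    stop("extinction table has no entry for ", wl, " nm")
  eps[i[1L], ]
}

#' Hemoglobin concentrations and StO2 from two-wavelength absorption
#'
#' Solves the 2x2 linear system
#' \deqn{\mu_a(\lambda) = \ln(10) [\epsilon_{HbO2}(\lambda) C_{HbO2} +
#'   \epsilon_{HHb}(\lambda) C_{HHb}]}
#' for the oxy- and deoxyhemoglobin concentrations at the two TRS wavelengths
#' and derives total hemoglobin and the oxygen saturation
#' StO2 = 100 * C_HbO2 / (C_HbO2 + C_HHb). Water and lipid chromophores are
#' not modeled. Negative concentrations are reported as-is with
#' \code{physical = FALSE}, never silently clipped.
#'
#' @param fit687 converged \linkS4class{TRSFit} at 687 nm (or any object with
#'   a \code{mua()} accessor; a bare numeric mu_a is also accepted).
#' @param fit830 converged \linkS4class{TRSFit} at 830 nm (or numeric mu_a).
#' @param eps extinction table (see \code{\link{extinctionTable}}).
#' @param wavelengths the two wavelengths (nm) to look up, in the same order
#'   as the fits.
#' @return a \linkS4class{Hemodynamics} object.
#' @examples
#' computeHemodynamics(0.14, 0.1406)
#' @export
computeHemodynamics <- function(fit687, fit830, eps = extinctionTable(),
                                wavelengths = c(687, 830)) {
  getMua <- function(f, what) {
    if (is.numeric(f)) return(as.numeric(f))
    if (is(f, "TRSFit")) {
      if (!isTRUE(f@converged))
        stop("cannot derive hemodynamics: ", what, " fit did not converge")
      return(f@mua)
    }
    stop("'", what, "' must be a TRSFit or a numeric mu_a")
  }
  muaV <- c(getMua(fit687, "687 nm"), getMua(fit830, "830 nm"))
  e1 <- .eps_at(eps, wavelengths[1L])
  e2 <- .eps_at(eps, wavelengths[2L])
  E <- rbind(c(e1$eps_hbo2, e1$eps_hhb),
             c(e2$eps_hbo2, e2$eps_hhb))
  if (abs(det(E)) < 1e-12 * prod(pmax(abs(E[, 1]), abs(E[, 2]))))
    stop("configuration error: extinction matrix is singular")
  conc <- solve(E, muaV / log(10))
  thc <- sum(conc)
  sto2 <- 100 * conc[1L] / thc
  new("Hemodynamics", cHbO2 = conc[1L], cHHb = conc[2L], thc = thc,
      sto2 = sto2, physical = all(conc >= 0))
}
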