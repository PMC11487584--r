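# Width between half-maximum crossings, linearly interpolated.
.fwhm_core <- function(x, y) {
  if (length(x) != length(y)) stop("abscissa/values length mismatch")
  ipk <- which.max(y)
  pk <- y[ipk]
  if (pk <= 0) stop("curve must have a positive maximum")
  half <- pk / 2
  left <- which(y[seq_len(ipk)] < half)
  right <- which(y[seq.int(ipk, length(y))] < half)
  if (!length(left) || !length(right))
    stop(errorCondition(
      "undefined width: curve never drops below half maximum on both sides",
      class = "diffuseQC_width_error"))
  iL <- max(left)            # last sub-half sample before the peak
  xL <- x[iL] + (half - y[iL]) / (y[iL + 1L] - y[iL]) * (x[iL + 1L] - x[iL])
  iR <- ipk + min(right) - 1L  # first sub-half sample after the peak
  xR <- x[iR - 1L] +
    (half - y[iR - 1L]) / (y[iR] - y[iR - 1L]) * (x[iR] - x[iR - 1L])
  xR - xL
}

#' @rdname fwhm
#' @param abscissa grid for the numeric method.
#' @export
setMethod("fwhm", "numeric", function(x, abscissa, ...) {
  .fwhm_core(abscissa, x)
})

#' @rdname fwhm
#' @export
setMethod("fwhm", "ModelCurve", function(x, ...) .fwhm_core(x@abscissa, x@values))

#' @rdname fwhm
#' @export
setMethod("fwhm", "IRF", function(x, ...) .fwhm_core(x@tGrid, x@values))

#' @rdname fwhm
#' @export
setMethod("fwhm", "DTOFHistogram", function(x, ...) .fwhm_core(x@tGrid, x@counts))

#' TRS figures of merit
#'
#' Computes the TRS quality metrics of a DTOF/IRF pair: the two FWHMs, their
#' ratio (rFWHM) and difference (dFWHM), the SNR (DTOF peak over the standard
#' deviation of the pre-pulse background), the dynamic range in decades
#' (log10 of peak over mean background, floored at 1 count), and the delay of
#' the DTOF peak from the IRF peak. The background window is every bin
#' earlier than (IRF peak - 5 * IRF FWHM) and must hold at least 20 bins.
#'
#' @param dtof a \linkS4class{DTOFHistogram}.
#' @param irf the matching \linkS4class{IRF}.
#' @param minBackgroundBins minimum pre-pulse bins (default 20).
#' @return a \linkS4class{QCMetrics} with the TRS fields filled.
#' @export
trsQCMetrics <- function(dtof, irf, minBackgroundBins = 20L) {
  stopifnot(is(dtof, "DTOFHistogram"), is(irf, "IRF"))
  if (!.same_grid_tol(dtof@tGrid, irf@tGrid))
    stop("DTOF and IRF must share the same time grid")
  bgIdx <- .background_window(dtof@tGrid, irf)
  if (length(bgIdx) < minBackgroundBins)
    stop(errorCondition(
      sprintf("configuration error: pre-pulse background window holds %d bins (need >= %d); move the IRF peak later or widen the grid",
              length(bgIdx), minBackgroundBins),
      class = "diffuseQC_config_error"))
  bgSd <- sd(dtof@counts[bgIdx])
  # a numerically-zero background (noiseless simulation) has no meaningful
  # noise floor: SNR would be effectively infinite
  if (!is.finite(bgSd) || bgSd < 1e-9 * max(dtof@counts))
    stop(errorCondition(
      "configuration error: background standard deviation is zero (noiseless curve); SNR is undefined",
      class = "diffuseQC_config_error"))
  fD <- fwhm(dtof)
  fI <- fwhm(irf)
  qcMetrics(
    fwhmDtof = fD, fwhmIrf = fI, rfwhm = fD / fI, dfwhm = fD - fI,
    snr = max(dtof@counts) / bgSd,
    dynamicRange = .dynamic_range(dtof@counts, bgIdx),
    peakDelay = dtof@tGrid[which.max(dtof@counts)] -
      irf@tGrid[which.max(irf@values)])
}

#' DCS figures of merit
#'
#' Fills the DCS quality metrics: count rate, fitted beta and BFI, the fit
#' residual, and the tail plateau (the measured g1 interpolated at tau =
#' \code{plateauTau}, default 1e-3 s, where a homogeneous healthy curve has
#' long since decayed to zero). Fields without data are NA; a missing or
#' refused fit sets \code{fitRefused}.
#'
#' @param g2 a \linkS4class{G2Curve}.
#' @param fit the \linkS4class{DCSFit} for this curve, or NULL when the fit
#'   was refused/failed.
#' @param secondaryDecay logical: was a secondary slow decay detected
#'   (see \code{\link{detectSecondaryDecay}}); NA when not assessed.
#' @param plateauTau delay at which the tail plateau is read (s).
#' @return a \linkS4class{QCMetrics} with the DCS fields filled.
#' @export
dcsQCMetrics <- function(g2, fit = NULL, secondaryDecay = NA,
                         plateauTau = 1e-3) {
  stopifnot(is(g2, "G2Curve"))
  beta <- if (!is.null(fit)) fit@beta else
    tryCatch(estimateBeta(g2), error = function(e) NA_real_)
  tail <- NA_real_
  if (is.finite(beta) && beta > 0) {
    g1meas <- sqrt(pmax(g2@values - 1, 0) / beta)
    if (plateauTau >= g2@tauGrid[1L] &&
        plateauTau <= g2@tauGrid[length(g2@tauGrid)])
      tail <- approx(g2@tauGrid, g1meas, xout = plateauTau)$y
  }
  qcMetrics(
    countRate = g2@countRate,
    beta = beta,
    bfi = if (!is.null(fit) && isTRUE(fit@converged)) fit@bfi else NA_real_,
    residualNorm = if (!is.null(fit) && isTRUE(fit@converged)) fit@residual
                   else NA_real_,
    tailPlateau = tail,
    fitRefused = is.null(fit) || !isTRUE(fit@converged),
    secondaryDecay = secondaryDecay)
}

#' Merge two QCMetrics containers
#'
#' Combines (typically) a TRS metrics object and a DCS metrics object into
#' one; non-NA fields must not conflict.
#'
#' @param a,b \linkS4class{QCMetrics} objects.
#' @return a merged \linkS4class{QCMetrics}.
#' @export
mergeQCMetrics <- function(a, b) {
  stopifnot(is(a, "QCMetrics"), is(b, "QCMetrics"))
  out <- a
  for (s in slotNames("QCMetrics")) {
    va <- slot(a, s); vb <- slot(b, s)
    if (is.na(va) && !is.na(vb)) slot(out, s) <- vb
  }
  out
}
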