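#' Result of a TRS (DTOF) model fit
#'
#' @slot mua fitted absorption coefficient (1/cm).
#' @slot musp fitted reduced scattering coefficient (1/cm).
#' @slot scale free amplitude multiplying the convolved model.
#' @slot fitRange time window actually fitted, c(t_start, t_end) in ns.
#' @slot residual normalized sum of squared (Poisson-weighted) residuals.
#' @slot converged logical.
#' @export
setClass("TRSFit",
  representation(mua = "numeric", musp = "numeric", scale = "numeric",
                 fitRange = "numeric", residual = "numeric",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@fitRange) != 2L)
      msg <- c(msg, "'fitRange' must have length 2")
    if (length(object@residual) == 1L && is.finite(object@residual) &&
        object@residual < 0)
      msg <- c(msg, "'residual' must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Result of a DCS (g2) model fit
#'
#' The fit first estimates the coherence parameter beta from the early-delay
#' plateau, converts g2 to g1 via the Siegert relation, and then fits the
#' semi-infinite correlation-diffusion model to the points with g1 at or above
#' \code{cutoffValue} (default 0.3).
#'
#' @slot bfi fitted blood-flow index (cm^2/s).
#' @slot beta fitted coherence parameter.
#' @slot residual root-mean-square residual in g1 units over the fitted points.
#' @slot cutoffValue g1 level below which points are excluded from the fit.
#' @slot converged logical.
#' @slot reliabilityFlag character vector of reliability annotations; empty
#'   when nothing is suspicious. \code{"unreliable"} marks a BFI below the
#'   ergodicity bound 3e-10 cm^2/s; \code{"poor model agreement"} marks a
#'   residual inconsistent with a homogeneous medium.
#' @export
setClass("DCSFit",
  representation(bfi = "numeric", beta = "numeric", residual = "numeric",
                 cutoffValue = "numeric", converged = "logical",
                 reliabilityFlag = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@bfi) == 1L && is.finite(object@bfi) && object@bfi < 0)
      msg <- c(msg, "'bfi' must be >= 0")
    if (length(object@cutoffValue) != 1L || object@cutoffValue <= 0 ||
        object@cutoffValue >= 1)
      msg <- c(msg, "'cutoffValue' must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' Hemoglobin concentrations and oxygen saturation
#'
#' Oxy- and deoxyhemoglobin concentrations obtained from the two-wavelength
#' absorption coefficients, with total hemoglobin THC = HbO2 + HHb and
#' StO2 = 100 * HbO2 / THC (percent). Negative concentrations are kept and
#' flagged non-physical rather than clipped.
#'
#' @slot cHbO2 oxyhemoglobin concentration (mol/L).
#' @slot cHHb deoxyhemoglobin concentration (mol/L).
#' @slot thc total hemoglobin concentration (mol/L).
#' @slot sto2 oxygen saturation (percent).
#' @slot physical logical; FALSE when any concentration is negative.
#' @export
setClass("Hemodynamics",
  representation(cHbO2 = "numeric", cHHb = "numeric", thc = "numeric",
                 sto2 = "numeric", physical = "logical"),
  validity = function(object) {
    msg <- character()
    if (abs(object@thc - (object@cHbO2 + object@cHHb)) >
        1e-12 * max(1, abs(object@thc)))
      msg <- c(msg, "'thc' must equal cHbO2 + cHHb")
    if (object@physical && (object@sto2 < -1e-9 || object@sto2 > 100 + 1e-9))
      msg <- c(msg, "'sto2' must lie in [0, 100] for physical concentrations")
    if (length(msg)) msg else TRUE
  }
)

#' Quality-control figures of merit
#'
#' One container for the TRS and DCS figures of merit; fields that do not
#' apply to the available data are NA. TRS fields: the DTOF and IRF full
#' widths at half maximum, their ratio (rFWHM) and difference (dFWHM), the
#' signal-to-noise ratio (DTOF peak over pre-pulse background standard
#' deviation), the dynamic range in decades, and the delay of the DTOF peak
#' from the IRF peak. DCS fields: count rate, fitted beta and BFI, the g1
#' value at 1e-3 s (tail plateau), and the fit residual.
#'
#' @slot fwhmDtof ns.
#' @slot fwhmIrf ns.
#' @slot rfwhm fwhmDtof / fwhmIrf.
#' @slot dfwhm fwhmDtof - fwhmIrf (ns).
#' @slot snr DTOF peak counts / background standard deviation.
#' @slot dynamicRange log10(peak / max(mean background, 1)), decades.
#' @slot peakDelay DTOF peak time minus IRF peak time (ns).
#' @slot countRate kHz.
#' @slot beta Siegert coherence parameter.
#' @slot bfi cm^2/s.
#' @slot tailPlateau measured g1 at tau = 1e-3 s.
#' @slot residualNorm DCS fit residual (rms, g1 units).
#' @slot sto2 percent (from the paired hemodynamic solve, if available).
#' @slot fitRefused TRUE when a model fit was refused or failed outright.
#' @slot secondaryDecay TRUE when a secondary (slow) g1 decay was detected.
#' @export
setClass("QCMetrics",
  representation(fwhmDtof = "numeric", fwhmIrf = "numeric", rfwhm = "numeric",
                 dfwhm = "numeric", snr = "numeric", dynamicRange = "numeric",
                 peakDelay = "numeric", countRate = "numeric", beta = "numeric",
                 bfi = "numeric", tailPlateau = "numeric",
                 residualNorm = "numeric", sto2 = "numeric",
                 fitRefused = "logical", secondaryDecay = "logical"),
  validity = function(object) {
    msg <- character()
    if (is.finite(object@rfwhm) && is.finite(object@fwhmDtof) &&
        is.finite(object@fwhmIrf) &&
        abs(object@rfwhm - object@fwhmDtof / object@fwhmIrf) >
          1e-9 * max(1, object@rfwhm))
      msg <- c(msg, "'rfwhm' must equal fwhmDtof / fwhmIrf")
    if (is.finite(object@dfwhm) && is.finite(object@fwhmDtof) &&
        is.finite(object@fwhmIrf) &&
        abs(object@dfwhm - (object@fwhmDtof - object@fwhmIrf)) > 1e-9)
      msg <- c(msg, "'dfwhm' must equal fwhmDtof - fwhmIrf")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a QCMetrics container (NA for anything unavailable)
#' @param ... named scalar fields matching the \linkS4class{QCMetrics} slots.
#' @return a \linkS4class{QCMetrics} object.
#' @export
qcMetrics <- function(...) {
  args <- list(...)
  slots <- list(fwhmDtof = NA_real_, fwhmIrf = NA_real_, rfwhm = NA_real_,
                dfwhm = NA_real_, snr = NA_real_, dynamicRange = NA_real_,
                peakDelay = NA_real_, countRate = NA_real_, beta = NA_real_,
                bfi = NA_real_, tailPlateau = NA_real_,
                residualNorm = NA_real_, sto2 = NA_real_,
                fitRefused = NA, secondaryDecay = NA)
  bad <- setdiff(names(args), names(slots))
  if (length(bad)) stop("unknown QCMetrics field(s): ", paste(bad, collapse = ", "))
  slots[names(args)] <- args
  do.call(new, c(list("QCMetrics"), slots))
}

#' Quality-control rule set
#'
#' Thresholds operationalizing the measurement guidelines for this class of
#' hybrid device. Hard rules (violations mean the data cannot be analyzed)
#' are the SNR floor, the dynamic-range floor, the count-rate noise floor,
#' and a refused fit. Plausibility rules (values exist but are distrusted)
#' are the beta window, the BFI window and ergodicity bound, the g1 tail
#' plateau, a detected secondary decay, the StO2 window, non-broadened DTOFs
#' (rFWHM <= 1, dFWHM <= 0), a short peak delay, and detector saturation.
#'
#' @slot snrMin SNR floor (default 10).
#' @slot dynamicRangeMin decades (default 3).
#' @slot peakDelayMin ns (default 0.7).
#' @slot rfwhmMin dimensionless (default 1).
#' @slot dfwhmMin ns (default 0).
#' @slot countRateWindow kHz, c(noise floor, saturation) (default c(0.5, 200)).
#' @slot betaWindow dimensionless (default c(0.35, 0.55)).
#' @slot bfiWindow cm^2/s, normal range (default c(1e-9, 8e-8)).
#' @slot bfiUnreliable cm^2/s, ergodicity bound (default 3e-10).
#' @slot tailPlateauMax g1 units (default 0.05).
#' @slot sto2Window percent (default c(50, 75)).
#' @export
setClass("QCRuleSet",
  representation(snrMin = "numeric", dynamicRangeMin = "numeric",
                 peakDelayMin = "numeric", rfwhmMin = "numeric",
                 dfwhmMin = "numeric", countRateWindow = "numeric",
                 betaWindow = "numeric", bfiWindow = "numeric",
                 bfiUnreliable = "numeric", tailPlateauMax = "numeric",
                 sto2Window = "numeric"),
  validity = function(object) {
    msg <- character()
    for (w in c("countRateWindow", "betaWindow", "bfiWindow", "sto2Window")) {
      v <- slot(object, w)
      if (length(v) != 2L || v[1L] >= v[2L])
        msg <- c(msg, sprintf("'%s' must be an increasing pair", w))
    }
    for (s in c("snrMin", "dynamicRangeMin", "peakDelayMin", "rfwhmMin",
                "bfiUnreliable", "tailPlateauMax")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a positive scalar", s))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Default quality-control rules
#' @return a \linkS4class{QCRuleSet} with the package defaults.
#' @export
defaultQCRules <- function() {
  new("QCRuleSet", snrMin = 10, dynamicRangeMin = 3, peakDelayMin = 0.7,
      rfwhmMin = 1, dfwhmMin = 0, countRateWindow = c(0.5, 200),
      betaWindow = c(0.35, 0.55), bfiWindow = c(1e-9, 8e-8),
      bfiUnreliable = 3e-10, tailPlateauMax = 0.05, sto2Window = c(50, 75))
}

#' Trustworthiness verdict
#'
#' @slot label \code{"acceptable"}, \code{"suspect"} or \code{"reject"}.
#' @slot reasons a data.frame with columns \code{rule} (identifier),
#'   \code{observed} (value as character), \code{bound} (threshold as
#'   character), \code{severity} ("hard" or "plausibility"); zero rows iff
#'   the label is acceptable.
#' @export
setClass("QCVerdict",
  representation(label = "character", reasons = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!(length(object@label) == 1L &&
          object@label %in% c("acceptable", "suspect", "reject")))
      msg <- c(msg, "'label' must be acceptable/suspect/reject")
    if (!all(c("rule", "observed", "bound", "severity") %in%
             names(object@reasons)))
      msg <- c(msg, "'reasons' must have rule/observed/bound/severity columns")
    else {
      if (identical(object@label, "acceptable") && nrow(object@reasons) > 0L)
        msg <- c(msg, "acceptable verdict must carry no reasons")
      if (!identical(object@label, "acceptable") && nrow(object@reasons) == 0L)
        msg <- c(msg, "non-acceptable verdict must carry reasons")
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname mua
#' @export
setMethod("mua", "TRSFit", function(x) x@mua)
#' @rdname musp
#' @export
setMethod("musp", "TRSFit", function(x) x@musp)
#' @rdname bfi
#' @export
setMethod("bfi", "DCSFit", function(x) x@bfi)
#' @rdname coherenceBeta
#' @export
setMethod("coherenceBeta", "DCSFit", function(x) x@beta)
#' @rdname bfi
#' @export
setMethod("bfi", "QCMetrics", function(x) x@bfi)
#' @rdname coherenceBeta
#' @export
setMethod("coherenceBeta", "QCMetrics", function(x) x@beta)

#' Oxygen saturation accessor (percent)
#' @param x a \linkS4class{Hemodynamics} object.
#' @return StO2 in percent.
#' @export
sto2 <- function(x) {
  stopifnot(is(x, "Hemodynamics"))
  x@sto2
}

#' Verdict label accessor
#' @param x a \linkS4class{QCVerdict}.
#' @return character label.
#' @export
verdictLabel <- function(x) {
  stopifnot(is(x, "QCVerdict"))
  x@label
}

#' Verdict reasons accessor
#' @param x a \linkS4class{QCVerdict}.
#' @return data.frame of violated rules.
#' @export
verdictReasons <- function(x) {
  stopifnot(is(x, "QCVerdict"))
  x@reasons
}

setMethod("show", "TRSFit", function(object) {
  if (isTRUE(object@converged))
    cat(sprintf(
      "TRSFit: mua = %.4g 1/cm, musp = %.4g 1/cm, residual %.3g, range [%.2f, %.2f] ns\n",
      object@mua, object@musp, object@residual,
      object@fitRange[1L], object@fitRange[2L]))
  else cat("TRSFit: not converged (no values reported)\n")
})

setMethod("show", "DCSFit", function(object) {
  flags <- if (length(object@reliabilityFlag))
    paste0(" [", paste(object@reliabilityFlag, collapse = "; "), "]") else ""
  if (isTRUE(object@converged))
    cat(sprintf("DCSFit: BFI = %.3g cm^2/s, beta = %.3g, rms residual %.3g%s\n",
                object@bfi, object@beta, object@residual, flags))
  else cat(sprintf("DCSFit: not converged%s\n", flags))
})

setMethod("show", "Hemodynamics", function(object) {
  cat(sprintf(
    "Hemodynamics: HbO2 = %.3g uM, HHb = %.3g uM, THC = %.3g uM, StO2 = %.1f%%%s\n",
    object@cHbO2 * 1e6, object@cHHb * 1e6, object@thc * 1e6, object@sto2,
    if (object@physical) "" else " [non-physical]"))
})

setMethod("show", "QCVerdict", function(object) {
  cat(sprintf("QCVerdict: %s\n", object@label))
  if (nrow(object@reasons))
    for (i in seq_len(nrow(object@reasons)))
      cat(sprintf("  - %s (observed %s, bound %s, %s)\n",
                  object@reasons$rule[i], object@reasons$observed[i],
                  object@reasons$bound[i], object@reasons$severity[i]))
})

setMethod("show", "QCMetrics", function(object) {
  fields <- c("fwhmDtof", "fwhmIrf", "rfwhm", "dfwhm", "snr", "dynamicRange",
              "peakDelay", "countRate", "beta", "bfi", "tailPlateau",
              "residualNorm", "sto2")
  vals <- vapply(fields, function(f) slot(object, f), numeric(1))
  keep <- is.finite(vals)
  cat("QCMetrics:\n")
  if (any(keep))
    cat(paste0("  ", fields[keep], " = ", signif(vals[keep], 4),
               collapse = "\n"), "\n")
})
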