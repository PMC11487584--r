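#' Detect a secondary (slow) decay in a field autocorrelation curve
#'
#' Compares a one-component semi-infinite Brownian fit against a two-component
#' intensity-weighted mixture fit. A secondary decay is declared present when
#' the two-component fit reduces the squared residual by at least
#' \code{improvement} (default 50 percent) AND the recovered slow-component
#' weight is at least \code{minWeight} (default 0.15). On a noiseless
#' single-component curve the one-component residual is already at machine
#' level, so the nested model cannot qualify.
#'
#' @param g1 a \linkS4class{ModelCurve} of kind \code{"g1"} sampled out to at
#'   least 1e-3 s (the decade where heterogeneity-driven plateaus live), or a
#'   list with elements \code{tau} and \code{values} for a measured (noisy)
#'   field-correlation estimate that need not satisfy the exact g1
#'   invariants.
#' @param props \linkS4class{OpticalProperties} at the DCS wavelength.
#' @param geom \linkS4class{ProbeGeometry} (default 2.5 cm separation).
#' @param improvement required relative residual reduction (default 0.5).
#' @param minWeight minimum slow-component weight (default 0.15).
#' @return a list with \code{present} (logical), \code{slowWeight},
#'   \code{slowBfi}, \code{fastBfi}, \code{rss1}, \code{rss2}. A curve with
#'   no decay (g1 never below 0.95) raises an error of class
#'   \code{"diffuseQC_flat_error"} ("no decay to analyze").
#' @export
detectSecondaryDecay <- function(g1, props = opticalProperties(0.1, 10, 785),
                                 geom = probeGeometry(rho = 2.5),
                                 improvement = 0.5, minWeight = 0.15) {
  if (is(g1, "ModelCurve")) {
    if (!identical(g1@kind, "g1")) stop("'g1' must be a curve of kind 'g1'")
    tau <- g1@abscissa
    y <- g1@values
  } else if (is.list(g1) && all(c("tau", "values") %in% names(g1))) {
    tau <- as.numeric(g1$tau)
    y <- as.numeric(g1$values)
  } else stop("'g1' must be a ModelCurve of kind 'g1' or a list(tau, values)")
  if (tau[length(tau)] < 1e-3)
    stop("g1 must be sampled out to at least 1e-3 s")
  if (min(y) > 0.95)
    stop(errorCondition("no decay to analyze: g1 never drops below 0.95",
                        class = "diffuseQC_flat_error"))
  pos <- tau > 0
  tauF <- tau[pos]
  yF <- y[pos]
  one_model <- function(logBfi)
    curveValues(dcsG1(tauF, props, flowSpec(exp(logBfi)), geom))
  f1 <- minpack.lm::nls.lm(par = log(1e-8),
                           fn = function(p) one_model(p[1L]) - yF,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  rss1 <- sum((one_model(f1$par[1L]) - yF)^2)
  two_model <- function(p) {
    w <- 1 / (1 + exp(-p[3L]))  # slow-component weight via logistic
    (1 - w) * one_model(p[1L]) + w * one_model(p[2L])
  }
  f2 <- minpack.lm::nls.lm(par = c(f1$par[1L], f1$par[1L] - log(100),
                                   log(0.25 / 0.75)),
                           fn = function(p) two_model(p) - yF,
                           control = minpack.lm::nls.lm.control(maxiter = 400))
  rss2 <- sum((two_model(f2$par) - yF)^2)
  w <- 1 / (1 + exp(-f2$par[3L]))
  bfis <- exp(f2$par[1:2])
  # identify the slow component as the smaller BFI
  if (bfis[2L] <= bfis[1L]) {
    slowBfi <- bfis[2L]; fastBfi <- bfis[1L]; slowW <- w
  } else {
    slowBfi <- bfis[1L]; fastBfi <- bfis[2L]; slowW <- 1 - w
  }
  floorRss <- 1e-10 * length(yF)  # residuals at machine level carry no signal
  present <- rss1 > floorRss && rss2 <= (1 - improvement) * rss1 &&
    slowW >= minWeight
  list(present = present, slowWeight = slowW, slowBfi = slowBfi,
       fastBfi = fastBfi, rss1 = rss1, rss2 = rss2)
}

.fmt_val <- function(x) {
  if (is.logical(x)) return(as.character(x))
  as.character(signif(x, 4))
}

.reason_row <- function(rule, observed, bound, severity) {
  data.frame(rule = rule, observed = .fmt_val(observed),
             bound = as.character(bound), severity = severity,
             stringsAsFactors = FALSE)
}

#' Classify curve trustworthiness from figures of merit
#'
#' Applies a rule set to the figures of merit of one measurement (TRS, DCS,
#' or both merged). Hard-rule violations (the data cannot be analyzed) yield
#' \code{"reject"}: SNR below the floor, dynamic range below the floor, count
#' rate below the noise level, or a refused/failed fit. Plausibility
#' violations (values exist but should be distrusted) yield
#' \code{"suspect"}: beta outside its window, BFI outside the normal range or
#' below the ergodicity bound, a g1 tail that does not reach zero, a detected
#' secondary decay, StO2 outside its window, a non-broadened DTOF (rFWHM <=
#' 1 or dFWHM <= 0), a short peak delay, or detector saturation. Reject
#' dominates suspect; with no violations the verdict is
#' \code{"acceptable"}. NA metrics are skipped. Every violation is
#' enumerated in the verdict's reasons.
#'
#' @param metrics a \linkS4class{QCMetrics}.
#' @param hemo optional \linkS4class{Hemodynamics} supplying StO2 (overrides
#'   the metrics slot when given).
#' @param rules a \linkS4class{QCRuleSet}.
#' @return a \linkS4class{QCVerdict}.
#' @examples
#' m <- qcMetrics(snr = 5, dynamicRange = 3.2)
#' classifyQC(m)  # reject: snr below 10
#' @export
classifyQC <- function(metrics, hemo = NULL, rules = defaultQCRules()) {
  stopifnot(is(metrics, "QCMetrics"), is(rules, "QCRuleSet"))
  if (!is.na(metrics@snr) && is.infinite(metrics@snr))
    stop(errorCondition(
      "configuration error: SNR is not finite (noiseless background?)",
      class = "diffuseQC_config_error"))
  rs <- list()
  add <- function(row) rs[[length(rs) + 1L]] <<- row
  fin <- function(x) length(x) == 1L && is.finite(x)

  # hard rules
  if (fin(metrics@snr) && metrics@snr < rules@snrMin)
    add(.reason_row("snr below exclusion bound", metrics@snr,
                    paste0(">=", rules@snrMin), "hard"))
  if (fin(metrics@dynamicRange) && metrics@dynamicRange < rules@dynamicRangeMin)
    add(.reason_row("dynamic range below minimum", metrics@dynamicRange,
                    paste0(">=", rules@dynamicRangeMin), "hard"))
  if (fin(metrics@countRate) && metrics@countRate < rules@countRateWindow[1L])
    add(.reason_row("count rate below noise level", metrics@countRate,
                    paste0(">=", rules@countRateWindow[1L]), "hard"))
  if (isTRUE(metrics@fitRefused))
    add(.reason_row("fit refused or failed", TRUE, "converged fit", "hard"))

  # plausibility rules
  if (fin(metrics@countRate) && metrics@countRate > rules@countRateWindow[2L])
    add(.reason_row("count rate above saturation level", metrics@countRate,
                    paste0("<=", rules@countRateWindow[2L]), "plausibility"))
  if (fin(metrics@beta) && (metrics@beta < rules@betaWindow[1L] ||
                            metrics@beta > rules@betaWindow[2L]))
    add(.reason_row("beta outside window", metrics@beta,
                    paste0("[", rules@betaWindow[1L], ", ",
                           rules@betaWindow[2L], "]"), "plausibility"))
  if (fin(metrics@bfi)) {
    if (metrics@bfi < rules@bfiUnreliable)
      add(.reason_row("unreliable BFI (ergodicity bound)", metrics@bfi,
                      paste0(">=", rules@bfiUnreliable), "plausibility"))
    else if (metrics@bfi < rules@bfiWindow[1L] ||
             metrics@bfi > rules@bfiWindow[2L])
      add(.reason_row("BFI outside normal range", metrics@bfi,
                      paste0("[", rules@bfiWindow[1L], ", ",
                             rules@bfiWindow[2L], "]"), "plausibility"))
  }
  if (fin(metrics@tailPlateau) && metrics@tailPlateau > rules@tailPlateauMax)
    add(.reason_row("g1 tail does not reach zero", metrics@tailPlateau,
                    paste0("<=", rules@tailPlateauMax), "plausibility"))
  if (isTRUE(metrics@secondaryDecay))
    add(.reason_row("secondary decay present", TRUE, "single decay",
                    "plausibility"))
  sto2v <- if (!is.null(hemo)) sto2(hemo) else metrics@sto2
  if (fin(sto2v) && (sto2v < rules@sto2Window[1L] ||
                     sto2v > rules@sto2Window[2L]))
    add(.reason_row("StO2 outside plausibility window", sto2v,
                    paste0("[", rules@sto2Window[1L], ", ",
                           rules@sto2Window[2L], "]"), "plausibility"))
  if (fin(metrics@rfwhm) && metrics@rfwhm <= rules@rfwhmMin)
    add(.reason_row("rFWHM not above 1 (no diffusive broadening)",
                    metrics@rfwhm, paste0(">", rules@rfwhmMin),
                    "plausibility"))
  if (fin(metrics@dfwhm) && metrics@dfwhm <= rules@dfwhmMin)
    add(.reason_row("dFWHM not positive", metrics@dfwhm,
                    paste0(">", rules@dfwhmMin), "plausibility"))
  if (fin(metrics@peakDelay) && metrics@peakDelay < rules@peakDelayMin)
    add(.reason_row("peak delay below minimum", metrics@peakDelay,
                    paste0(">=", rules@peakDelayMin), "plausibility"))

  reasons <- if (length(rs)) do.call(rbind, rs) else
    data.frame(rule = character(), observed = character(),
               bound = character(), severity = character(),
               stringsAsFactors = FALSE)
  label <- if (any(reasons$severity == "hard")) "reject"
           else if (nrow(reasons)) "suspect" else "acceptable"
  new("QCVerdict", label = label, reasons = reasons)
}

.rule_file_fields <- c(
  snr_min = "snrMin", dynamic_range_min = "dynamicRangeMin",
  peak_delay_min = "peakDelayMin", rfwhm_min = "rfwhmMin",
  dfwhm_min = "dfwhmMin", count_rate_window = "countRateWindow",
  beta_window = "betaWindow", bfi_window = "bfiWindow",
  bfi_unreliable = "bfiUnreliable", tail_plateau_max = "tailPlateauMax",
  sto2_window = "sto2Window")

#' Read a QC rule set from a YAML or JSON file
#'
#' The file holds the snake_case fields \code{snr_min, dynamic_range_min,
#' peak_delay_min, rfwhm_min, dfwhm_min, count_rate_window, beta_window,
#' bfi_window, bfi_unreliable, tail_plateau_max, sto2_window}; missing fields
#' take the package defaults.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a \linkS4class{QCRuleSet}.
#' @export
readQCRules <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("rule file not found: ", path),
                        class = "diffuseQC_config_error"))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), names(.rule_file_fields))
  if (length(bad))
    stop(errorCondition(
      paste0("unknown rule field(s): ", paste(bad, collapse = ", ")),
      class = "diffuseQC_config_error"))
  rules <- defaultQCRules()
  for (nm in names(cfg))
    slot(rules, .rule_file_fields[[nm]]) <- as.numeric(unlist(cfg[[nm]]))
  validObject(rules)
  rules
}

#' Write a QC rule set to a YAML or JSON file
#' @param rules a \linkS4class{QCRuleSet}.
#' @param path destination (.yaml/.yml or .json).
#' @return the path, invisibly.
#' @export
writeQCRules <- function(rules, path) {
  stopifnot(is(rules, "QCRuleSet"))
  lst <- lapply(.rule_file_fields, function(s) slot(rules, s))
  names(lst) <- names(.rule_file_fields)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.metrics_snapshot <- function(metrics) {
  out <- lapply(slotNames("QCMetrics"), function(s) {
    v <- slot(metrics, s)
    if (is.na(v)) NULL else v
  })
  names(out) <- slotNames("QCMetrics")
  out[!vapply(out, is.null, logical(1))]
}

#' Serialize a verdict (with its metrics and rule snapshot) to JSON
#'
#' @param verdict a \linkS4class{QCVerdict}.
#' @param metrics the \linkS4class{QCMetrics} the verdict was computed from.
#' @param rules the \linkS4class{QCRuleSet} used.
#' @param path optional file to write; when NULL the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
verdictToJSON <- function(verdict, metrics, rules, path = NULL) {
  stopifnot(is(verdict, "QCVerdict"), is(metrics, "QCMetrics"),
            is(rules, "QCRuleSet"))
  ruleSnap <- lapply(.rule_file_fields, function(s) slot(rules, s))
  names(ruleSnap) <- names(.rule_file_fields)
  obj <- list(label = verdict@label,
              reasons = verdict@reasons,
              metrics = .metrics_snapshot(metrics),
              rules = ruleSnap)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
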