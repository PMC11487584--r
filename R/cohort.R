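# Map a tissue composition onto the preset family whose signatures a
# measurement over it would plausibly show. Priority: ischemic tissue, then
# hematomas, subarachnoid blood, trapped air, swollen tissue (with/without
# CSF), sub-skull CSF, and finally healthy-like.
.composition_preset <- function(compString) {
  if (is.na(compString) || !nzchar(compString)) return("H0")
  has <- function(code) compositionContains(compString, code)
  if (has("IT")) return("case1")
  if (has("EH") || has("ICH") || has("BC")) return("case6")
  if (has("SAH")) return("case5")
  if (has("A")) return("case8")
  if (has("SST") && has("CSF")) return("case3")
  if (has("SST")) return("case2")
  if (has("CSF")) return("case7")
  "H0"
}

#' Generate a synthetic measurement cohort
#'
#' Samples tissue compositions with the relative frequencies of the packaged
#' composition table, maps each composition to a case-preset family, draws
#' per-ROI ground-truth optical/hemodynamic values around the preset values
#' (5 percent lognormal-ish jitter), and assembles the per-ROI table and its
#' long-format dataset table. Curves are not simulated by default (the table
#' is the product); set \code{includeCurves = TRUE} to also generate the
#' paired TRS + DCS curves for every ROI via \code{\link{generateCase}}.
#' Seeds propagate hierarchically (cohort seed to per-ROI child seeds), so
#' any subset of ROIs is reproducible.
#'
#' @param nRois number of probed regions (>= 1).
#' @param seed integer seed.
#' @param compositionFreqs data.frame with columns \code{composition},
#'   \code{count}, \code{skull_present} (default the packaged fixture).
#' @param includeCurves also generate the per-ROI curve bundles.
#' @return a list with \code{rois} (per-ROI data.frame), \code{table} (the
#'   long-format dataset table, 2 rows per ROI), and \code{curves} (NULL or
#'   a named list of measurement bundles).
#' @examples
#' coh <- generateCohort(10, seed = 7)
#' nrow(coh$table)  # 20
#' @export
generateCohort <- function(nRois, seed = 1,
                           compositionFreqs = compositionFixture(),
                           includeCurves = FALSE) {
  if (nRois < 1) stop("'nRois' must be >= 1")
  if (!is.data.frame(compositionFreqs) || !nrow(compositionFreqs) ||
      !all(c("composition", "count") %in% names(compositionFreqs)))
    stop("empty or malformed composition frequency table")
  set.seed(as.integer(seed))
  presets <- casePresets()
  idx <- sample.int(nrow(compositionFreqs), nRois, replace = TRUE,
                    prob = compositionFreqs$count)
  comps <- compositionFreqs$composition[idx]
  skull <- if ("skull_present" %in% names(compositionFreqs))
    compositionFreqs$skull_present[idx] else !grepl("\\*", comps)
  nSubj <- max(1L, ceiling(nRois / 3.4))
  subjIds <- sprintf("S%03d", seq_len(nSubj))
  subjCohort <- sample(c("MCA", "TBI", "SAH"), nSubj, replace = TRUE,
                       prob = c(9, 26, 1) / 36)
  subjGender <- sample(c("M", "F"), nSubj, replace = TRUE, prob = c(27, 9) / 36)
  subjAge <- pmax(16, round(rnorm(nSubj, mean = 41, sd = 15)))
  roiSubj <- sort(rep_len(seq_len(nSubj), nRois))
  jit <- function(x, k) x * (1 + 0.05 * rnorm(length(x)))
  rois <- do.call(rbind, lapply(seq_len(nRois), function(i) {
    pid <- .composition_preset(comps[i])
    p <- presets[[pid]]
    pr687 <- p@trs$props[["687"]]; pr830 <- p@trs$props[["830"]]
    refused <- identical(pid, "case1") || identical(pid, "case4")
    m687 <- if (refused) NA_real_ else jit(pr687$mua)
    s687 <- if (refused) NA_real_ else jit(pr687$musp)
    m830 <- if (refused) NA_real_ else jit(pr830$mua)
    s830 <- if (refused) NA_real_ else jit(pr830$musp)
    sto2v <- if (refused) NA_real_ else
      sto2(computeHemodynamics(m687, m830))
    bfiLead <- p@dcs$components[[1L]]$bfi
    bfiv <- if (bfiLead > 0) jit(bfiLead) else NA_real_
    data.frame(
      measurement_id = sprintf("M%04d", i),
      subject_id = subjIds[roiSubj[i]],
      cohort = subjCohort[roiSubj[i]],
      mua_687 = m687, musp_687 = s687, mua_830 = m830, musp_830 = s830,
      sto2 = sto2v, bfi = bfiv,
      tissue_composition = comps[i],
      injury = !identical(pid, "H0"),
      surgery = !skull[i] ||
        compositionContains(comps[i], "SST") && runif(1) < 0.2,
      sedation = runif(1) < 0.65,
      hematoma = grepl("SAH|EH|ICH", comps[i]),
      gender = subjGender[roiSubj[i]],
      skull = skull[i],
      age_years = subjAge[roiSubj[i]],
      stringsAsFactors = FALSE)
  }))
  tab <- toLongTable(rois)
  curves <- NULL
  if (includeCurves) {
    curves <- lapply(seq_len(nRois), function(i)
      generateCase(.composition_preset(comps[i]),
                   seed = .child_seed(seed, i)))
    names(curves) <- rois$measurement_id
  }
  list(rois = rois, table = tab, curves = curves)
}
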