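.long_table_cols <- c("measurement_id", "subject_id", "cohort",
                      "wavelength_nm", "mua_percm", "musp_percm",
                      "sto2_percent", "bfi_cm2s", "tissue_composition",
                      "injury", "surgery", "sedation", "hematoma", "gender",
                      "skull", "age_years")

.roi_input_cols <- c("measurement_id", "subject_id", "cohort",
                     "mua_687", "musp_687", "mua_830", "musp_830",
                     "sto2", "bfi", "tissue_composition", "injury",
                     "surgery", "sedation", "hematoma", "gender", "skull",
                     "age_years")

#' Long-format dataset table from per-ROI records
#'
#' Expands one row per probed region (ROI) into the deposited-spreadsheet
#' layout: exactly two rows per ROI, one per TRS wavelength (687 and 830
#' nm), with the wavelength-specific optical coefficients in each row and
#' the shared quantities (StO2, BFI, clinical and demographic fields)
#' repeated across the pair. Rows are ordered by measurement id, then
#' wavelength ascending. Failed fits are carried as NA.
#'
#' @param rois a data.frame with one row per ROI and columns
#'   \code{measurement_id, subject_id, cohort, mua_687, musp_687, mua_830,
#'   musp_830, sto2, bfi, tissue_composition, injury, surgery, sedation,
#'   hematoma, gender, skull, age_years}.
#' @return a data.frame with \code{2 * nrow(rois)} rows and the fixed column
#'   set \code{measurement_id, subject_id, cohort, wavelength_nm, mua_percm,
#'   musp_percm, sto2_percent, bfi_cm2s, tissue_composition, injury,
#'   surgery, sedation, hematoma, gender, skull, age_years}.
#' @export
toLongTable <- function(rois) {
  stopifnot(is.data.frame(rois))
  missing <- setdiff(.roi_input_cols, names(rois))
  if (length(missing))
    stop("ROI table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(rois$measurement_id))
    stop(errorCondition("schema error: duplicate measurement ids",
                        class = "diffuseQC_schema_error"))
  one <- function(wl) {
    data.frame(
      measurement_id = rois$measurement_id,
      subject_id = rois$subject_id,
      cohort = rois$cohort,
      wavelength_nm = wl,
      mua_percm = rois[[paste0("mua_", wl)]],
      musp_percm = rois[[paste0("musp_", wl)]],
      sto2_percent = rois$sto2,
      bfi_cm2s = rois$bfi,
      tissue_composition = rois$tissue_composition,
      injury = rois$injury, surgery = rois$surgery,
      sedation = rois$sedation, hematoma = rois$hematoma,
      gender = rois$gender, skull = rois$skull,
      age_years = rois$age_years,
      stringsAsFactors = FALSE)
  }
  out <- rbind(one(687), one(830))
  out <- out[order(out$measurement_id, out$wavelength_nm), ]
  rownames(out) <- NULL
  out
}

# round half away from zero to integer (the convention of the printed
# percentage columns)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cohort summary of a long-format dataset table
#'
#' Counts and integer percentages (rounded half away from zero) computed
#' over distinct ROIs for each yes/no flag (surgery, skull, injury,
#' sedation, hematoma); subject-level cohort counts, gender ratio, and age
#' mean/SD (ages are stored per subject and summarized per subject);
#' tissue-composition counts keyed by canonical composition string (ROIs
#' with no recorded composition are skipped in the composition tally).
#'
#' @param table a long-format data.frame from \code{\link{toLongTable}} (or
#'   the packaged fixture).
#' @return a list with elements \code{n_rois}, \code{n_rows},
#'   \code{n_subjects}, \code{flags} (data.frame flag/yes/no/percent_yes),
#'   \code{cohorts} (named counts), \code{gender} (named counts),
#'   \code{age_mean}, \code{age_sd}, \code{compositions} (named counts).
#' @export
summarizeDataset <- function(table) {
  stopifnot(is.data.frame(table))
  if (!nrow(table)) stop("cannot summarize an empty table")
  missing <- setdiff(.long_table_cols, names(table))
  if (length(missing))
    stop("table is missing column(s): ", paste(missing, collapse = ", "))
  rois <- table[!duplicated(table$measurement_id), , drop = FALSE]
  subj <- rois[!duplicated(rois$subject_id), , drop = FALSE]
  yn <- function(flag) {
    v <- rois[[flag]]
    yes <- sum(v %in% c(TRUE, "Y", "yes", "TRUE", 1))
    no <- nrow(rois) - yes
    data.frame(flag = flag, yes = yes, no = no,
               percent_yes = .round_half_away(100 * yes / nrow(rois)),
               stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, lapply(c("surgery", "skull", "injury", "sedation",
                                   "hematoma"), yn))
  comp <- rois$tissue_composition
  comp <- comp[!is.na(comp) & nzchar(comp)]
  comp <- vapply(comp, function(s) formatComposition(parseComposition(s)),
                 character(1), USE.NAMES = FALSE)
  compCounts <- sort(table(comp), decreasing = TRUE)
  list(
    n_rois = nrow(rois),
    n_rows = nrow(table),
    n_subjects = nrow(subj),
    flags = flags,
    cohorts = vapply(split(subj, subj$cohort), nrow, integer(1)),
    gender = vapply(split(subj, subj$gender), nrow, integer(1)),
    age_mean = mean(subj$age_years),
    age_sd = sd(subj$age_years),
    compositions = setNames(as.integer(compCounts), names(compCounts)))
}

#' Write / read a long-format dataset table as CSV
#'
#' Comma-separated, UTF-8, mandatory header row, \code{"."} decimal
#' separator.
#'
#' @param table a long-format data.frame.
#' @param path file path.
#' @return \code{writeDatasetCSV}: the path invisibly;
#'   \code{readDatasetCSV}: the data.frame.
#' @export
writeDatasetCSV <- function(table, path) {
  missing <- setdiff(.long_table_cols, names(table))
  if (length(missing))
    stop("table is missing column(s): ", paste(missing, collapse = ", "))
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeDatasetCSV
#' @export
readDatasetCSV <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.long_table_cols, names(tab))
  if (length(missing))
    stop(errorCondition(
      paste0("schema error: CSV is missing column(s): ",
             paste(missing, collapse = ", ")),
      class = "diffuseQC_schema_error"))
  tab
}

#' Packaged synthetic cohort fixture
#'
#' A synthetic per-ROI table (121 ROIs from 36 subjects) constructed to
#' reproduce the printed cohort marginals of the study population it
#' emulates: 27:9 gender ratio, ages with mean 41 (SD 15), subjects split
#' 9 MCA / 26 TBI / 1 SAH, surgery 23:98 ROIs, skull presence 108:13 ROIs,
#' and the full tissue-composition frequency table (118 categorized ROIs
#' plus 3 without a recorded composition). All rows are synthetic; no
#' patient data are included.
#'
#' @return a per-ROI data.frame suitable for \code{\link{toLongTable}}
#'   (optical columns are NA; the fixture documents bookkeeping, not
#'   optics).
#' @export
cohortFixture <- function() {
  path <- system.file("extdata", "cohort_rois_synthetic.csv",
                      package = "diffuseQC", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged tissue-composition frequency fixture
#'
#' The 32 printed tissue-composition categories with their ROI counts and a
#' flag for the categories marked as lacking cranial bone. Counts sum to
#' 118 (121 ROIs minus the 3 omitted for missing CT).
#'
#' @return a data.frame with columns \code{composition}, \code{count},
#'   \code{skull_present}.
#' @export
compositionFixture <- function() {
  path <- system.file("extdata", "tissue_compositions.csv",
                      package = "diffuseQC", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
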