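# Sidecar schema: required fields by curve kind. The machine-readable copy
# ships in inst/extdata/curve_sidecar_schema.json.
.sidecar_required <- list(
  dtof = c("kind", "wavelength", "n_averaged", "background_level"),
  irf = c("kind", "fwhm"),
  g2 = c("kind", "count_rate", "n_channels", "duration"))

#' Write a curve to a two-column text file with a JSON sidecar
#'
#' The curve file holds '#'-prefixed header lines followed by two
#' tab-separated columns (abscissa, value) at 15 significant digits. The
#' metadata (kind, wavelength, bookkeeping, optional rho/beta/seed) goes in
#' a JSON sidecar at \code{<path>.json}.
#'
#' @param curve a \linkS4class{DTOFHistogram}, \linkS4class{IRF} or
#'   \linkS4class{G2Curve}.
#' @param path destination path for the two-column file.
#' @param extra named list of extra sidecar fields (e.g. rho, beta, seed).
#' @return the path, invisibly.
#' @export
writeCurve <- function(curve, path, extra = list()) {
  if (is(curve, "DTOFHistogram")) {
    kind <- "dtof"
    ab <- curve@tGrid; vals <- curve@counts
    meta <- list(kind = kind, wavelength = curve@wavelength,
                 n_averaged = curve@nAveraged,
                 background_level = curve@backgroundLevel)
    cols <- c("time_ns", "counts")
  } else if (is(curve, "IRF")) {
    kind <- "irf"
    ab <- curve@tGrid; vals <- curve@values
    meta <- list(kind = kind, fwhm = curve@fwhm)
    cols <- c("time_ns", "response")
  } else if (is(curve, "G2Curve")) {
    kind <- "g2"
    ab <- curve@tauGrid; vals <- curve@values
    meta <- list(kind = kind, count_rate = curve@countRate,
                 n_channels = curve@nChannels, duration = curve@duration)
    cols <- c("tau_s", "g2")
  } else stop("unsupported curve class: ", class(curve)[1L])
  meta <- c(meta, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# diffuseQC curve file, kind=", kind),
               paste0("# columns: ", paste(cols, collapse = "\t"))), con)
  writeLines(paste(formatC(ab, format = "g", digits = 15),
                   formatC(vals, format = "g", digits = 15), sep = "\t"), con)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a curve file written by \code{writeCurve}
#'
#' The JSON sidecar at \code{<path>.json} determines the object class. A
#' missing sidecar or missing required fields raise a validation error
#' naming the field; a non-increasing abscissa raises a format error.
#'
#' @param path path to the two-column curve file.
#' @return a \linkS4class{DTOFHistogram}, \linkS4class{IRF} or
#'   \linkS4class{G2Curve} according to the sidecar kind.
#' @export
readCurve <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("curve file not found: ", path),
                        class = "diffuseQC_io_error"))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(errorCondition(
      paste0("validation error: missing sidecar ", sidecar),
      class = "diffuseQC_validation_error"))
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$kind) || !meta$kind %in% names(.sidecar_required))
    stop(errorCondition(
      "validation error at field 'kind': must be one of dtof/irf/g2",
      class = "diffuseQC_validation_error"))
  missing <- setdiff(.sidecar_required[[meta$kind]], names(meta))
  if (length(missing))
    stop(errorCondition(
      paste0("validation error at field '", missing[1L],
             "': required for kind ", meta$kind),
      class = "diffuseQC_validation_error"))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ab <- as.numeric(vapply(parts, `[`, character(1), 1L))
  vals <- as.numeric(vapply(parts, `[`, character(1), 2L))
  if (anyNA(ab) || anyNA(vals))
    stop(errorCondition("format error: non-numeric curve data",
                        class = "diffuseQC_format_error"))
  if (any(diff(ab) <= 0))
    stop(errorCondition(
      "format error: abscissa must be strictly increasing",
      class = "diffuseQC_format_error"))
  switch(meta$kind,
    dtof = dtofHistogram(ab, vals, wavelength = meta$wavelength,
                         nAveraged = meta$n_averaged,
                         backgroundLevel = meta$background_level),
    irf = new("IRF", tGrid = ab,
              values = vals / (sum(vals) * (ab[2L] - ab[1L])),
              fwhm = meta$fwhm),
    g2 = g2Curve(ab, vals, countRate = meta$count_rate,
                 nChannels = meta$n_channels, duration = meta$duration))
}

#' Write a generated measurement bundle to a directory
#'
#' Writes the four curves of one measurement (DTOFs at both wavelengths,
#' IRF, g2) as text curve files with sidecars, plus the ground-truth preset
#' as JSON.
#'
#' @param meas a measurement list from \code{\link{generateCase}}.
#' @param dir destination directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeMeasurement <- function(meas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeCurve(meas$dtof687, file.path(dir, "dtof_687.tsv"))
  writeCurve(meas$dtof830, file.path(dir, "dtof_830.tsv"))
  writeCurve(meas$irf, file.path(dir, "irf.tsv"))
  writeCurve(meas$g2, file.path(dir, "g2.tsv"))
  if (!is.null(meas$truth)) {
    p <- meas$truth
    jsonlite::write_json(
      list(case_id = p@caseId, description = p@description, trs = p@trs,
           dcs = p@dcs, expected_verdicts = p@expectedVerdicts,
           design = p@design),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
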