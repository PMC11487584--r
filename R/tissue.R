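.tissue_codes <- c("ST", "SST", "CB", "NB", "A", "CSF", "SAH", "EH", "ICH",
                   "IT", "BC")

#' Tissue composition of a probed region
#'
#' An ordered outer-to-inner description of the tissue layers under the
#' probe, written as codes joined by \code{"+"}, with \code{"/"} marking a
#' mixed layer of exactly two components (e.g., \code{"ST+CB+CSF/NB"}).
#' Recognized codes: ST (subcutaneous tissue), SST (swollen subcutaneous
#' tissue), CB (cranial bone), NB (normal brain), A (air), CSF
#' (cerebrospinal fluid), SAH (subarachnoid hemorrhage), EH (extracerebral
#' hematoma), ICH (intracerebral hematoma), IT (ischemic tissue), BC (brain
#' contusion).
#'
#' @slot layers a list, outer to inner; each element a character vector of
#'   1 (plain layer) or 2 (mixed layer) codes.
#' @slot raw the canonical string form.
#' @export
setClass("TissueComposition",
  representation(layers = "list", raw = "character"),
  validity = function(object) {
    msg <- character()
    if (!length(object@layers)) msg <- c(msg, "at least one layer required")
    for (ly in object@layers) {
      if (!is.character(ly) || !(length(ly) %in% 1:2))
        msg <- c(msg, "each layer must hold 1 or 2 codes")
      else if (!all(ly %in% .tissue_codes))
        msg <- c(msg, paste0("unknown code(s): ",
                             paste(setdiff(ly, .tissue_codes), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Parse a tissue-composition string
#'
#' \code{"+"} separates layers (outer to inner); \code{"/"} marks a mixed
#' layer of exactly two codes. Whitespace around codes is ignored. A trailing
#' \code{"*"} (the no-cranial-bone mark used in printed tables) is not part
#' of the grammar and is rejected; strip it and record skull absence
#' separately.
#'
#' @param text composition string, e.g. \code{"SST+CB+CSF/NB"}.
#' @return a \linkS4class{TissueComposition}.
#' @examples
#' parseComposition("ST+CB+CSF+NB")
#' parseComposition("SST+CB+CSF/NB")
#' @export
parseComposition <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("composition must be a single non-empty string")
  parts <- strsplit(text, "+", fixed = TRUE)[[1L]]
  if (!length(parts)) stop("parse error: empty composition")
  layers <- lapply(parts, function(p) {
    comps <- trimws(strsplit(p, "/", fixed = TRUE)[[1L]])
    if (!length(comps) || any(!nzchar(comps)))
      stop("parse error: empty layer in '", text, "'")
    if (length(comps) > 2L)
      stop("parse error: mixed layer '", trimws(p),
           "' must contain exactly 2 codes")
    bad <- setdiff(comps, .tissue_codes)
    if (length(bad))
      stop("parse error: unknown tissue code '", bad[1L], "' in '", text, "'")
    comps
  })
  canon <- paste(vapply(layers, paste, character(1), collapse = "/"),
                 collapse = "+")
  new("TissueComposition", layers = layers, raw = canon)
}

#' Canonical string form of a tissue composition
#' @param comp a \linkS4class{TissueComposition}.
#' @return the canonical composition string.
#' @export
formatComposition <- function(comp) {
  stopifnot(is(comp, "TissueComposition"))
  comp@raw
}

#' Does a composition contain a given tissue code (in any layer)?
#' @param comp a \linkS4class{TissueComposition} or composition string.
#' @param code a tissue code.
#' @return logical.
#' @export
compositionContains <- function(comp, code) {
  if (is.character(comp)) comp <- parseComposition(comp)
  any(vapply(comp@layers, function(ly) code %in% ly, logical(1)))
}

setMethod("show", "TissueComposition", function(object) {
  cat(sprintf("TissueComposition: %s (%d layers, outer to inner)\n",
              object@raw, length(object@layers)))
})

#' Area of a circular region of interest
#'
#' The probed region is modeled as a circle of given radius under the probe
#' (default radius 15 mm, about 700 mm^2, matching the depth most detected
#' photons reach at a 30-mm interfiber distance).
#'
#' @param radius radius in mm (>= 0).
#' @return area in mm^2.
#' @examples
#' roiArea(15)  # ~706.9, i.e. ~700 mm^2
#' @export
roiArea <- function(radius) {
  if (!is.numeric(radius) || any(radius < 0))
    stop("'radius' must be nonnegative (mm)")
  pi * radius^2
}
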