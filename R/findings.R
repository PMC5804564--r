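# Controlled issue vocabulary and the Finding record.
#
# Findings are plain data.frames (one row per issue) with a fixed column
# set, so they can be concatenated, counted and diffed across pipeline
# stages. The code column is drawn from a packaged controlled vocabulary:
# the classic biocuration issue taxonomy plus dictionary-validation and
# operational codes. Severity is fixed per code.

.issueCodes <- local({
  curation <- c(
    "Chirality error"                                                   = "error",
    "Polymer backbone linkage"                                          = "error",
    "Atomic clashes"                                                    = "error",
    "Sequence discrepancy"                                              = "error",
    "Atoms with unrealistic or zero occupancies"                        = "error",
    "High real space R-factor and low correlation in the structure factors" = "error",
    "Incomplete data in the structure factors"                          = "error",
    "Missing and/or inconsistent metadata values"                       = "error",
    "Reported and calculated quaternary structure do not agree"         = "error",
    "Ligand geometry"                                                   = "error",
    "Occupancy of atoms on special symmetry positions"                  = "error",
    "Wavelength discrepancy"                                            = "error",
    "Missing anisotropic B-factor"                                      = "warning",
    "Ligand identity"                                                   = "error",
    "Distant waters"                                                    = "warning",
    "Polymer geometry"                                                  = "error",
    "Unusual phi/psi torsion angles"                                    = "warning",
    "Extra hydrogen atoms"                                              = "error",
    "Zero B-factor"                                                     = "warning",
    "Missing free R test set in the structure factors"                  = "warning"
  )
  dictionary <- c(
    missing_mandatory = "error",
    enum_violation    = "error",
    type_violation    = "error",
    hard_range        = "error",
    soft_range        = "warning",
    key_integrity     = "error",
    unknown_category  = "error"
  )
  operational <- c(
    missing_sample_sequence = "error",
    merge_conflict          = "error",
    transform_refused       = "error",
    chain_merged            = "info",
    chain_split             = "info",
    relabelled_residue      = "info",
    water_moved             = "info",
    ligand_partial_match    = "warning",
    indeterminate_chirality = "info",
    skipped_stereocenter    = "info",
    unmodeled_region        = "info",
    correspondence_needed   = "error",
    non_mx_entry            = "info",
    incomplete_backbone     = "info",
    unassigned_segment      = "warning",
    missing_atom            = "warning"
  )
  c(curation, dictionary, operational)
})

#' Issue vocabulary
#'
#' The packaged controlled vocabulary of issue codes raised during
#' biocuration, with the fixed severity of each code. It comprises the 19
#' classic curation issue codes (chirality errors, backbone linkage,
#' clashes, ...), the dictionary-validation codes (missing_mandatory,
#' enum_violation, type_violation, hard_range, soft_range, key_integrity,
#' unknown_category) and operational/bookkeeping codes.
#'
#' @return A data.frame with columns \code{code} and \code{severity}.
#' @export
#' @examples
#' head(issueVocabulary())
issueVocabulary <- function() {
  data.frame(code = names(.issueCodes), severity = unname(.issueCodes),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Construct a finding
#'
#' A finding is one detected issue: a controlled-vocabulary code, the fixed
#' severity of that code, an optional dictionary item name, an optional
#' locus (free-form, e.g. \code{"entity_src_gen[2]"} or \code{"A:64:CA"})
#' and a human-readable message.
#'
#' @param code issue code; must be in \code{issueVocabulary()}.
#' @param message description of the issue.
#' @param item optional "category.item" dictionary name.
#' @param locus optional locus string.
#' @return A one-row findings data.frame.
#' @export
finding <- function(code, message, item = NA_character_, locus = NA_character_) {
  if (!code %in% names(.issueCodes))
    .stopf("minidepVocabularyError", "unknown issue code: '%s'", code)
  data.frame(severity = unname(.issueCodes[code]), code = code,
             item = item, locus = locus, message = message,
             stringsAsFactors = FALSE)
}

#' @rdname finding
#' @export
emptyFindings <- function() {
  data.frame(severity = character(0), code = character(0),
             item = character(0), locus = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

# rbind a list of findings frames (possibly empty / NULL entries).
.bindFindings <- function(...) {
  xs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(xs) == 0) return(emptyFindings())
  do.call(rbind, c(xs, list(make.row.names = FALSE)))
}

.bindFindingsList <- function(xs) do.call(.bindFindings, xs)
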