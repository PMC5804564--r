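# S4 classes for the central data containers.

#' @import methods
NULL

#' ItemDef: one dictionary item definition
#'
#' Describes a single "category.item" of the validation dictionary: its type
#' code, whether it is mandatory, an optional enumeration, optional hard and
#' soft numeric limits (inclusive), and an optional parent item that the
#' value must reference.
#'
#' @slot name "category.item" string.
#' @slot typeCode one of text, int, float, enum, date.
#' @slot mandatory logical.
#' @slot enumeration allowed strings (present iff typeCode is enum).
#' @slot hardRange numeric(0) or c(lo, hi); violations are errors.
#' @slot softRange numeric(0) or c(lo, hi); violations are warnings.
#' @slot parent character(0) or the name of the parent item.
#' @export
setClass("ItemDef", representation(
  name = "character", typeCode = "character", mandatory = "logical",
  enumeration = "character", hardRange = "numeric", softRange = "numeric",
  parent = "character"
), prototype(mandatory = FALSE, enumeration = character(0),
             hardRange = numeric(0), softRange = numeric(0),
             parent = character(0)))

setValidity("ItemDef", function(object) {
  msgs <- character(0)
  if (!grepl("^[^.]+\\.[^.]+$", object@name))
    msgs <- c(msgs, "name must have the form 'category.item'")
  if (!object@typeCode %in% c("text", "int", "float", "enum", "date"))
    msgs <- c(msgs, sprintf("unknown type code '%s'", object@typeCode))
  if ((object@typeCode == "enum") != (length(object@enumeration) > 0))
    msgs <- c(msgs, "enumeration must be present iff typeCode is 'enum'")
  for (slot in c("hardRange", "softRange")) {
    r <- slot(object, slot)
    if (length(r) %in% c(0L, 2L)) {
      if (length(r) == 2 && r[1] > r[2])
        msgs <- c(msgs, sprintf("%s lo > hi", slot))
      if (length(r) == 2 && !object@typeCode %in% c("int", "float"))
        msgs <- c(msgs, sprintf("%s only allowed for numeric items", slot))
    } else msgs <- c(msgs, sprintf("%s must have length 0 or 2", slot))
  }
  if (length(object@hardRange) == 2 && length(object@softRange) == 2) {
    if (object@softRange[1] < object@hardRange[1] ||
        object@softRange[2] > object@hardRange[2])
      msgs <- c(msgs, "softRange must be contained in hardRange")
  }
  if (length(msgs)) msgs else TRUE
})

#' CategoryDef: one dictionary category
#'
#' @slot name category name.
#' @slot keyItems item names forming the category key (subset of items).
#' @slot items list of \linkS4class{ItemDef}.
#' @export
setClass("CategoryDef", representation(
  name = "character", keyItems = "character", items = "list"
), prototype(keyItems = character(0), items = list()))

setValidity("CategoryDef", function(object) {
  itemNames <- vapply(object@items, function(i) i@name, character(1))
  short <- sub("^[^.]+\\.", "", itemNames)
  msgs <- character(0)
  if (anyDuplicated(itemNames))
    msgs <- c(msgs, "duplicate item names in category")
  if (!all(startsWith(itemNames, paste0(object@name, "."))))
    msgs <- c(msgs, "all items must belong to the category")
  if (!all(object@keyItems %in% short))
    msgs <- c(msgs, "keyItems must be a subset of the category's items")
  if (length(msgs)) msgs else TRUE
})

#' DictionarySchema: a validation dictionary
#'
#' A small dictionary of category and item definitions used to validate
#' deposition data blocks: types, mandatory items, enumerations, hard/soft
#' numeric limits and parent/child key relationships.
#'
#' @slot categories named list of \linkS4class{CategoryDef}.
#' @slot version schema version string.
#' @export
setClass("DictionarySchema", representation(
  categories = "list", version = "character"
), prototype(categories = list(), version = "0"))

setValidity("DictionarySchema", function(object) {
  msgs <- character(0)
  if (!identical(names(object@categories),
                 unname(vapply(object@categories, function(c) c@name,
                               character(1)))))
    msgs <- c(msgs, "categories must be named by their category name")
  allItems <- unlist(lapply(object@categories, function(cat)
    vapply(cat@items, function(i) i@name, character(1))))
  if (anyDuplicated(allItems))
    msgs <- c(msgs, "item names must be globally unique")
  parents <- character(0)
  for (cat in object@categories) for (it in cat@items) {
    if (length(it@parent)) {
      if (!it@parent %in% allItems)
        msgs <- c(msgs, sprintf("dangling parent '%s' of '%s'",
                                it@parent, it@name))
      parents <- c(parents, structure(it@parent, names = it@name))
    }
  }
  # acyclicity of the parent/child item graph
  for (start in names(parents)) {
    seen <- start; cur <- start
    while (cur %in% names(parents)) {
      cur <- parents[[cur]]
      if (cur %in% seen) { msgs <- c(msgs, "parent/child graph has a cycle"); break }
      seen <- c(seen, cur)
    }
  }
  if (length(msgs)) unique(msgs) else TRUE
})

#' DataBlock: one block of tabular deposition data
#'
#' Category tables of string values prior to typing. The null conventions
#' of the format are preserved: "?" means unknown and "." inapplicable.
#'
#' @slot blockId block identifier.
#' @slot tables named list of data.frames (all-character columns); names
#'   are category names, columns are item names without the category prefix.
#' @export
setClass("DataBlock", representation(blockId = "character", tables = "list"),
         prototype(blockId = "block", tables = list()))

setValidity("DataBlock", function(object) {
  ok <- vapply(object@tables, function(tb) {
    is.data.frame(tb) && all(vapply(tb, is.character, logical(1)))
  }, logical(1))
  if (all(ok)) TRUE else "all tables must be all-character data.frames"
})

#' ChemComp: a reference chemical component
#'
#' @slot compId component code (up to 3 characters).
#' @slot atoms data.frame with columns name, element, charge.
#' @slot bonds data.frame with columns a, b, order
#'   (single/double/triple/aromatic).
#' @slot stereocenters list of list(center, neighbors, parity) where parity
#'   is the sign (+1/-1) of the triple product over the first three ordered
#'   neighbors in the ideal coordinates.
#' @slot idealXyz numeric matrix (n x 3) with atom-name rownames, possibly
#'   0-row when no ideal coordinates are defined.
#' @export
setClass("ChemComp", representation(
  compId = "character", atoms = "data.frame", bonds = "data.frame",
  stereocenters = "list", idealXyz = "matrix"
), prototype(stereocenters = list(),
             idealXyz = matrix(numeric(0), 0, 3)))

setValidity("ChemComp", function(object) {
  msgs <- character(0)
  if (nchar(object@compId) > 3 || !nzchar(object@compId))
    msgs <- c(msgs, "compId must be 1-3 characters")
  nm <- object@atoms$name
  if (anyDuplicated(nm)) msgs <- c(msgs, "duplicate atom names")
  if (nrow(object@bonds) &&
      !all(c(object@bonds$a, object@bonds$b) %in% nm))
    msgs <- c(msgs, "bond endpoints must be defined atoms")
  # connectivity (single atoms are trivially connected)
  if (length(nm) > 1) {
    adj <- lapply(stats::setNames(nm, nm), function(x) character(0))
    for (k in seq_len(nrow(object@bonds))) {
      a <- object@bonds$a[k]; b <- object@bonds$b[k]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    seen <- nm[1]; frontier <- nm[1]
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) < length(nm)) msgs <- c(msgs, "component graph must be connected")
  }
  for (sc in object@stereocenters) {
    if (!sc$center %in% nm || !all(sc$neighbors %in% nm))
      msgs <- c(msgs, "stereocenter atoms must be defined")
    if (length(sc$neighbors) < 3 || length(sc$neighbors) > 4)
      msgs <- c(msgs, "stereocenters require 3 or 4 ordered neighbors")
    if (!sc$parity %in% c(-1, 1))
      msgs <- c(msgs, "parity must be +1 or -1")
  }
  if (nrow(object@idealXyz) && !identical(rownames(object@idealXyz), nm))
    msgs <- c(msgs, "idealXyz rownames must equal atom names")
  if (length(msgs)) unique(msgs) else TRUE
})

#' MatchResult: a scored component match
#'
#' @slot compId matched component id.
#' @slot score (mapped atoms + mapped bonds) / (component atoms + bonds).
#' @slot mapping named character vector instance atom -> component atom.
#' @slot unmatchedComponentAtoms component atoms without an instance image.
#' @slot discrepancies findings data.frame.
#' @export
setClass("MatchResult", representation(
  compId = "character", score = "numeric", mapping = "character",
  unmatchedComponentAtoms = "character", discrepancies = "data.frame"
))

#' Deposition: the unit flowing through the pipeline
#'
#' @slot depId deposition identifier.
#' @slot atoms data.frame of atom records: chain, seqNum, compId, atomName,
#'   element, x, y, z, occupancy, bFactor, altId.
#' @slot sampleSequences named character vector, chain id -> depositor
#'   sample sequence (one-letter with (XXX) inserts).
#' @slot entities data.frame filled by \code{buildEntities}.
#' @slot metadata \linkS4class{DataBlock} of non-coordinate categories.
#' @slot assemblyOps list of assembly operators (id, R 3x3 Cartesian, t).
#' @slot declarations named list of depositor declarations (mutations,
#'   tags, intents, ligands of interest, oligomeric state, ...).
#' @export
setClass("Deposition", representation(
  depId = "character", atoms = "data.frame", sampleSequences = "character",
  entities = "data.frame", metadata = "DataBlock", assemblyOps = "list",
  declarations = "list"
), prototype(entities = data.frame(), assemblyOps = list(),
             declarations = list(), sampleSequences = character(0)))

setValidity("Deposition", function(object) {
  need <- c("chain", "seqNum", "compId", "atomName", "element",
            "x", "y", "z", "occupancy", "bFactor", "altId")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && !all(is.finite(xyz))) return("coordinates must be finite")
  TRUE
})

#' WorkflowState: curation pipeline state machine
#'
#' Stage order is fixed: entity, ligand, sequence, annotation, validation,
#' communication. A stage may run only once all predecessors are complete;
#' the history is append-only.
#'
#' @slot status named character over the six stages, each one of pending,
#'   running, complete, error, needs_depositor.
#' @slot history data.frame log (step, module, event, status).
#' @export
setClass("WorkflowState", representation(
  status = "character", history = "data.frame"
))

#' ReleaseSchedule: hold, reminders and release
#'
#' @slot depositDate deposit date.
#' @slot holdExpiry deposit date plus one year (month-end clamped).
#' @slot reminderDates three reminder dates (3, 2, 1 months before expiry).
#' @slot releaseDate planned release date (NA when withdrawn).
#' @slot trigger one of publication, hold_expiry, depositor_request,
#'   withdrawn.
#' @export
setClass("ReleaseSchedule", representation(
  depositDate = "Date", holdExpiry = "Date", reminderDates = "Date",
  releaseDate = "Date", trigger = "character"
))

setValidity("ReleaseSchedule", function(object) {
  msgs <- character(0)
  if (length(object@reminderDates) != 3 ||
      any(object@reminderDates >= object@holdExpiry))
    msgs <- c(msgs, "the three reminders must fall strictly before expiry")
  if (object@trigger != "withdrawn" && !is.na(object@releaseDate) &&
      object@releaseDate > object@holdExpiry)
    msgs <- c(msgs, "releaseDate must not exceed holdExpiry unless withdrawn")
  if (length(msgs)) msgs else TRUE
})

#' ReportBundle: aggregated validation report and depositor letter
#'
#' @slot findings the full findings data.frame.
#' @slot counts named integer, findings per issue code.
#' @slot percentiles named numeric percentile scores per metric.
#' @slot letter character vector of letter lines.
#' @slot status overall status ("ok" or "needs_depositor").
#' @export
setClass("ReportBundle", representation(
  findings = "data.frame", counts = "integer", percentiles = "numeric",
  letter = "character", status = "character"
))

setValidity("ReportBundle", function(object) {
  if (sum(object@counts) != nrow(object@findings))
    return("counts must total the number of findings")
  TRUE
})
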