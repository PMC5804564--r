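# Generics, accessors and show methods.

#' @rdname accessors
#' @export
setGeneric("depId", function(x) standardGeneric("depId"))
#' @rdname accessors
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))
#' @rdname accessors
#' @export
setGeneric("atomRecords<-", function(x, value) standardGeneric("atomRecords<-"))
#' @rdname accessors
#' @export
setGeneric("sampleSequences", function(x) standardGeneric("sampleSequences"))
#' @rdname accessors
#' @export
setGeneric("entityTable", function(x) standardGeneric("entityTable"))
#' @rdname accessors
#' @export
setGeneric("metadataBlock", function(x) standardGeneric("metadataBlock"))
#' @rdname accessors
#' @export
setGeneric("schemaCategories", function(x) standardGeneric("schemaCategories"))
#' @rdname accessors
#' @export
setGeneric("schemaVersion", function(x) standardGeneric("schemaVersion"))
#' @rdname accessors
#' @export
setGeneric("blockTables", function(x) standardGeneric("blockTables"))
#' @rdname accessors
#' @export
setGeneric("compId", function(x) standardGeneric("compId"))
#' @rdname accessors
#' @export
setGeneric("matchScore", function(x) standardGeneric("matchScore"))
#' @rdname accessors
#' @export
setGeneric("atomMapping", function(x) standardGeneric("atomMapping"))
#' @rdname accessors
#' @export
setGeneric("stageStatus", function(x) standardGeneric("stageStatus"))
#' @rdname accessors
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))
#' @rdname accessors
#' @export
setGeneric("reportLetter", function(x) standardGeneric("reportLetter"))
#' @rdname accessors
#' @export
setGeneric("reportStatus", function(x) standardGeneric("reportStatus"))
#' @rdname accessors
#' @export
setGeneric("reportFindings", function(x) standardGeneric("reportFindings"))

#' Accessors for the pipeline containers
#'
#' @param x a minidep S4 object.
#' @param value replacement value.
#' @return the slot value (or the updated object for setters).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("depId", "Deposition", function(x) x@depId)
#' @rdname accessors
#' @export
setMethod("atomRecords", "Deposition", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atomRecords<-", "Deposition", function(x, value) {
  x@atoms <- value; validObject(x); x
})
#' @rdname accessors
#' @export
setMethod("sampleSequences", "Deposition", function(x) x@sampleSequences)
#' @rdname accessors
#' @export
setMethod("entityTable", "Deposition", function(x) x@entities)
#' @rdname accessors
#' @export
setMethod("metadataBlock", "Deposition", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("schemaCategories", "DictionarySchema", function(x) x@categories)
#' @rdname accessors
#' @export
setMethod("schemaVersion", "DictionarySchema", function(x) x@version)
#' @rdname accessors
#' @export
setMethod("blockTables", "DataBlock", function(x) x@tables)
#' @rdname accessors
#' @export
setMethod("compId", "ChemComp", function(x) x@compId)
#' @rdname accessors
#' @export
setMethod("compId", "MatchResult", function(x) x@compId)
#' @rdname accessors
#' @export
setMethod("matchScore", "MatchResult", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("atomMapping", "MatchResult", function(x) x@mapping)
#' @rdname accessors
#' @export
setMethod("stageStatus", "WorkflowState", function(x) x@status)
#' @rdname accessors
#' @export
setMethod("reportCounts", "ReportBundle", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("reportLetter", "ReportBundle", function(x) x@letter)
#' @rdname accessors
#' @export
setMethod("reportStatus", "ReportBundle", function(x) x@status)
#' @rdname accessors
#' @export
setMethod("reportFindings", "ReportBundle", function(x) x@findings)

setMethod("show", "DictionarySchema", function(object) {
  nIt <- sum(vapply(object@categories, function(c) length(c@items), integer(1)))
  cat(sprintf("DictionarySchema v%s: %d categories, %d items\n",
              object@version, length(object@categories), nIt))
  cat(" ", paste(names(object@categories), collapse = ", "), "\n")
})

setMethod("show", "DataBlock", function(object) {
  cat(sprintf("DataBlock '%s' with %d categories\n",
              object@blockId, length(object@tables)))
  for (nm in names(object@tables))
    cat(sprintf("  %s: %d row(s)\n", nm, nrow(object@tables[[nm]])))
})

setMethod("show", "ChemComp", function(object) {
  cat(sprintf("ChemComp %s: %d atoms, %d bonds, %d stereocenter(s)%s\n",
              object@compId, nrow(object@atoms), nrow(object@bonds),
              length(object@stereocenters),
              if (nrow(object@idealXyz)) ", ideal coordinates" else ""))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %s score %.3f (%d atoms mapped, %d unmatched)\n",
              object@compId, object@score, length(object@mapping),
              length(object@unmatchedComponentAtoms)))
})

setMethod("show", "Deposition", function(object) {
  cat(sprintf("Deposition '%s': %d atoms, %d chain(s), %d sample sequence(s)\n",
              object@depId, nrow(object@atoms),
              length(unique(object@atoms$chain)),
              length(object@sampleSequences)))
  if (nrow(object@entities))
    cat(sprintf("  entities: %s\n",
                paste(object@entities$etype, collapse = ", ")))
})

setMethod("show", "WorkflowState", function(object) {
  cat("WorkflowState:\n")
  for (m in names(object@status))
    cat(sprintf("  %-13s %s\n", m, object@status[[m]]))
})

setMethod("show", "ReleaseSchedule", function(object) {
  cat(sprintf("ReleaseSchedule: deposited %s, hold expires %s\n",
              object@depositDate, object@holdExpiry))
  cat(sprintf("  reminders: %s\n",
              paste(object@reminderDates, collapse = ", ")))
  cat(sprintf("  release: %s (trigger: %s)\n",
              object@releaseDate, object@trigger))
})

setMethod("show", "ReportBundle", function(object) {
  cat(sprintf("ReportBundle: %d finding(s), status '%s'\n",
              nrow(object@findings), object@status))
  if (length(object@counts)) {
    for (nm in names(object@counts))
      cat(sprintf("  %s: %d\n", nm, object@counts[[nm]]))
  }
})
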