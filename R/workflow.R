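# Workflow orchestration: the stage state machine, geographic routing,
# the release-policy calendar, percentile scores and the report bundle.

.workflowModules <- c("entity", "ligand", "sequence", "annotation",
                      "validation", "communication")
.workflowStatuses <- c("pending", "running", "complete", "error",
                       "needs_depositor")

#' Create a fresh workflow state
#'
#' All six stages (entity, ligand, sequence, annotation, validation,
#' communication) start pending with an empty history.
#'
#' @return A \linkS4class{WorkflowState}.
#' @export
newWorkflow <- function() {
  new("WorkflowState",
      status = stats::setNames(rep("pending", length(.workflowModules)),
                               .workflowModules),
      history = data.frame(step = integer(0), module = character(0),
                           event = character(0), status = character(0),
                           stringsAsFactors = FALSE))
}

#' Advance the workflow state machine
#'
#' Events: \code{start} (allowed only when every predecessor stage is
#' complete and the stage is not already running/complete),
#' \code{complete} and \code{fail} (allowed only on a running stage), and
#' \code{restart} (resets the stage and all its successors to pending).
#' Illegal transitions raise an ordering error and leave the state
#' unchanged. Every applied transition is appended to the history.
#'
#' @param state a \linkS4class{WorkflowState}.
#' @param module one of the six stage names.
#' @param event one of start, complete, fail, restart.
#' @return The updated \linkS4class{WorkflowState}.
#' @export
advanceWorkflow <- function(state, module,
                            event = c("start", "complete", "fail",
                                      "restart")) {
  event <- match.arg(event)
  if (!module %in% .workflowModules)
    .stopf("minidepOrderingError", "unknown workflow module '%s'", module)
  status <- state@status
  idx <- match(module, .workflowModules)
  cur <- status[[module]]
  if (event == "start") {
    if (idx > 1 && !all(status[seq_len(idx - 1)] == "complete"))
      .stopf("minidepOrderingError",
             "cannot start '%s': predecessors not all complete", module)
    if (cur %in% c("running", "complete"))
      .stopf("minidepOrderingError",
             "cannot start '%s': stage is already %s", module, cur)
    status[[module]] <- "running"
  } else if (event %in% c("complete", "fail")) {
    if (cur != "running")
      .stopf("minidepOrderingError",
             "cannot %s '%s': stage is %s, not running", event, module, cur)
    status[[module]] <- if (event == "complete") "complete" else "error"
  } else {                                           # restart
    status[idx:length(status)] <- "pending"
  }
  state@status <- status
  state@history <- rbind(state@history, data.frame(
    step = nrow(state@history) + 1L, module = module, event = event,
    status = status[[module]], stringsAsFactors = FALSE))
  state
}

#' Route a deposition to a processing center by region
#'
#' Americas and Oceania go to RCSB, Europe and Africa to PDBe, Asia to
#' PDBj.
#'
#' @param region one of Americas, Oceania, Europe, Africa, Asia.
#' @return "RCSB", "PDBe" or "PDBj".
#' @export
routeDeposition <- function(region) {
  table <- c(Americas = "RCSB", Oceania = "RCSB", Europe = "PDBe",
             Africa = "PDBe", Asia = "PDBj")
  if (!region %in% names(table))
    .stopf("minidepRoutingError", "unknown region '%s'", region)
  unname(table[region])
}

# first date >= from falling on the weekly release weekday (Wednesday).
.nextReleaseDay <- function(from, weekday = 3) {
  offset <- (weekday - lubridate::wday(from, week_start = 1)) %% 7
  from + offset
}

#' Plan the release schedule of a deposition
#'
#' The hold expires one calendar year after deposit (month-end clamped, so
#' a 2016-02-29 deposit expires 2017-02-28); depositors are reminded 3, 2
#' and 1 calendar months before expiry (day-of-month preserved, clamped).
#' A publication event before expiry triggers release on the next weekly
#' release day (Wednesday by default) at or after publication; a
#' depositor_request event releases the same way; with no event the entry
#' is released at expiry. A withdrawal cancels release, and any event
#' after a withdrawal is a policy error.
#'
#' @param depositDate deposit date (Date or ISO string).
#' @param events list of list(date, kind) with kind in publication,
#'   depositor_request, withdrawn.
#' @param releaseWeekday weekly release day, 1 = Monday (default 3,
#'   Wednesday).
#' @return A \linkS4class{ReleaseSchedule}.
#' @export
planRelease <- function(depositDate, events = list(), releaseWeekday = 3) {
  depositDate <- as.Date(depositDate)
  if (is.na(depositDate))
    .stopf("minidepArgumentError", "invalid deposit date")
  expiry <- lubridate::add_with_rollback(depositDate, lubridate::years(1))
  reminders <- as.Date(vapply(3:1, function(k)
    as.character(lubridate::add_with_rollback(expiry,
                                              lubridate::period(-k, "months"))),
    character(1)))
  release <- expiry; trigger <- "hold_expiry"
  withdrawnAt <- NULL
  if (length(events)) {
    dates <- as.Date(vapply(events, function(e) as.character(as.Date(e$date)),
                            character(1)))
    events <- events[order(dates)]
    for (e in events) {
      d <- as.Date(e$date)
      if (is.na(d)) .stopf("minidepArgumentError", "invalid event date")
      if (!is.null(withdrawnAt))
        .stopf("minidepPolicyError",
               "event '%s' on %s follows the withdrawal on %s", e$kind, d,
               withdrawnAt)
      if (e$kind == "withdrawn") {
        withdrawnAt <- d
        release <- as.Date(NA); trigger <- "withdrawn"
      } else if (e$kind %in% c("publication", "depositor_request")) {
        if (trigger == "hold_expiry" && d <= expiry) {
          candidate <- .nextReleaseDay(d, releaseWeekday)
          release <- min(candidate, expiry)
          trigger <- e$kind
        }
      } else .stopf("minidepArgumentError", "unknown event kind '%s'", e$kind)
    }
  }
  new("ReleaseSchedule", depositDate = depositDate, holdExpiry = expiry,
      reminderDates = reminders, releaseDate = release, trigger = trigger)
}

#' Percentile score of a value against a reference distribution
#'
#' score = 100 * (count(worse) + 0.5 * count(ties)) / n, where "worse" is
#' oriented by \code{higherIsBetter}.
#'
#' @param value the metric value.
#' @param reference nonempty numeric reference values.
#' @param higherIsBetter TRUE when larger values are better.
#' @return A score in [0, 100].
#' @export
percentileScore <- function(value, reference, higherIsBetter = FALSE) {
  if (!length(reference))
    .stopf("minidepArgumentError", "empty reference distribution")
  worse <- if (higherIsBetter) sum(reference < value)
           else sum(reference > value)
  ties <- sum(reference == value)
  100 * (worse + 0.5 * ties) / length(reference)
}

#' Compile the validation report and depositor letter
#'
#' Findings are grouped and counted by issue code; the letter lists every
#' error first, then warnings, then info, each with its locus, from a
#' fixed plain-text template. Overall status is needs_depositor when any
#' error-severity finding is present, otherwise ok.
#'
#' @param findings a findings data.frame.
#' @param percentiles named numeric percentile scores (optional).
#' @param depId deposition id used in the letter heading.
#' @return A \linkS4class{ReportBundle}.
#' @export
compileReport <- function(findings, percentiles = numeric(0),
                          depId = "unassigned") {
  if (is.null(findings)) findings <- emptyFindings()
  counts <- vapply(split(seq_len(nrow(findings)), findings$code),
                   length, integer(1))
  counts <- counts[order(names(counts))]
  status <- if (any(findings$severity == "error")) "needs_depositor" else "ok"
  lines <- c(sprintf("Deposition %s: biocuration summary", depId), "")
  if (length(percentiles)) {
    lines <- c(lines, "Percentile scores:",
               sprintf("  %s: %.1f", names(percentiles), percentiles), "")
  }
  if (!nrow(findings)) {
    lines <- c(lines, "No outstanding issues were identified.")
  } else {
    for (sev in c("error", "warning", "info")) {
      sub <- findings[findings$severity == sev, , drop = FALSE]
      if (!nrow(sub)) next
      lines <- c(lines, sprintf("%s (%d):", toupper(sev), nrow(sub)))
      sub <- sub[order(sub$code, sub$locus, sub$message), , drop = FALSE]
      lines <- c(lines, sprintf("  [%s] %s%s", sub$code,
                                ifelse(is.na(sub$locus), "",
                                       paste0(sub$locus, ": ")),
                                sub$message))
      lines <- c(lines, "")
    }
    if (status == "needs_depositor")
      lines <- c(lines,
                 "Corrections are requested for the errors listed above.")
  }
  new("ReportBundle", findings = findings, counts = counts,
      percentiles = percentiles, letter = lines, status = status)
}
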