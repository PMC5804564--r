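# Workflow manager: state machine, routing, release calendar, scores,
# report compilation.

test_that("the happy-path stage sequence runs start/complete in order", {
  wf <- newWorkflow()
  mods <- c("entity", "ligand", "sequence", "annotation", "validation",
            "communication")
  for (m in mods) {
    wf <- advanceWorkflow(wf, m, "start")
    wf <- advanceWorkflow(wf, m, "complete")
  }
  expect_true(all(wf@status == "complete"))
  expect_identical(nrow(wf@history), 12L)
  expect_identical(wf@history$step, 1:12)
})

test_that("illegal transitions raise ordering errors and change nothing", {
  wf <- newWorkflow()
  expect_error(advanceWorkflow(wf, "ligand", "start"),
               class = "minidepOrderingError")
  expect_error(advanceWorkflow(wf, "entity", "complete"),
               class = "minidepOrderingError")
  expect_error(advanceWorkflow(wf, "nonsense", "start"),
               class = "minidepOrderingError")
  wf <- advanceWorkflow(wf, "entity", "start")
  expect_error(advanceWorkflow(wf, "entity", "start"),
               class = "minidepOrderingError")
  wf <- advanceWorkflow(wf, "entity", "fail")
  expect_identical(unname(wf@status[["entity"]]), "error")
  wf <- advanceWorkflow(wf, "entity", "restart")
  expect_true(all(wf@status == "pending"))
})

test_that("exhaustive event enumeration admits no ordering violation", {
  # breadth-first exploration of every reachable status vector under every
  # (module, event) pair, judged against an independent rule model and an
  # ordering invariant: a non-pending stage implies all its predecessors
  # are complete.
  mods <- c("entity", "ligand", "sequence", "annotation", "validation",
            "communication")
  events <- c("start", "complete", "fail", "restart")
  modelLegal <- function(st, m, e) {
    i <- match(m, mods)
    if (e == "start")
      return((i == 1 || all(st[seq_len(i - 1)] == "complete")) &&
               !st[[i]] %in% c("running", "complete"))
    if (e %in% c("complete", "fail")) return(st[[i]] == "running")
    TRUE                                               # restart
  }
  invariantOk <- function(st) {
    for (i in seq_along(st))
      if (st[i] != "pending" && i > 1 &&
          !all(st[seq_len(i - 1)] == "complete")) return(FALSE)
    TRUE
  }
  key <- function(st) paste(st, collapse = "|")
  start <- newWorkflow()@status
  seen <- new.env(parent = emptyenv())
  assign(key(start), TRUE, envir = seen)
  frontier <- list(start)
  explored <- 0L
  while (length(frontier)) {
    st <- frontier[[1]]; frontier <- frontier[-1]
    explored <- explored + 1L
    wf <- newWorkflow(); wf@status <- st
    for (m in mods) for (e in events) {
      res <- tryCatch(advanceWorkflow(wf, m, e)@status,
                      minidepOrderingError = function(err) NULL)
      legal <- modelLegal(st, m, e)
      expect_identical(!is.null(res), legal,
                       info = sprintf("state %s, %s %s", key(st), m, e))
      if (!is.null(res)) {
        expect_true(invariantOk(res),
                    info = sprintf("state %s after %s %s", key(st), m, e))
        if (!exists(key(res), envir = seen)) {
          assign(key(res), TRUE, envir = seen)
          frontier <- c(frontier, list(res))
        }
      }
    }
  }
  expect_gte(explored, 19L)   # 3 live statuses per active frontier stage
})

test_that("depositions route to the regional center", {
  expect_identical(routeDeposition("Americas"), "RCSB")
  expect_identical(routeDeposition("Oceania"), "RCSB")
  expect_identical(routeDeposition("Europe"), "PDBe")
  expect_identical(routeDeposition("Africa"), "PDBe")
  expect_identical(routeDeposition("Asia"), "PDBj")
  expect_error(routeDeposition("Atlantis"), class = "minidepRoutingError")
})

test_that("release planning follows the hold/reminder/weekly-cut policy", {
  # plain hold expiry one year on, reminders 3/2/1 months before
  s <- planRelease("2023-05-10")
  expect_identical(s@holdExpiry, as.Date("2024-05-10"))
  expect_identical(s@reminderDates,
                   as.Date(c("2024-02-10", "2024-03-10", "2024-04-10")))
  expect_identical(s@releaseDate, as.Date("2024-05-10"))
  expect_identical(s@trigger, "hold_expiry")
  # leap-day deposit clamps to month end
  expect_identical(planRelease("2016-02-29")@holdExpiry,
                   as.Date("2017-02-28"))
  # publication releases on the next Wednesday at or after the paper date
  p <- planRelease("2023-05-10",
                   list(list(date = "2023-08-10", kind = "publication")))
  expect_identical(p@trigger, "publication")
  expect_identical(weekdays(p@releaseDate), "Wednesday")
  expect_gte(as.numeric(p@releaseDate - as.Date("2023-08-10")), 0)
  expect_lt(as.numeric(p@releaseDate - as.Date("2023-08-10")), 7)
  # a publication after expiry does not beat the expiry release
  late <- planRelease("2023-05-10",
                      list(list(date = "2024-08-01", kind = "publication")))
  expect_identical(late@trigger, "hold_expiry")
  # withdrawal cancels release; later events are policy errors
  w <- planRelease("2023-05-10",
                   list(list(date = "2023-06-01", kind = "withdrawn")))
  expect_identical(w@trigger, "withdrawn")
  expect_true(is.na(w@releaseDate))
  expect_error(planRelease("2023-05-10", list(
    list(date = "2023-06-01", kind = "withdrawn"),
    list(date = "2023-07-01", kind = "publication"))),
    class = "minidepPolicyError")
})

test_that("percentile scores follow the midrank convention", {
  ref <- c(1, 2, 3, 4, 5)
  expect_equal(percentileScore(0.5, ref), 100)        # best (low is good)
  expect_equal(percentileScore(10, ref), 0)
  expect_equal(percentileScore(3, ref), 50)
  expect_equal(percentileScore(3, ref, higherIsBetter = TRUE), 50)
  expect_equal(percentileScore(5, ref, higherIsBetter = TRUE), 90)
  expect_error(percentileScore(1, numeric(0)),
               class = "minidepArgumentError")
})

test_that("compileReport counts, sorts and letters findings", {
  f <- rbind(
    finding("Atomic clashes", "pair B", locus = "A:2"),
    finding("Atomic clashes", "pair A", locus = "A:1"),
    finding("Zero B-factor", "atom", locus = "A:3"))
  rep <- compileReport(f, percentiles = c(clashscore = 42), depId = "D_1")
  expect_identical(unname(rep@counts),
                   c(2L, 1L))
  expect_identical(names(rep@counts), c("Atomic clashes", "Zero B-factor"))
  expect_identical(rep@status, "needs_depositor")
  expect_true(any(grepl("ERROR (2):", rep@letter, fixed = TRUE)))
  expect_true(any(grepl("WARNING (1):", rep@letter, fixed = TRUE)))
  expect_true(any(grepl("clashscore: 42.0", rep@letter, fixed = TRUE)))
  # deterministic order: locus A:1 before A:2
  i1 <- grep("A:1", rep@letter, fixed = TRUE)
  i2 <- grep("A:2", rep@letter, fixed = TRUE)
  expect_lt(i1, i2)
  clean <- compileReport(emptyFindings())
  expect_identical(clean@status, "ok")
  expect_true(any(grepl("No outstanding issues", clean@letter)))
})
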