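# Minimal PDBx/mmCIF-subset reader and writer.
#
# Supported constructs: one data_ block, key-value pairs
# (_category.item value), loop_ headers with whitespace-separated rows,
# single- and double-quoted values, '#' comments and multi-line
# semicolon-delimited text fields. This is deliberately a subset: no DDL2,
# no save frames, no multiple data blocks.

.tokenizeCifLine <- function(line) {
  toks <- character(0)
  i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1; next }
    if (ch == "#") break
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= n && !(substr(line, j, j) == ch &&
                         (j == n || substr(line, j + 1, j + 1) %in% c(" ", "\t"))))
        j <- j + 1
      toks <- c(toks, substr(line, i + 1, j - 1))
      i <- j + 2
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1
      toks <- c(toks, substr(line, i, j - 1))
      i <- j
    }
  }
  toks
}

# Turn the file into a flat token stream. Semicolon text blocks become one
# token each; '#' comments are stripped.
.cifTokens <- function(lines) {
  toks <- character(0)
  i <- 1; n <- length(lines)
  while (i <= n) {
    if (startsWith(lines[i], ";")) {
      buf <- substring(lines[i], 2); i <- i + 1
      body <- character(0)
      while (i <= n && !startsWith(lines[i], ";")) {
        body <- c(body, lines[i]); i <- i + 1
      }
      if (i > n) .stopf("minidepParseError", "unterminated ';' block")
      parts <- c(if (nzchar(buf)) buf, body)
      toks <- c(toks, paste(parts, collapse = "\n"))
      i <- i + 1
    } else {
      toks <- c(toks, .tokenizeCifLine(lines[i]))
      i <- i + 1
    }
  }
  toks
}

#' Read a data block from an mmCIF-subset file
#'
#' @param path file path (or lines via \code{text}).
#' @param text optional character vector of lines.
#' @return A \linkS4class{DataBlock}.
#' @export
readMmcif <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  toks <- .cifTokens(lines)
  blockId <- "block"
  loops <- list()   # category -> list(items = shorts, rows = list of char vecs)
  kv <- list()      # category -> named character
  p <- 1; n <- length(toks)
  isName <- function(t) startsWith(t, "_") && grepl("\\.", t)
  while (p <= n) {
    tok <- toks[p]
    if (startsWith(tok, "data_")) {
      blockId <- substring(tok, 6); p <- p + 1
    } else if (tok == "loop_") {
      p <- p + 1
      items <- character(0)
      while (p <= n && isName(toks[p])) { items <- c(items, toks[p]); p <- p + 1 }
      if (!length(items)) .stopf("minidepParseError", "loop_ without items")
      cat <- sub("^_([^.]+)\\..*$", "\\1", items[1])
      shorts <- sub("^_[^.]+\\.", "", items)
      if (is.null(loops[[cat]])) loops[[cat]] <- list(items = shorts, rows = list())
      while (p <= n && !isName(toks[p]) && toks[p] != "loop_" &&
             !startsWith(toks[p], "data_")) {
        if (p + length(items) - 1 > n)
          .stopf("minidepParseError", "truncated loop row in category %s", cat)
        loops[[cat]]$rows <- c(loops[[cat]]$rows,
                               list(toks[p:(p + length(items) - 1)]))
        p <- p + length(items)
      }
    } else if (isName(tok)) {
      if (p + 1 > n)
        .stopf("minidepParseError", "item %s without a value", tok)
      cat <- sub("^_([^.]+)\\..*$", "\\1", tok)
      short <- sub("^_[^.]+\\.", "", tok)
      kv[[cat]] <- c(kv[[cat]], stats::setNames(toks[p + 1], short))
      p <- p + 2
    } else {
      .stopf("minidepParseError", "unexpected token '%s'", tok)
    }
  }
  tables <- list()
  for (cat in names(loops)) {
    it <- loops[[cat]]$items
    rows <- loops[[cat]]$rows
    tb <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    if (!length(rows))
      tb <- as.data.frame(matrix(character(0), 0, length(it)),
                          stringsAsFactors = FALSE)
    names(tb) <- it
    tables[[cat]] <- tb
  }
  for (cat in names(kv)) {
    tb <- as.data.frame(as.list(kv[[cat]]), stringsAsFactors = FALSE,
                        check.names = FALSE)
    if (cat %in% names(tables))
      .stopf("minidepParseError",
             "category %s given both as loop_ and key-value", cat)
    tables[[cat]] <- tb
  }
  new("DataBlock", blockId = blockId, tables = tables)
}

.cifQuote <- function(v) {
  vapply(v, function(x) {
    if (!nzchar(x)) return("?")
    if (grepl("[ '\"]", x) || x == "loop_" || startsWith(x, "_") ||
        startsWith(x, "data_") || startsWith(x, "#"))
      paste0("'", gsub("'", "\"", x), "'")
    else x
  }, character(1), USE.NAMES = FALSE)
}

#' Write a data block to an mmCIF-subset file
#'
#' Categories are written in stored order; every category is emitted as a
#' loop_ with a canonical item order (the stored column order). Values
#' containing newlines use semicolon blocks.
#'
#' @param block a \linkS4class{DataBlock}.
#' @param path output path; when NULL the lines are returned.
#' @return The lines, invisibly when written to a file.
#' @export
writeMmcif <- function(block, path = NULL) {
  out <- paste0("data_", block@blockId)
  for (cat in names(block@tables)) {
    tb <- block@tables[[cat]]
    if (!nrow(tb)) next
    out <- c(out, "#", "loop_", sprintf("_%s.%s", cat, names(tb)))
    for (r in seq_len(nrow(tb))) {
      vals <- vapply(names(tb), function(m) tb[[m]][r], character(1))
      line <- character(0)
      for (v in vals) {
        if (grepl("\n", v)) {
          if (length(line)) {
            out <- c(out, paste(line, collapse = " ")); line <- character(0)
          }
          out <- c(out, paste0(";", v), ";")
        } else line <- c(line, .cifQuote(v))
      }
      if (length(line)) out <- c(out, paste(line, collapse = " "))
    }
  }
  out <- c(out, "#")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}
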