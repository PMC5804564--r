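# Flat schema dialect: one record per line.
#
# Grammar (documented; '#' starts a comment, blank lines ignored):
#   version <string>
#   category <name> [key=<item>[,<item>...]]
#   item <category>.<item> type=<text|int|float|enum|date> [mandatory=yes|no]
#        [enum="v1|v2|..."] [hard=<lo>:<hi>] [soft=<lo>:<hi>]
#        [parent=<category>.<item>]
# Categories must be declared before their items. Values containing spaces
# are double-quoted. The writer emits records in stored order, so
# load -> serialize -> load is the identity.

.splitSchemaTokens <- function(line) {
  toks <- character(0); buf <- ""; inq <- FALSE
  for (ch in strsplit(line, "")[[1]]) {
    if (ch == '"') { inq <- !inq }
    else if (ch == " " && !inq) {
      if (nzchar(buf)) { toks <- c(toks, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  if (inq) return(NULL)
  if (nzchar(buf)) toks <- c(toks, buf)
  toks
}

.schemaKv <- function(toks) {
  kv <- list()
  for (t in toks) {
    m <- regmatches(t, regexec("^([A-Za-z_]+)=(.*)$", t))[[1]]
    if (length(m) != 3) return(NULL)
    kv[[m[2]]] <- m[3]
  }
  kv
}

.parseRange <- function(s, line) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  v <- suppressWarnings(as.numeric(parts))
  if (length(v) != 2 || any(is.na(v)))
    .stopf("minidepParseError", "line %d: bad range '%s'", line, s)
  v
}

#' Load a validation dictionary from the flat schema dialect
#'
#' Parses the packaged line-oriented schema format (one record per item)
#' into a \linkS4class{DictionarySchema}. Malformed lines raise a parse
#' error naming the offending line; a parent reference to an item that
#' does not exist raises a schema error.
#'
#' @param path path to a schema file, or a character vector of lines via
#'   \code{text}.
#' @param text optional character vector of schema lines (overrides
#'   \code{path}).
#' @return A \linkS4class{DictionarySchema}.
#' @seealso \code{\link{writeSchema}}, \code{\link{validateBlock}}
#' @export
#' @examples
#' sch <- loadSchema(minidepSchemaFile("core"))
#' length(schemaCategories(sch))
loadSchema <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  version <- "1"
  cats <- list()       # name -> list(keyItems, items)
  order <- character(0)
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    toks <- .splitSchemaTokens(raw)
    if (is.null(toks))
      .stopf("minidepParseError", "line %d: unterminated quote", ln)
    kind <- toks[1]
    if (kind == "version") {
      if (length(toks) != 2)
        .stopf("minidepParseError", "line %d: version takes one value", ln)
      version <- toks[2]
    } else if (kind == "category") {
      if (length(toks) < 2)
        .stopf("minidepParseError", "line %d: category needs a name", ln)
      nm <- toks[2]
      kv <- .schemaKv(toks[-(1:2)])
      if (is.null(kv))
        .stopf("minidepParseError", "line %d: bad attribute", ln)
      keys <- if (!is.null(kv$key)) strsplit(kv$key, ",", fixed = TRUE)[[1]]
              else character(0)
      cats[[nm]] <- list(keyItems = keys, items = list())
      order <- c(order, nm)
    } else if (kind == "item") {
      if (length(toks) < 3)
        .stopf("minidepParseError", "line %d: item needs name and type", ln)
      nm <- toks[2]
      cat <- sub("\\..*$", "", nm)
      if (!cat %in% names(cats))
        .stopf("minidepParseError",
               "line %d: item '%s' before its category declaration", ln, nm)
      kv <- .schemaKv(toks[-(1:2)])
      if (is.null(kv) || is.null(kv$type))
        .stopf("minidepParseError", "line %d: item needs type=", ln)
      item <- new("ItemDef", name = nm, typeCode = kv$type,
                  mandatory = identical(kv$mandatory, "yes"),
                  enumeration = if (!is.null(kv$enum))
                    strsplit(kv$enum, "|", fixed = TRUE)[[1]] else character(0),
                  hardRange = if (!is.null(kv$hard)) .parseRange(kv$hard, ln)
                              else numeric(0),
                  softRange = if (!is.null(kv$soft)) .parseRange(kv$soft, ln)
                              else numeric(0),
                  parent = if (!is.null(kv$parent)) kv$parent else character(0))
      cats[[cat]]$items <- c(cats[[cat]]$items, item)
    } else {
      .stopf("minidepParseError", "line %d: unknown record '%s'", ln, kind)
    }
  }
  categories <- lapply(order, function(nm)
    new("CategoryDef", name = nm, keyItems = cats[[nm]]$keyItems,
        items = cats[[nm]]$items))
  names(categories) <- order
  schema <- new("DictionarySchema", categories = categories, version = version)
  err <- validObject(schema, test = TRUE)
  if (is.character(err))
    .stopf("minidepSchemaError", "invalid schema: %s",
           paste(err, collapse = "; "))
  schema
}

.quoteIfNeeded <- function(s) {
  if (grepl("[ \"]", s)) paste0('"', s, '"') else s
}

#' Serialize a validation dictionary to the flat schema dialect
#'
#' @param schema a \linkS4class{DictionarySchema}.
#' @param path optional output file; when NULL the lines are returned.
#' @return The schema lines, invisibly when written to a file.
#' @export
writeSchema <- function(schema, path = NULL) {
  lines <- sprintf("version %s", schema@version)
  for (cat in schema@categories) {
    hdr <- paste("category", cat@name)
    if (length(cat@keyItems))
      hdr <- paste0(hdr, " key=", paste(cat@keyItems, collapse = ","))
    lines <- c(lines, hdr)
    for (it in cat@items) {
      rec <- sprintf("item %s type=%s", it@name, it@typeCode)
      if (it@mandatory) rec <- paste0(rec, " mandatory=yes")
      if (length(it@enumeration))
        rec <- paste0(rec, " enum=",
                      .quoteIfNeeded(paste(it@enumeration, collapse = "|")))
      if (length(it@hardRange))
        rec <- paste0(rec, sprintf(" hard=%.15g:%.15g",
                                   it@hardRange[1], it@hardRange[2]))
      if (length(it@softRange))
        rec <- paste0(rec, sprintf(" soft=%.15g:%.15g",
                                   it@softRange[1], it@softRange[2]))
      if (length(it@parent)) rec <- paste0(rec, " parent=", it@parent)
      lines <- c(lines, rec)
    }
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Packaged schema files
#'
#' \code{"core"} is the compact seven-category dictionary (entity,
#' entity_poly, entity_src_gen, atom_site, cell, symmetry, reflns);
#' \code{"deposition"} extends it with the extra categories a full
#' deposition carries (experiment metadata, radiation wavelength, assembly
#' operators, depositor declarations).
#'
#' @param which \code{"core"} or \code{"deposition"}.
#' @return Path to the packaged schema file.
#' @export
minidepSchemaFile <- function(which = c("core", "deposition")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, "_schema.txt"), package = "minidep",
              mustWork = TRUE)
}

# Look up an ItemDef by full name; NULL when absent.
.schemaItem <- function(schema, name) {
  cat <- sub("\\..*$", "", name)
  cd <- schema@categories[[cat]]
  if (is.null(cd)) return(NULL)
  for (it in cd@items) if (it@name == name) return(it)
  NULL
}
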