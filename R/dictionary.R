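# Dictionary-driven validation of data blocks: types, mandatory items,
# enumerations, hard/soft numeric limits, parent/child key integrity.

.isNullValue <- function(v) v %in% c("?", ".") | !nzchar(v)

.parseNumeric <- function(v) suppressWarnings(as.numeric(v))

#' Validate a numeric value against an item's hard and soft limits
#'
#' Hard limits mark values that are physically impossible (an error); soft
#' limits mark values that are statistically unusual (a warning). The two
#' checks partition the real line: a finite value yields exactly one of
#' no finding, a soft_range warning, or a hard_range error. The classic
#' worked case is the merging R value (Rmerge), whose soft limits are
#' 0.01-0.2: 0.7 or 13 draw a warning where 0.13 passes silently.
#'
#' @param value a numeric value, or a string to be typed first.
#' @param item an \linkS4class{ItemDef} with numeric type.
#' @return \code{NULL} when the value is inside all limits, otherwise a
#'   one-row findings data.frame (type_violation if the string is not
#'   numeric).
#' @export
#' @examples
#' rmerge <- new("ItemDef", name = "reflns.pdbx_Rmerge_I_obs",
#'               typeCode = "float", softRange = c(0.01, 0.2))
#' checkRange(0.7, rmerge)$code    # soft_range
#' is.null(checkRange(0.13, rmerge))
checkRange <- function(value, item) {
  stopifnot(is(item, "ItemDef"))
  if (!item@typeCode %in% c("int", "float"))
    .stopf("minidepTypeError", "item '%s' is not numeric", item@name)
  if (is.character(value)) {
    num <- .parseNumeric(value)
    if (is.na(num))
      return(finding("type_violation",
                     sprintf("value '%s' of %s is not numeric", value,
                             item@name), item = item@name))
    value <- num
  }
  if (length(item@hardRange) &&
      (value < item@hardRange[1] || value > item@hardRange[2]))
    return(finding("hard_range",
                   sprintf("%s = %g outside hard limits [%g, %g]",
                           item@name, value, item@hardRange[1],
                           item@hardRange[2]), item = item@name))
  if (length(item@softRange) &&
      (value < item@softRange[1] || value > item@softRange[2]))
    return(finding("soft_range",
                   sprintf("%s = %g outside soft limits [%g, %g]",
                           item@name, value, item@softRange[1],
                           item@softRange[2]), item = item@name))
  NULL
}

#' Derive soft limits from an observed distribution
#'
#' Soft limits for approximately normal archive distributions are placed
#' k sample standard deviations either side of the mean (k = 3 by
#' convention: values more than three standard deviations from the mean
#' are reported as outliers).
#'
#' @param samples numeric vector of at least two finite observations.
#' @param k width in standard deviations (default 3).
#' @return c(lo, hi) = mean -/+ k * sd (n-1 denominator).
#' @export
#' @examples
#' deriveSoftLimits(c(0.11, 0.13, 0.15))  # (0.07, 0.19)
deriveSoftLimits <- function(samples, k = 3) {
  if (length(samples) < 2 || !all(is.finite(samples)))
    .stopf("minidepInsufficientData",
           "need at least 2 finite samples to derive soft limits")
  m <- mean(samples); s <- stats::sd(samples)
  c(m - k * s, m + k * s)
}

.typeFinding <- function(item, value, row) {
  locus <- sprintf("%s[%d]", sub("\\..*$", "", item@name), row)
  if (item@typeCode %in% c("int", "float")) {
    num <- .parseNumeric(value)
    if (is.na(num))
      return(finding("type_violation",
                     sprintf("'%s' is not a valid %s for %s", value,
                             item@typeCode, item@name),
                     item = item@name, locus = locus))
    if (item@typeCode == "int" && num != round(num))
      return(finding("type_violation",
                     sprintf("'%s' is not an integer for %s", value,
                             item@name), item = item@name, locus = locus))
    f <- checkRange(num, item)
    if (!is.null(f)) { f$locus <- locus; return(f) }
  } else if (item@typeCode == "enum") {
    if (!value %in% item@enumeration)
      return(finding("enum_violation",
                     sprintf("'%s' is not in the enumeration of %s", value,
                             item@name), item = item@name, locus = locus))
  } else if (item@typeCode == "date") {
    d <- tryCatch(as.Date(value), error = function(e) NA)
    if (is.na(d))
      return(finding("type_violation",
                     sprintf("'%s' is not an ISO date for %s", value,
                             item@name), item = item@name, locus = locus))
  }
  NULL
}

#' Check parent/child key integrity of a data block
#'
#' Emits one key_integrity error for every child row whose parent-key value
#' has no matching parent row, and a key_integrity error on a parent
#' category whose (composite) key values are duplicated.
#'
#' @param block a \linkS4class{DataBlock}.
#' @param schema a \linkS4class{DictionarySchema}.
#' @return A findings data.frame.
#' @export
checkKeys <- function(block, schema) {
  out <- list()
  # duplicate composite keys on parent categories
  for (catName in names(schema@categories)) {
    tb <- block@tables[[catName]]
    cd <- schema@categories[[catName]]
    if (is.null(tb) || !nrow(tb) || !length(cd@keyItems)) next
    if (!all(cd@keyItems %in% names(tb))) next
    key <- do.call(paste, c(tb[cd@keyItems], sep = "\r"))
    dup <- unique(key[duplicated(key)])
    for (d in dup)
      out <- c(out, list(finding(
        "key_integrity",
        sprintf("duplicate key value '%s' in category %s",
                gsub("\r", "+", d), catName),
        locus = catName)))
  }
  # child values must reference an existing parent row
  for (catName in names(schema@categories)) {
    tb <- block@tables[[catName]]
    if (is.null(tb) || !nrow(tb)) next
    for (it in schema@categories[[catName]]@items) {
      if (!length(it@parent)) next
      short <- sub("^[^.]+\\.", "", it@name)
      if (!short %in% names(tb)) next
      pCat <- sub("\\..*$", "", it@parent)
      pShort <- sub("^[^.]+\\.", "", it@parent)
      pTab <- block@tables[[pCat]]
      parentVals <- if (!is.null(pTab) && pShort %in% names(pTab))
        pTab[[pShort]] else character(0)
      vals <- tb[[short]]
      for (r in seq_along(vals)) {
        if (.isNullValue(vals[r])) next
        if (!vals[r] %in% parentVals)
          out <- c(out, list(finding(
            "key_integrity",
            sprintf("%s = '%s' has no matching row in %s", it@name,
                    vals[r], pCat),
            item = it@name, locus = sprintf("%s[%d]", catName, r))))
      }
    }
  }
  .bindFindingsList(out)
}

#' Validate a data block against a dictionary
#'
#' Applies every dictionary rule to the block: missing mandatory items,
#' type violations, enumeration violations, hard/soft range violations and
#' parent/child key integrity. Null values ("?" unknown, "." inapplicable)
#' skip typing and range checks but count as missing for mandatory items.
#' The finding order is deterministic: categories in schema order, then
#' row, then item; unknown categories are reported last in block order.
#' An empty return means the block is fully conformant.
#'
#' @param block a \linkS4class{DataBlock}.
#' @param schema a \linkS4class{DictionarySchema}.
#' @return A findings data.frame.
#' @export
#' @examples
#' sch <- loadSchema(minidepSchemaFile("core"))
#' blk <- makeTable1Block()
#' nrow(validateBlock(blk, sch))  # 0
validateBlock <- function(block, schema) {
  out <- list()
  for (catName in names(schema@categories)) {
    tb <- block@tables[[catName]]
    if (is.null(tb) || !nrow(tb)) next
    cd <- schema@categories[[catName]]
    itemNames <- vapply(cd@items, function(i) i@name, character(1))
    shorts <- sub("^[^.]+\\.", "", itemNames)
    # mandatory items missing entirely from the table
    for (k in seq_along(cd@items)) {
      it <- cd@items[[k]]
      if (it@mandatory && !shorts[k] %in% names(tb))
        out <- c(out, list(finding(
          "missing_mandatory",
          sprintf("mandatory item %s absent from category %s", it@name,
                  catName), item = it@name, locus = catName)))
    }
    for (r in seq_len(nrow(tb))) {
      for (k in seq_along(cd@items)) {
        it <- cd@items[[k]]
        if (!shorts[k] %in% names(tb)) next
        val <- tb[[shorts[k]]][r]
        if (.isNullValue(val)) {
          if (it@mandatory)
            out <- c(out, list(finding(
              "missing_mandatory",
              sprintf("mandatory item %s is null in row %d", it@name, r),
              item = it@name, locus = sprintf("%s[%d]", catName, r))))
          next
        }
        f <- .typeFinding(it, val, r)
        if (!is.null(f)) out <- c(out, list(f))
      }
    }
  }
  for (catName in setdiff(names(block@tables), names(schema@categories))) {
    out <- c(out, list(finding(
      "unknown_category",
      sprintf("category %s is not defined in the dictionary", catName),
      locus = catName)))
  }
  .bindFindings(.bindFindingsList(out), checkKeys(block, schema))
}
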