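# Conversion between the tabular DataBlock form and the Deposition object,
# plus typed accessors for cell, symmetry and depositor declarations.

.atomSiteCols <- c(id = "id", chain = "auth_asym_id", seqNum = "auth_seq_id",
                   compId = "label_comp_id", atomName = "label_atom_id",
                   element = "type_symbol", x = "Cartn_x", y = "Cartn_y",
                   z = "Cartn_z", occupancy = "occupancy",
                   bFactor = "B_iso_or_equiv", altId = "label_alt_id")

#' Convert a data block into a Deposition
#'
#' Pulls atom records from atom_site, sample sequences from entity_poly
#' (pdbx_seq_one_letter_code keyed to chains by pdbx_strand_id), assembly
#' operators from pdbx_struct_oper_list and depositor declarations from the
#' minidep_declaration category; all remaining categories stay in the
#' metadata block.
#'
#' @param block a \linkS4class{DataBlock}.
#' @return A \linkS4class{Deposition}.
#' @export
blockToDeposition <- function(block) {
  tabs <- block@tables
  as <- tabs[["atom_site"]]
  if (is.null(as)) .stopf("minidepParseError", "deposition lacks atom_site")
  atoms <- data.frame(
    chain = as[[.atomSiteCols["chain"]]],
    seqNum = as.integer(as[[.atomSiteCols["seqNum"]]]),
    compId = as[[.atomSiteCols["compId"]]],
    atomName = as[[.atomSiteCols["atomName"]]],
    element = as[[.atomSiteCols["element"]]],
    x = as.numeric(as[[.atomSiteCols["x"]]]),
    y = as.numeric(as[[.atomSiteCols["y"]]]),
    z = as.numeric(as[[.atomSiteCols["z"]]]),
    occupancy = as.numeric(as[[.atomSiteCols["occupancy"]]]),
    bFactor = as.numeric(as[[.atomSiteCols["bFactor"]]]),
    altId = ifelse(.isNullValue(as[[.atomSiteCols["altId"]]]), NA_character_,
                   as[[.atomSiteCols["altId"]]]),
    stringsAsFactors = FALSE)
  seqs <- character(0)
  ep <- tabs[["entity_poly"]]
  if (!is.null(ep) && "pdbx_strand_id" %in% names(ep)) {
    for (r in seq_len(nrow(ep))) {
      if (.isNullValue(ep$pdbx_seq_one_letter_code[r])) next
      s <- gsub("[\n ]", "", ep$pdbx_seq_one_letter_code[r])
      for (ch in strsplit(ep$pdbx_strand_id[r], ",", fixed = TRUE)[[1]])
        seqs[trimws(ch)] <- s
    }
  }
  ops <- list()
  ol <- tabs[["pdbx_struct_oper_list"]]
  if (!is.null(ol)) {
    for (r in seq_len(nrow(ol))) {
      R <- matrix(as.numeric(c(
        ol[["matrix[1][1]"]][r], ol[["matrix[1][2]"]][r], ol[["matrix[1][3]"]][r],
        ol[["matrix[2][1]"]][r], ol[["matrix[2][2]"]][r], ol[["matrix[2][3]"]][r],
        ol[["matrix[3][1]"]][r], ol[["matrix[3][2]"]][r], ol[["matrix[3][3]"]][r])),
        3, 3, byrow = TRUE)
      t <- as.numeric(c(ol[["vector[1]"]][r], ol[["vector[2]"]][r],
                        ol[["vector[3]"]][r]))
      ops[[length(ops) + 1]] <- list(id = ol$id[r], R = R, t = t)
    }
  }
  decl <- list()
  dt <- tabs[["minidep_declaration"]]
  if (!is.null(dt)) {
    for (k in unique(dt$kind))
      decl[[k]] <- dt$value[dt$kind == k]
  }
  meta <- tabs[setdiff(names(tabs), "atom_site")]
  new("Deposition", depId = block@blockId, atoms = atoms,
      sampleSequences = seqs,
      metadata = new("DataBlock", blockId = block@blockId, tables = meta),
      assemblyOps = ops, declarations = decl)
}

#' Convert a Deposition back into a data block
#'
#' @param dep a \linkS4class{Deposition}.
#' @return A \linkS4class{DataBlock} with atom_site rebuilt from the atom
#'   records and all metadata categories preserved.
#' @export
depositionToBlock <- function(dep) {
  a <- dep@atoms
  fmt <- function(v) formatC(v, format = "fg", digits = 15)
  as <- data.frame(
    id = as.character(seq_len(nrow(a))),
    auth_asym_id = a$chain,
    auth_seq_id = as.character(a$seqNum),
    label_comp_id = a$compId,
    label_atom_id = a$atomName,
    type_symbol = a$element,
    Cartn_x = fmt(a$x), Cartn_y = fmt(a$y), Cartn_z = fmt(a$z),
    occupancy = fmt(a$occupancy),
    B_iso_or_equiv = fmt(a$bFactor),
    label_alt_id = ifelse(is.na(a$altId), ".", a$altId),
    stringsAsFactors = FALSE)
  tabs <- c(dep@metadata@tables, list(atom_site = as))
  new("DataBlock", blockId = dep@depId, tables = tabs)
}

#' Read / write a deposition file
#'
#' @param path an mmCIF-subset deposition file.
#' @return \code{readDeposition}: a \linkS4class{Deposition}.
#' @export
readDeposition <- function(path) blockToDeposition(readMmcif(path))

#' @rdname readDeposition
#' @param dep a \linkS4class{Deposition}.
#' @export
writeDeposition <- function(dep, path) {
  writeMmcif(depositionToBlock(dep), path)
  invisible(path)
}

# Typed cell parameters from the metadata block; NULL when absent.
.getCell <- function(dep) {
  tb <- dep@metadata@tables[["cell"]]
  if (is.null(tb) || !nrow(tb)) return(NULL)
  list(a = as.numeric(tb$length_a[1]), b = as.numeric(tb$length_b[1]),
       c = as.numeric(tb$length_c[1]), alpha = as.numeric(tb$angle_alpha[1]),
       beta = as.numeric(tb$angle_beta[1]), gamma = as.numeric(tb$angle_gamma[1]))
}

.getSpaceGroup <- function(dep) {
  tb <- dep@metadata@tables[["symmetry"]]
  if (is.null(tb) || !nrow(tb)) return(NULL)
  tb[["space_group_name_H-M"]][1]
}

.getMethod <- function(dep) {
  tb <- dep@metadata@tables[["exptl"]]
  if (is.null(tb) || !nrow(tb)) return(NA_character_)
  tb$method[1]
}

.metaValue <- function(dep, category, item) {
  tb <- dep@metadata@tables[[category]]
  if (is.null(tb) || !nrow(tb) || !item %in% names(tb)) return(NA_character_)
  tb[[item]][1]
}
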