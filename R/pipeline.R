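# End-to-end biocuration pipeline: drives the six workflow stages over a
# deposition and compiles the depositor report.

# consistency checks on source metadata (Table 3 "Missing and/or
# inconsistent metadata values")
.metadataConsistency <- function(dep) {
  out <- emptyFindings()
  tabs <- dep@metadata@tables
  src <- tabs$entity_src_gen
  if (!is.null(src)) {
    for (k in seq_len(nrow(src))) {
      for (fld in c("pdbx_gene_src_ncbi_taxonomy_id",
                    "pdbx_host_org_ncbi_taxonomy_id")) {
        nameFld <- sub("_ncbi_taxonomy_id", "_scientific_name", fld)
        val <- src[[fld]][k]
        nm <- if (!is.null(src[[nameFld]])) src[[nameFld]][k] else NA
        if ((is.null(val) || is.na(val) || .isNullValue(val)) &&
            !is.null(nm) && !is.na(nm) && !.isNullValue(nm)) {
          out <- .bindFindings(out, finding(
            "Missing and/or inconsistent metadata values",
            sprintf("source organism '%s' is named but %s is missing",
                    nm, fld),
            item = paste0("entity_src_gen.", fld),
            locus = sprintf("entity_src_gen[%d]", k)))
        }
      }
    }
  }
  out
}

# ligand stage: identify every non-polymer, non-water residue against the
# component dictionary
.curateLigands <- function(dep, ccd) {
  out <- emptyFindings()
  atoms <- dep@atoms
  isWater <- atoms$compId %in% .waterComps
  isPoly <- .isPolymerComp(atoms$compId)
  het <- atoms[!isWater & !isPoly, , drop = FALSE]
  if (!nrow(het)) return(list(findings = out, identified = character(0)))
  keys <- unique(paste(het$chain, het$seqNum, sep = ":"))
  identified <- character(0)
  declared <- dep@declarations$declared_ligand
  for (key in keys) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    res <- het[het$chain == parts[1] & het$seqNum == as.integer(parts[2]), ,
               drop = FALSE]
    g <- perceiveGraph(res, locus = key)
    hits <- searchCcd(g, ccd, top = 1)
    if (!length(hits)) {
      newId <- if (res$compId[1] %in% names(ccd)) "UNL" else res$compId[1]
      reg <- registerComponent(g, proposedId = newId, ccd = ccd)
      ccd <- reg$ccd
      identified <- c(identified, newId)
      next
    }
    hit <- hits[[1]]
    identified <- c(identified, hit@compId)
    if (hit@score < 1) {
      out <- .bindFindings(out, finding(
        "ligand_partial_match",
        sprintf("residue %s matches component %s with score %.2f (missing: %s)",
                key, hit@compId, hit@score,
                paste(hit@unmatchedComponentAtoms, collapse = ", ")),
        locus = key))
    } else {
      out <- .bindFindings(out,
                           checkChirality(res, ccd[[hit@compId]],
                                          hit@mapping))
    }
    if (!is.null(declared) && !identical(declared, hit@compId)) {
      out <- .bindFindings(out, finding(
        "Ligand identity",
        sprintf("residue %s was deposited as %s but matches component %s",
                key, declared, hit@compId), locus = key))
    }
  }
  list(findings = out, identified = unique(identified))
}

# sequence stage for one polymer chain
.curateChainSequence <- function(dep, chain, refdb) {
  sample <- dep@sampleSequences[[chain]]
  chainAtoms <- dep@atoms[dep@atoms$chain == chain &
                            .isPolymerComp(dep@atoms$compId), , drop = FALSE]
  cs <- deriveCoordSequence(chainAtoms, sample)
  out <- cs$findings
  annotations <- NULL
  segments <- NULL
  if (!is.null(refdb) && nrow(refdb)) {
    seg <- segmentChimera(sample, refdb)
    if (seg$chimeric) {
      out <- .bindFindings(out, seg$findings)
      segments <- seg$segments
    } else {
      hits <- searchReferences(sample, refdb)
      if (nrow(hits)) {
        ref <- refdb[refdb$accession == hits$accession[1], , drop = FALSE]
        rec <- reconcileSequences(sample, cs$coordSeq, ref,
                                  declarations = dep@declarations)
        out <- .bindFindings(out, rec$findings)
        annotations <- rec$annotations
      }
    }
  }
  list(findings = out, annotations = annotations, segments = segments)
}

#' Run the full biocuration pipeline over a deposition
#'
#' Drives the six workflow stages in order. Entity: dictionary validation
#' of the deposited block, entity construction, source-metadata
#' consistency. Ligand: graph perception, component identification,
#' declared-identity and chirality checks. Sequence: coordinate-sequence
#' derivation, chimera segmentation, reference reconciliation. Annotation:
#' water repositioning, link generation, hetero renumbering, secondary
#' structure, assembly construction and the reported-vs-calculated
#' quaternary structure check. Validation: geometry/occupancy/metadata
#' checks plus the structure-factor completeness check. Communication:
#' the compiled report bundle.
#'
#' @param dep a \linkS4class{Deposition}.
#' @param ccd chemical component dictionary (named list of
#'   \linkS4class{ChemComp}).
#' @param refdb reference sequence data.frame from \code{\link{readRefDb}}
#'   or \code{\link{makeRefDb}} (NULL to skip reference work).
#' @param schema validation dictionary; default the packaged deposition
#'   schema.
#' @param completenessMin minimum acceptable reflection completeness (%).
#' @return list(report, workflow, deposition, annotations, segments,
#'   entities, heteroMap, findings).
#' @export
curateDeposition <- function(dep, ccd = makeMiniCcd(), refdb = NULL,
                             schema = loadSchema(
                               minidepSchemaFile("deposition")),
                             completenessMin = 90) {
  wf <- newWorkflow()
  all <- list()
  step <- function(module, fun) {
    wf <<- advanceWorkflow(wf, module, "start")
    res <- fun()
    wf <<- advanceWorkflow(wf, module, "complete")
    res
  }

  # --- entity
  entities <- NULL
  step("entity", function() {
    all[[length(all) + 1]] <<- validateBlock(depositionToBlock(dep), schema)
    ents <- buildEntities(dep)
    entities <<- ents$entities
    all[[length(all) + 1]] <<- ents$findings
    all[[length(all) + 1]] <<- .metadataConsistency(dep)
    NULL
  })

  # --- ligand
  step("ligand", function() {
    lig <- .curateLigands(dep, ccd)
    all[[length(all) + 1]] <<- lig$findings
    NULL
  })

  # --- sequence
  annotations <- list(); segments <- list()
  step("sequence", function() {
    for (chain in names(dep@sampleSequences)) {
      res <- .curateChainSequence(dep, chain, refdb)
      all[[length(all) + 1]] <<- res$findings
      if (!is.null(res$annotations)) annotations[[chain]] <<- res$annotations
      if (!is.null(res$segments)) segments[[chain]] <<- res$segments
    }
    NULL
  })

  # --- annotation
  heteroMap <- NULL
  step("annotation", function() {
    rw <- repositionWaters(dep)
    dep <<- rw$deposition
    all[[length(all) + 1]] <<- rw$findings
    generateLinks(dep)
    rn <- renumberHeteros(dep)
    dep <<- rn$deposition
    heteroMap <<- rn$map
    for (chain in names(dep@sampleSequences)) {
      chainAtoms <- dep@atoms[dep@atoms$chain == chain &
                                .isPolymerComp(dep@atoms$compId), ,
                              drop = FALSE]
      ss <- assignSecondaryStructure(chainAtoms)
      all[[length(all) + 1]] <<- ss$findings
    }
    asm <- buildAssembly(dep)
    declared <- dep@declarations$oligomeric_count
    if (!is.null(declared)) {
      calc <- sum(asm$stoichiometry$copies[
        asm$stoichiometry$chain %in% names(dep@sampleSequences)])
      if (calc != suppressWarnings(as.integer(declared)) ||
          is.na(suppressWarnings(as.integer(declared)))) {
        all[[length(all) + 1]] <<- finding(
          "Reported and calculated quaternary structure do not agree",
          sprintf("declared oligomeric count %s but the assembly contains %d polymer chain(s)",
                  declared, calc), locus = "assembly")
      }
    }
    NULL
  })

  # --- validation
  step("validation", function() {
    all[[length(all) + 1]] <<- extendedChecks(dep, ccd = ccd)
    compl <- suppressWarnings(
      as.numeric(.metaValue(dep, "reflns", "pdbx_completeness")))
    if (!is.na(compl) && compl < completenessMin) {
      all[[length(all) + 1]] <<- finding(
        "Incomplete data in the structure factors",
        sprintf("reflection completeness %s%% is below the %s%% minimum",
                compl, completenessMin),
        item = "reflns.pdbx_completeness",
        locus = "reflns.pdbx_completeness")
    }
    NULL
  })

  # --- communication
  findings <- .bindFindingsList(all)
  report <- step("communication", function()
    compileReport(findings, depId = dep@depId))

  list(report = report, workflow = wf, deposition = dep,
       annotations = annotations, segments = segments, entities = entities,
       heteroMap = heteroMap, findings = findings)
}
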