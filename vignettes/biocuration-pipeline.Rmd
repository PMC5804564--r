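---
title: "The minidep biocuration pipeline: methods"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The minidep biocuration pipeline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minidep)
```

# Overview

`minidep` re-creates, at the scale of one protein chain, the curation
pipeline that structural-biology archives run on every incoming
deposition. A deposition here is a small object: atom records, a
depositor sample sequence per polymer chain, free-form depositor
declarations, metadata tables in an mmCIF-style subset, and declared
assembly operators. `curateDeposition()` drives it through six strictly
ordered stages — entity, ligand, sequence, annotation, validation,
communication — under a workflow state machine, collecting findings that
compile into a report and a depositor letter. This vignette documents the
methods behind each stage and the design decisions that make the whole
pipeline testable against independent oracles.

# Dictionary-driven validation

Metadata live in category tables governed by a flat-file dictionary
(`loadSchema()`, packaged as `extdata/core_schema.txt` and
`extdata/deposition_schema.txt`). The dictionary carries per-item types
(`text`, `int`, `float`, `enum`, `date`), mandatory flags, enumerations,
parent/child key relations, and two kinds of numeric limits:

* **hard limits** bound the physically possible; a violation is an
  error;
* **soft limits** bound the statistically usual; a violation is a
  warning.

For a finite value the two checks partition the real line: exactly one of
*no finding*, `soft_range`, or `hard_range` results (`checkRange()`). Soft
limits for approximately normal archive distributions are derived as the
mean plus/minus three sample standard deviations (`deriveSoftLimits()`).
The stored soft range for the merging R value, 0.01–0.2, reproduces the
canonical worked example: candidate values 0.7 and 13 warn, 0.13 passes.

```{r rmerge}
schema <- loadSchema(minidepSchemaFile("core"))
items <- schema@categories[["reflns"]]@items
rmerge <- items[[which(vapply(items, function(i) i@name, character(1)) ==
                         "reflns.pdbx_Rmerge_I_obs")]]
lapply(c(0.7, 13, 0.13), checkRange, item = rmerge)
```

`validateBlock()` applies the full rule set deterministically (categories
in schema order, then row, then item), and `checkKeys()` enforces
composite-key uniqueness on parent categories and referential integrity on
child items.

# Entity transformation

`buildEntities()` classifies each chain's residues from the coordinates
themselves: consecutive residues whose C–N (or O3'–P) distance falls in
the standard linkage window form polymer runs; isolated hetero residues
become non-polymer entities grouped by component id; waters pool into one
water entity. Polymer chains sharing a sample sequence collapse into one
polymer entity with several instances. Breaks and out-of-window linkages
are reported (`detectPolymerLinks()`), and `splitOrMerge()` applies
depositor split/merge intent only where the geometry supports it.
Peptide-like small molecules are matched against a peptide reference
dictionary in either representation: `transformRepresentation()` cuts
peptide C–N bonds so that every fragment is isomorphic to a dictionary
amino acid, which makes the polymer and non-polymer forms of one molecule
resolve to the same PRD id (`matchPrd()`).

# Ligand identification

`perceiveGraph()` turns a hetero residue into an element-labelled graph by
bonding atom pairs within the covalent-radius sum plus a tolerance.
`searchCcd()` matches that instance graph into every dictionary component
by subgraph *monomorphism* (backtracking with element and degree pruning),
so a partially modeled ligand still finds its parent component; the score
is (mapped atoms + mapped bonds) / (component atoms + component bonds),
and exact isomorphism scores 1. Among automorphic mappings the
lexicographically smallest is kept, making results deterministic. Exact
matches get archive-standard atom names (`standardizeAtoms()`) and a
chirality check: for each stereocenter the sign of the triple product of
the vectors to its first three ordered neighbors is compared with the
component's stored parity (`checkChirality()`); near-planar centers are
indeterminate rather than wrong. Graphs matching nothing are registered
as new components (`registerComponent()`), which refuses id collisions and
graphs isomorphic to an existing component.

The property suite pins the matcher to a brute-force enumerator over all
injective, element-preserving assignments on every fixture graph with at
most eight atoms.

# Sequence reconciliation

Three sequences must agree: the depositor sample, the coordinate-derived
sequence (`deriveCoordSequence()`, which also raises "Sequence
discrepancy" errors where the model contradicts the sample), and a
reference found by Smith–Waterman search over the reference database
(`searchReferences()`). `reconcileSequences()` aligns sample to reference
globally with free end gaps (match +2, mismatch −1, a gap of length
*L* costs 5 + *L*) and classifies every difference with a controlled
vocabulary: terminal sample-only spans become *expression tag* (when a
declared range or a known tag motif covers them) or *cloning artifact*;
internal sample-only spans become *linker* or *insertion*; substitutions
become *mutation* (declared), *variant* (known reference variant), or
*conflict* (undeclared, which raises a correspondence request); reference
spans absent from the sample become *deletions*; unmodeled sample
positions are annotated from the coordinate sequence.

Chimeric constructs are segmented by a per-position Viterbi dynamic
program (`segmentChimera()`). Candidate states are ungapped blocks of
local hits; emissions score +2/−1; switching between candidates of the
same reference costs a small gap penalty while switching references costs
`kappa`, including switches bridged through the unassigned state — the
unassigned states carry the last reference as context precisely so that a
cheap detour cannot undercut the switch penalty. Setting `kappa = Inf`
collapses the result to the best single-reference explanation. Unassigned
runs of at most three residues are absorbed into the longer flank; longer
runs are reported. The recovery property (100 seeded plants with
boundary-identifiable junctions, at least 95 recovered exactly) guards the
whole construction.

# Structural annotation

All annotation runs in the crystal frame defined by `cellOrthoMatrix()`
and the space-group operator table (`spaceGroupOps()`, symbolic symop
parsing/rendering round-trips exactly).

* **Solvent repositioning** (`repositionWaters()`): each water is moved to
  the symmetry image (operator × 27 neighbouring cells) nearest the
  polymer; waters already home stay bitwise put, and waters farther than
  5 Å from the polymer in *every* image are flagged "Distant waters".
  The property suite checks the chosen image against an independent
  brute-force search on 50 seeded positions.
* **Link generation** (`generateLinks()`): heavy-atom pairs from
  different residues within covalent range, skipping the standard
  backbone bond.
* **Secondary structure** (`assignSecondaryStructure()`): Kabsch–Sander
  hydrogen-bond energetics (E = 0.084 · 332 · (1/rON + 1/rCH − 1/rOH −
  1/rCN) kcal/mol, bond when E < −0.5) with helix from consecutive
  (i, i+4) turns and strand from bridge ladders.
* **Assemblies** (`buildAssembly()`): every chain is copied under every
  declared operator (orthonormality enforced); the identity operator
  yields bitwise-equal coordinates.
* **Hetero renumbering** (`renumberHeteros()`): ligands and waters attach
  to the polymer chain owning their nearest polymer atom and are numbered
  from 501 and 1001 respectively; the operation is idempotent.
* **Extended checks** (`extendedChecks()`): clashes (van der Waals
  overlap beyond 0.4 Å between non-bonded atoms), occupancy sanity
  including special positions (a water on a two-fold should carry
  occupancy 1/multiplicity), zero B-factors, stray hydrogens, bond-length
  deviations beyond four standard deviations of the reference geometry,
  Ramachandran outliers against permissive helix/sheet boxes, wavelength
  consistency between declared and measured values, free-R presence, and
  completeness.

# Workflow, release policy and reporting

`advanceWorkflow()` implements the stage state machine: a stage starts
only when all predecessors are complete, completes or fails only while
running, and restarting resets the stage and all successors. The test
suite model-checks this exhaustively: every (module, event) pair is
applied in every reachable state and compared against an independent rule
model, with the invariant that a non-pending stage implies fully complete
predecessors.

`planRelease()` encodes the release calendar: a one-year hold
(month-end clamped), reminders three/two/one months before expiry, weekly
release days (Wednesday), publication or depositor request pulling the
release forward to the next release day, withdrawal cancelling release,
and any post-withdrawal event a policy error. `percentileScore()` ranks a
metric against a reference distribution by midrank. `compileReport()`
counts findings by issue code and renders the letter deterministically —
errors, then warnings, then info, each sorted by code, locus and message.

# Fixtures as ground truth

Every input is manufactured by the fixture factory. `buildIdealChain()`
places backbone atoms by natural extension reference frames from exact
bond lengths, angles and torsions, so a helix built at (φ, ψ) =
(−57°, −47°) measures back those torsions to machine precision.
`makeMiniCcd()` provides nine components including stereocenter parities
computed from the ideal coordinates; `makeRefDb()` seeds a five-protein
reference database; `makeTable1Block()` is a clean source-organism
metadata example (host *Escherichia coli*, taxonomy 562).

`makeDeposition(plan, seed)` plants each requested defect exactly once in
a defect-free base (30-residue helix, one ligand, five waters, P 2₁ cell)
and returns a manifest naming the expected issue code, severity and locus.
Two invariants anchor the whole package: the empty plan curates to zero
findings, and every single-defect plan round-trips — the compiled report
contains exactly the manifest's finding and nothing else above
informational severity. Determinism is byte-level: identical (plan, seed)
produce identical files.

```{r roundtrip}
fx <- makeDeposition("Zero B-factor", seed = 11)
res <- curateDeposition(fx$deposition, refdb = makeRefDb(seed = 11))
fx$manifest
res$report@counts
```
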