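---
title: "Evaluating chemosensory GPCR-agonist models against mutagenesis data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating chemosensory GPCR-agonist models against mutagenesis data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrcontacts)
```

## The problem

Bitter taste receptors (hTAS2Rs) and odorant receptors (hORs) are
seven-transmembrane (7TM) G-protein coupled receptors with essentially no
experimental structures, so structural work on agonist binding rests on
homology models combined with docking or simulation.  The only systematic
way to judge such models is indirect: site-directed mutagenesis with
functional (EC50) readouts flags residues whose mutation perturbs the
response, and a structural model is credible to the extent that its
predicted ligand-contact residues coincide with those flags.

`gpcrcontacts` implements that evaluation loop as a reusable, tested
pipeline:

1. **Contact detection.** A polymer residue is in atomic contact with the
   ligand when its minimum heavy-atom distance to any ligand atom is below
   5.5 Å — the sum of two carbon van der Waals radii plus a water-molecule
   diameter, i.e. close enough that no water layer fits between the
   groups.  A second, chemical filter keeps only contacts that realize a
   classical interaction (hydrogen bond, salt bridge, aromatic stacking,
   hydrophobic contact).
2. **Generic numbering.** Residues are labelled with GPCRdb-style generic
   positions (`helix.offset`, anchored at the most conserved `X.50`
   residue of each helix) projected from an annotated template through a
   user-supplied alignment, so residues are comparable across receptors
   and to mutagenesis records.
3. **Scoring.** Experimentally tested residues in the extracellular (top)
   half of the bundle — the location of the canonical orthosteric site —
   are classified as TP/FP/TN/FN by agreement between prediction and
   EC50 effect, and summarized as precision `TP/(TP+FP)`, recall
   `TP/(TP+FN)` and predictive power `(TP+TN)·100/total tested`.
4. **Activation analysis.** Side-chain contact maps (van der Waals sum
   criterion, backbone excluded) of active/inactive structure pairs are
   differenced in generic-position space and aggregated across receptors;
   positions that are both highly conserved and frequently rewired are
   candidate activation switches.
5. **Conservation.** Family alignments are queried per generic position
   (single residues or residue classes such as V/L/I), scanned for
   conserved TM motifs, and curated by gap content and motif presence.

## Confusion-matrix conventions

Only residues with an experimental measurement enter the counts: a
predicted contact at an untested residue is reported separately
(`untested_contacts`) and influences neither precision nor predictive
power.  This follows from the predictive-power denominator being the
number of experimental data points; calling untested contacts "false
positives" would mix two different universes.  Three further conventions:

- a residue with both affecting and non-affecting mutations counts as
  `affects_response` (worst-case collapse, one decision per residue);
- `0/0` precision or recall is defined as 0;
- predictive power on zero tested residues is an error, not a number.

Metrics are kept at full precision internally and rounded half away from
zero to two decimals only for display and for comparison with published
tables.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `ligand_contact_cutoff` | 5.5 | Å | water-exclusion distance; the constant itself is authoritative, not re-derived from radii |
| `hbond_max` | 3.5 | Å | conventional heavy-atom donor–acceptor ceiling |
| `salt_bridge_max` | 4.0 | Å | charged-group atom pair ceiling |
| `ring_centroid_max` | 5.0 | Å | ring centroid–centroid ceiling for stacking |
| `hydrophobic_max` | 4.5 | Å | apolar carbon–carbon ceiling |
| `vdw_tolerance` | 0.6 | Å | the practical form of the vdW-sum contact rule; 0 recovers the literal "shorter than the sum" |
| `min_seq_separation` | 4 | residues | excludes trivially contacting sequence neighbours from contact maps |
| EC50 fold threshold | 2 | fold | a mutation "affects the response" at ≥ 2-fold shift (or abolition); configurable |
| `min_support` | 3 | receptor pairs | majority of a five-receptor activation panel |
| `min_conservation` | 70 | % | operational meaning of "highly conserved" for ranking |
| `gap_frac_max` | 0.2 | fraction | family curation: tolerated gap fraction over TM columns |

The chemical filter codifies as deterministic geometry what is often done
by visual inspection.  Ligand chemistry (formal charges, aromatic rings,
donors/acceptors, apolar carbons) is *declared* in a descriptor file and
never perceived from geometry — bond perception on arbitrary hetero
groups is ambiguous, and the descriptor makes the rules reproducible.
Residue-side chemistry comes from fixed side-chain templates; backbone
N/O never contribute to the chemical filter (they are not binding-site
determinants that mutagenesis could confirm), and histidine is a neutral
donor/acceptor unless explicitly flagged protonated.

## Numbering

Generic numbers are projected from the template by counting template
positions from each helix anchor: `offset = 50 + (position − anchor)`.
GPCRdb bulge/constriction adjustments are deliberately not implemented —
the projection-through-the-template convention is what the evaluation
needs, and it keeps the map one-to-one and monotone.  Residues aligned to
template gaps (insertions), residues in helices whose anchor column is
gapped in the target, and offsets escaping 1–99 are reported as unmapped
rather than guessed.  The package never computes alignments; they are
inputs.

## Geometry conventions

The bundle axis is the first principal component of the transmembrane
C-alpha cloud, oriented so that the most N-terminal TM residue projects
positively (class A topology: extracellular N-terminus).  Perfectly
collinear C-alphas still define the axis (the first principal direction
of a line is the line); only coincident points are degenerate and raise
an error.  "Top half" means axial projection at or above the centroid
projection, ties included; residues without a C-alpha are excluded with a
warning.  Distances ignore hydrogens throughout (models from
homology-modelling pipelines are heavy-atom), and altloc resolution keeps
the highest-occupancy conformer (ties to conformer A).  Waters never
enter contact computations.

## What the synthetic generators emulate

Every pipeline input can be generated with planted ground truth:

- `gen_bundle_complex()` builds an idealized 7-helix bundle (C-alpha rise
  1.5 Å/residue, 100° turn, helix radius 2.3 Å, bundle radius 12 Å, 25
  residues per helix) around a compact agonist-like ligand in the
  extracellular half.  Planted contact residues get side-chain
  pseudo-atoms with correct element types placed 0.3 Å *inside* their
  interaction rule's cutoff and satisfying *only* that rule; decoys stay
  at least 0.5 Å *outside* the 5.5 Å rule.  These margins dominate the
  PDB format's 10⁻³ Å coordinate precision, so the planted truth survives
  a write/parse round trip.
- `gen_mutagenesis_table()` realizes any feasible (TP, FP, TN, FN) against
  the planted truth, so scoring can be checked exactly.
- `gen_family_msa()` plants exact per-column residue counts
  (`round(frequency · n_rows)`) plus gap-defective and motif-defective
  rows for the curation filter.
- `gen_state_pair()` plants contact rewiring between activation states:
  the inactive structure has an empty side-chain contact map, the active
  one adds exactly the requested generic-position contacts, with
  side-chain meeting points placed near the empty pore axis (one height
  band per pair, 6 Å apart) so no third residue is perturbed.

Each generator re-verifies its own output by brute force (explicit
double loops over atoms) before returning and fails loudly otherwise —
there are no silently bad fixtures.  Geometrically impossible requests
(too many planted contacts, rewired pairs whose placement would disturb
other contacts) are errors by design.

What the generators do **not** emulate: real side-chain rotamers, loops,
membrane, ligand flexibility, or the error structure of homology models
and docking poses.  Passing the planted-truth suites therefore shows that
the *bookkeeping* — distance rules, chemistry rules, numbering,
confusion-matrix logic, aggregation — is exact; it says nothing about the
accuracy of any particular modelling pipeline, which is precisely what
the package is meant to measure on real inputs.

## Problem sizes

The shipped verification suites run at the study's own scale: 50 seeded
complexes for the contact-rule oracles, 100 seeded (complex, mutagenesis)
scenarios for confusion-matrix recovery, 20 seeded activation-state pairs
with 1–5 planted rewirings, 25-sequence families for conservation, and a
five-complex worked-example panel for the metric arithmetic.  A
175-residue bundle with ~900 atoms keeps an exhaustive O(N²·A²) oracle
comparison affordable while exercising every rule.

## Known limitations

- The evaluation cannot distinguish binding from transduction effects:
  an EC50 shift flags a residue as functionally important, not
  mechanistically classified.  This is a property of the data, inherited
  by any metric computed from it.
- Conservation denominators are ambiguous in the field; both "non-gap
  rows" (primary) and "all rows" percentages are reported.
- Activation-state labels are taken from the input manifest verbatim;
  the package does not validate them against external databases.
- mmCIF parsing, docking, pocket prediction, π-cation and water-mediated
  interactions are out of scope.
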