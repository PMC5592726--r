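# gpcrcontacts

Contact-based evaluation of chemosensory GPCR–agonist structural models
against site-directed mutagenesis data.

Bitter taste receptors (hTAS2Rs) and odorant receptors (hORs) are
seven-transmembrane GPCRs with no experimental structures, so structural
claims about agonist binding come from homology models plus docking or
simulation. The only systematic check on such models is agreement with
mutagenesis: residues whose mutation shifts the agonist's EC50 should be
the residues the model places in contact with the ligand. This package
implements that evaluation as a tested pipeline, plus the companion
activation analysis on active/inactive crystal-structure pairs.

## What it computes

**Contacts.** A residue is in atomic contact with the ligand when its
minimum heavy-atom distance is below 5.5 Å (two carbon van der Waals
radii plus a water diameter); a chemical filter then keeps contacts
realizing a classical interaction — hydrogen bond, salt bridge, aromatic
stacking, or hydrophobic contact — under deterministic geometric rules.

**Scoring.** Over the experimentally tested residues in the extracellular
(top) half of the bundle:

    PREC = TP / (TP + FP)        REC = TP / (TP + FN)
    predictive power = (TP + TN) * 100 / (number of tested residues)

with TP = affects-response ∧ predicted contact, FN = affects-response ∧
not predicted, FP = no-effect ∧ predicted, TN = no-effect ∧ not
predicted. Predicted contacts at untested residues are reported
separately and never enter the counts.

**Numbering.** GPCRdb-style generic positions (`helix.offset`, anchor
`X.50`) projected from an annotated template through an input alignment,
so residues are comparable across receptors (e.g. position 7.52).

**Activation.** Side-chain residue–residue contact maps (distance below
the van der Waals radius sum plus tolerance, backbone excluded) of
active/inactive structure pairs are differenced in generic-position space
and aggregated across receptors; positions are ranked by how often their
interaction network is rewired, filtered by family conservation.

**Conservation.** Per-position residue (or residue-class) conservation in
family alignments, conserved-motif scanning, and gap/motif-based family
curation.

**Synthetic data.** Seeded generators build every input with planted
ground truth — 7-helix bundles with planted contacts and decoys,
mutagenesis tables realizing a chosen confusion matrix, alignments with
exact planted column frequencies, state pairs with planted rewired
contacts — each re-verified by brute force at generation time.

## Worked example

```r
library(gpcrcontacts)

cx <- gen_bundle_complex(1,
  n_contacts = c(hbond = 1, salt_bridge = 1,
                 aromatic_stacking = 1, hydrophobic = 1),
  n_decoys = 5)
contacts <- detect_ligand_contacts(cx$structure,
                                   descriptor = cx$descriptor, map = cx$map)
contacts
#> # A tibble: 4 × 8
#>   res_key chain seqnum resname generic min_dist labels            passes_chemical_filter
#> 1 A:7     A          7 PHE     1.44        3.71 aromatic_stacking TRUE
#> 2 A:57    A         57 ASP     3.44        3.70 salt_bridge       TRUE
#> 3 A:108   A        108 LEU     5.45        4.20 hydrophobic       TRUE
#> 4 A:144   A        144 SER     6.56        3.20 hbond             TRUE
```

The four planted residues — and only those — are detected, each with its
planted interaction type and its minimum heavy-atom distance (Å) to the
ligand; `generic` gives the GPCRdb-style position of each residue.
Scoring against a mutagenesis table planted to contain 3 true positives,
1 false positive, 2 true negatives and 1 false negative:

```r
mt <- gen_mutagenesis_table(cx$truth, c(TP = 3, FP = 1, TN = 2, FN = 1),
                            seed = 1)
ev <- evaluate_complex(contacts, mt$records,
                       top_half_residues(cx$structure))
ev
#> <binding_eval>
#>   counts: TP=3 FP=1 TN=2 FN=1
#>   precision 0.75  recall 0.75  predictive power 71.4%
```

Precision 0.75 means one of four predicted-and-tested contacts was a
false alarm; recall 0.75 means one experimentally important residue was
missed; predictive power 71.4% is the fraction of the 7 tested residues
the model classifies correctly. `tidy(ev)` returns the per-residue
ledger, `glance(ev)` the one-row metric summary, and `autoplot(ev)` a
precision–recall plot.

## Layout

- `R/` — structure I/O and geometry, numbering, contacts, evaluation,
  conservation, activation, synthetic generators, pipeline stages, plots
- `inst/scripts/gpcr-pipeline.R` — command-line wrapper over
  `run_stage()` (stages: simulate, contacts, evaluate, numbering,
  conserve, curate, rewire, report)
- `vignettes/` — the methods vignette: model, parameters, conventions,
  generator design, limitations
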