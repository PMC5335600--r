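# admetk

Small-molecule ADME profiling in R: physicochemical properties,
lipophilicity, water solubility, pharmacokinetics, drug-likeness and
medicinal-chemistry friendliness, computed from SMILES input.

The package is aimed at medicinal chemists and cheminformaticians who
want fast, interpretable per-molecule property panels — the kind used to
triage compound lists before synthesis or purchase — with every model
open and re-thresholdable.

## What it computes

For each molecule (standardized: canonicalized, kekulized, salt-stripped,
neutralized; Open Babel does the parsing):

* **Physicochemical descriptors** — MW, heavy/aromatic atom counts,
  fraction Csp3, rotatable bonds, H-bond donors/acceptors, molar
  refractivity (Wildman–Crippen fragmental sum), and the fragmental
  **TPSA** with polar sulfur and phosphorus,
  `TPSA = Σ_i contribution(environment_i)` over N/O/S/P environments.
* **Lipophilicity** — atomistic **WLOGP** (68-class Wildman–Crippen
  system, `logP = Σ_atoms c(class)`), topological **MLOGP** (Moriguchi's
  13-parameter regression), an optional table-driven fragment model, and
  external-value slots for predictors that need outside software; the
  **consensus log P** is the arithmetic mean of available predictors.
* **Water solubility** — ESOL
  (`logS = 0.16 − 0.63 logP − 0.0062 MW + 0.066 RB − 0.74 AP`), a
  logP/TPSA linear model, and a table-driven fragmental model; each with
  mol/l and mg/ml conversions and the qualitative class scale
  (insoluble < −10 < poorly < −6 < moderately < −4 < soluble < −2 <
  very < 0 < highly).
* **Pharmacokinetics** — Potts–Guy-type skin permeation
  (log Kp in cm/s), and passive gastrointestinal absorption / brain
  access read from the position in the (TPSA, WLOGP) plane relative to
  two configurable ellipses ("white" = absorption, "yolk" = brain
  access), with per-molecule plot data for the classification graph.
* **Drug-likeness** — Lipinski, Ghose, Veber, Egan and Muegge filters
  with explicit violation lists, the Abbott bioavailability score
  (0.11 / 0.17 / 0.56 / 0.85 classes from charge, TPSA and Lipinski
  compliance), and a six-axis bioavailability radar (lipophilicity,
  size, polarity, solubility, saturation, flexibility).
* **Medicinal chemistry** — PAINS and Brenk-type structural-alert
  screening (SMARTS catalogs; the shipped files are documented synthetic
  stand-ins preserving the published entry counts), leadlikeness, and a
  **synthetic-accessibility score** (1 = very easy … 10 = very
  difficult) from the frequency of 1024 hashed linear-path fingerprint
  fragments in a reference library, corrected by size and complexity
  penalties (stereocentres, spiro, bridged rings, macrocycles).
* **SVM pipeline** — the classifier-building methodology behind
  substrate/inhibitor predictions: descriptor rejection (non-zero
  fraction ≥ 20%, CV ≥ 3%, |r| ≤ 0.9 with F-score tie-break), Ward
  clustering class balancing, training-set normalization, RBF-SVM
  (C, γ) grid search maximizing 10-fold cross-validated accuracy, and
  external evaluation (ACC, AUC, sensitivity, specificity).
  `adme_svm_fit()` returns a model object with `print`/`summary`/
  `predict` methods.

## Worked example

```r
library(admetk)
p <- adme_profile("Cn1cnc2c1c(=O)n(C)c(=O)n2C", "Caffeine")
print(p)
```

```
== Caffeine ==
  SMILES: Cn1cnc2c1c(=O)n(C)c(=O)n2C  ( C8H10N4O2 )
  MW 194.19 | TPSA 61.82 | WLOGP -1.03 | MLOGP 0.33 | consensus -0.35
  ESOL logS -0.87 (very) | logKp -8.21 cm/s | HIA TRUE | BBB FALSE
  filters: Lipinski:pass Ghose:FAIL Veber:pass Egan:pass Muegge:FAIL
  bioavailability score 0.56 | radar not drug-like | leadlikeness fail
  PAINS alerts: 0
  Brenk alerts: 0
```

Reading the panel: caffeine is small (MW 194.19 g/mol), moderately polar
(TPSA 61.82 Å²) and hydrophilic (consensus log P −0.35, the mean of
WLOGP and MLOGP here).  Its ESOL estimate (log S −0.87, "very" soluble,
equivalently 10^−0.87 mol/l) and skin permeability (log Kp −8.21 cm/s:
poorly skin-permeant) follow from those descriptors.  It passes
Lipinski, Veber and Egan; Ghose and Muegge object to its small size
(fewer than 20 heavy atoms; MW below 200).  The 0.56 bioavailability
score is the default Lipinski-compliant class.  The radar flags it as
not fully drug-like: five axes pass, but the lipophilicity axis uses
the atomistic WLOGP (−1.03, below the −0.7 floor) when no external
atomistic prediction is supplied; `print(p$radar)` lists the per-axis
verdicts.  No structural alerts fire.

Batch use, CSV report and classification plot data:

```r
profiles <- adme_profile_batch(readLines("molecules.smi"))
write_report(profiles, "report.csv")
egg_plot_data(profiles)       # name, TPSA, WLOGP, hia, bbb, pgp, in_range
```

The same operations are available from a shell via the bundled CLI
(`exec/admet`): subcommands `profile`, `egg`, `sa-table` and `svm`; see
`admet help`.

## Notes

* The shipped PAINS/Brenk catalog files are synthetic count-preserving
  stand-ins (genuine core motifs + inert fillers; see the file headers).
  Load the original catalog files with `load_catalog()` for production
  screening.
* The absorption/brain-access ellipse geometry and all filter
  thresholds are configuration data (`egg_geometry.txt`,
  `druglikeness_rules()`, `radar_ranges()`), not code constants.
* See `vignettes/admetk-methods.Rmd` for the full model documentation,
  parameter meanings and design decisions.
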