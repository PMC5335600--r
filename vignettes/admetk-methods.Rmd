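---
title: "admetk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{admetk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`admetk` profiles small molecules from SMILES input: physicochemical
descriptors, lipophilicity, water solubility, pharmacokinetic readouts,
rule-based drug-likeness, structural alerts and a fragment-frequency
synthetic-accessibility (SA) score, plus an SVM pipeline for building
binary pharmacokinetics classifiers.  This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where the underlying methods left room.

## Molecule standardization

Input SMILES are syntax-checked, canonicalized and kekulized through Open
Babel (via ChemmineOB).  Hydrogens are made explicit and counted per heavy
atom; the largest covalent fragment is kept (salt stripping); simple
protonation states are neutralized (carboxylate-type `O-` gains a
hydrogen, protonated amines lose one).  Permanently charged centres —
quaternary nitrogen, nitro and N-oxide oxygens — are left untouched: they
cannot be neutralized by (de)protonation.  The net formal charge of the
as-input structure is recorded *before* neutralization; the
bioavailability score uses that value, because whether a molecule is an
anion at the point of administration is a property of the submitted form,
not of the neutralized calculation form.  All descriptor models run on the
neutralized, salt-stripped structure.

Aromaticity is taken from Open Babel's canonical aromatic SMILES rather
than re-perceived: Open Babel preserves atom order between a SMILES and
the SDF it writes from it, and the package asserts the element sequence
to catch any violation of that assumption.

Open Babel recovers silently from some malformed SMILES (it parses `C(`
as methane), so a token-level syntax validator (balanced brackets,
paired ring-closure digits, no dangling bond) enforces the documented
invalid-input error before Open Babel sees the string.

## Fragmental TPSA

The topological polar surface area is the sum of tabulated surface
contributions over polar atom environments, with sulfur and phosphorus
environments included by default (`include_sp = FALSE` removes them).
Environments are keyed by element, aromaticity, formal charge, hydrogen
count, 3-ring membership, and bond-order pattern.  Polar atoms in
environments absent from the published table (for example an isolated
water molecule) contribute zero — the table is used as published rather
than extrapolated.

## Lipophilicity

Two predictors are computed in-package:

* **WLOGP** — the atomistic Wildman–Crippen system: every atom
  (hydrogens included) is assigned one of the published atom classes by
  ordered structural rules and the contributions are summed.  The
  per-atom typing was validated against an independent implementation of
  the same published table on a 98-molecule development set (agreement
  better than 0.005 log-units per molecule).
* **MLOGP** — the Moriguchi topological regression on 13 structural
  parameters.  Two of the original parameters were assessed by visual
  inspection in the source publication and are necessarily heuristic
  here: the intramolecular hydrogen-bond dummy (detected as an ortho
  donor/acceptor substituent pair on an aromatic ring) and the
  amphoteric dummy (alpha-amino acid, aminobenzoic-type and
  pyridine-carboxylic-type patterns).  The nitro group carries its own
  regression term, so its N and O atoms are excluded from the generic
  N/O count.

A table-driven hybrid fragment/descriptor model (`fragment_logp()`)
evaluates SMARTS-keyed fragment counts plus topological descriptors with
user-supplied coefficients.  No coefficient table is shipped for it: the
open-source program the coefficients would come from is not
redistributable here, so the predictor reports as unavailable unless a
table is supplied, and the consensus adapts.

Predictors that require external physics or closed-source programs are
**external-value slots**: per-molecule predictions (for example an
XLOGP3 or a GB/SA-based value) can be supplied in a CSV and enter the
consensus like any computed value.  The **consensus log P** is the
arithmetic mean of whatever predictors are available; the contributor
count is reported.  Downstream models that were published against an
atomistic external predictor (solubility, skin permeation, the Muegge
filter, leadlikeness, the radar's lipophilicity axis) use the external
value when supplied and WLOGP otherwise; the substitution is recorded in
the profile (`lipo_slot_source`).

## Water solubility

Three estimators of log10 molar solubility (log S):

* **ESOL**: `0.16 − 0.63·logP − 0.0062·MW + 0.066·RB − 0.74·AP`, with AP
  the aromatic-heavy-atom proportion.
* **logP/TPSA model**: `−1.0323 − 1.0148·logP − 0.0056·TPSA`.  The
  original publication of this melting-point-free reformulation was not
  accessible when the constants were vendored; the functional form
  (linear, both slopes negative) is as published and the constants are
  package data a user can re-source.
* **Fragmental model** (`fragment_logs()`): table-driven fragment
  contributions plus a square-root-of-MW term; like the fragment log P,
  it activates only when a coefficient table is supplied.

log S is converted exactly to mol/l (`10^logS`) and mg/ml
(`10^logS · MW`), and classed on the qualitative scale insoluble <
−10 < poorly < −6 < moderately < −4 < soluble < −2 < very < 0 < highly.
A value exactly on a boundary takes the more soluble label (the
published scale uses strict inequalities in both directions, leaving
boundaries ambiguous; solubility is the optimistic reading).

## Pharmacokinetics

**Skin permeation** is the linear Potts–Guy-type model, implemented from
its cm/h form (`−2.74 + 0.71·logP − 0.0061·MW`) and converted to cm/s by
subtracting log10(3600); the report prints log Kp in cm/s (more negative
= less permeant).

**Gastrointestinal absorption and brain access** are read from the
position of the molecule in the (TPSA, WLOGP) plane relative to two
ellipses — the "white" (high probability of passive HIA absorption) and
the "yolk" (high probability of BBB permeation).  The two regions are
not mutually exclusive.  The ellipse geometry is configuration data
(`inst/extdata/egg_geometry.txt`): the source publication prints no
coefficients, so the defaults are the best-fit ellipse parameters in
circulation for that model, and any user file in the same key-value
format replaces them.  Points outside the configured plot range (TPSA
0–200, WLOGP −4–8, matching the published figure's extent) are flagged
out-of-range and classified negative for both readouts.

**P-gp substrate** calls come from an SVM classifier built with the
pipeline below when the user supplies training data; no pre-trained
model is shipped (the published training sets are external databases),
and the plot-data table reports `NA` rather than a fabricated value when
no model is loaded.

## Drug-likeness

Five rule-based filters with thresholds held as configuration
(`druglikeness_rules()`):

| Filter  | Rules |
|---------|-------|
| Lipinski | MW ≤ 500, MLOGP ≤ 4.15, HBD ≤ 5, HBA ≤ 10; passes with ≤ 1 violation |
| Ghose    | 160 ≤ MW ≤ 480, −0.4 ≤ WLOGP ≤ 5.6, 40 ≤ MR ≤ 130, 20 ≤ atoms ≤ 70 (closed intervals) |
| Veber    | rotatable bonds ≤ 10, TPSA ≤ 140 |
| Egan     | WLOGP ≤ 5.88, TPSA ≤ 131.6 |
| Muegge   | 200 ≤ MW ≤ 600, −2 ≤ logP ≤ 5, TPSA ≤ 150, rings ≤ 7, C > 4, heteroatoms > 1, RB ≤ 15, HBA ≤ 10, HBD ≤ 5 |

Violation lists always enumerate exactly the breached sub-rules, so
stricter users can re-threshold.  H-bond counts are Lipinski-style (HBA
= all N+O; HBD = all N–H and O–H); a stricter acceptor count (excluding
amide/sulfonamide N, pyrrole-type aromatic N and nitro O) is exposed
separately in the descriptor panel.  The heavy-atom count serves as the
Ghose atom count.

The **bioavailability score** maps (input net charge, TPSA, Lipinski
compliance) onto four probability classes: anions by TPSA (≤ 75: 0.85;
75–150: 0.56; > 150: 0.11), everything else 0.56 when Lipinski-compliant
and 0.17 otherwise.  The default-class constant is configurable (0.56
here; the original publication prints 0.55).

The **bioavailability radar** checks six axes: lipophilicity (slot
value, range −0.7 to +6.0), size (MW 150–500 g/mol), polarity (TPSA
20–130 Å²), solubility (ESOL log S ≥ −6), saturation (fraction Csp3 ≥
0.25) and flexibility (≤ 9 rotatable bonds); a molecule is drug-like
when all six pass.  The lipophilicity ceiling is configurable because
the source material states both +5.0 and +6.0; the methods-text value
+6.0 is the default.

## Medicinal chemistry

**Structural alerts.**  PAINS-type (481 entries) and reactive/toxic
fragment (105 entries) catalogs are screened by SMARTS substructure
search; every matching pattern is reported once with its match count, in
catalog order.  The *shipped catalog files are synthetic count-preserving
stand-ins*: a core of genuine published alert motifs (quinones,
rhodanines, catechols, Michael acceptors, azo groups, and so on) padded
to the published entry counts with inert rare-element patterns that
compile but cannot match organic molecules.  The original files could
not be redistributed from the build environment; any catalog in the same
`SMARTS<TAB>description` format can be loaded in their place, and
`load_catalog()` validates pattern compilation and entry count.

**Leadlikeness**: 250 ≤ MW ≤ 350, slot log P ≤ 3.5, ≤ 7 rotatable bonds.

**Synthetic accessibility.**  A frequency table is built from a SMILES
library: per-bit occupancy counts of the 1024-bit linear-path
fingerprint are normalized by the maximum count and log-transformed, so
the most common fragment contributes 0 and rarer fragments are
increasingly negative; never-observed bits get a floor of
`ln(0.5/max)` (pseudo-count 0.5, configurable).  A molecule's raw score
is the mean contribution of its set bits minus non-negative complexity
penalties: size (`n^1.005 − n` on the heavy-atom count, the classical
coefficient form, with heavy atoms as the size measure proportional to
MW), stereocentres, spiro atoms and bridgehead atoms (`log10(n+1)`
each), and a flat `log10 2` when a macrocycle — any ring with more than
8 members — is present.  Stereocentre counts are the tetrahedral marks
specified in the input SMILES.  The raw score maps onto [1, 10] (1 =
very easy, 10 = very difficult) by an affine transform calibrated on the
library at table-build time — the library's own raw range defines the
easy end, with a fixed margin of 3 raw units beyond the hardest library
molecule on the difficult end — and the calibration constants are stored
inside the persisted table, next to the fingerprint dialect identifier
that the scorer verifies.  Sign conventions are fixed by the
monotonicity requirement (rarer fragments and larger penalties never
lower the score) and asserted in the tests.

The fingerprint dialect: all simple linear paths of 1–7 bonds over heavy
atoms, each path encoded as (atomic number, formal charge, bond order)
tuples, canonicalized as the lexicographically smaller direction, hashed
with 32-bit FNV-1a modulo 1024.  Hydrogens are not path members.  Any
self-consistent dialect works because the table builder and the scorer
share it; the dialect string stored with tables prevents mixing.

The packaged synthetic library generator composes valid SMILES from
chain and ring units.  It emulates a vendor catalog only structurally —
common chains, rings, functional groups — not its size or diversity, so
SA scores calibrated on it are suitable for the package's property tests
and for relative comparisons, not for absolute agreement with scores
calibrated on a multi-million-compound commercial library.

## SVM pipeline

`adme_svm_fit()` is the classic one-call fitting interface returning a
classed model object with `print`, `summary` and `predict` methods.

1. **Descriptor filtering**: a descriptor is rejected when its non-zero
   fraction is below 20% or its coefficient of variation (sample SD over
   |mean|; infinite when the mean is 0 with positive SD, so such columns
   are kept) is below 3%; among remaining pairs correlated above |r| =
   0.9, the member with the higher class-separation F-score (between-
   class over within-class variance ratio, the standard SVM
   feature-selection form) survives.
2. **Class balancing** (`cluster_balance()`): the larger class is Ward-
   clustered (on 1 − Tanimoto over fingerprints by default; the
   dissimilarity is a parameter) into as many clusters as the target
   size and each cluster's centre — smallest sum of dissimilarities,
   ties to the lowest input index — is kept.
3. **Normalization**: training features to zero mean/unit variance;
   the parameters are stored and re-applied to any test set (never
   refit).
4. **Grid search**: (C, γ) over log2 grids — coarse C 2⁻⁵…2¹⁵, γ
   2⁻¹⁵…2³ in steps of 4, then a 3×3 refinement at one-third of the
   coarse step around the winner — maximizing stratified 10-fold
   cross-validated accuracy; ties prefer smaller C, then smaller γ (the
   simpler model).  Fold assignment is stratified and seeded.
5. **Statistics**: cross-validated accuracy and AUC at the winning
   parameters (AUC by the rank-based Mann–Whitney formula on decision
   values); external evaluation adds accuracy, AUC, sensitivity and
   specificity on a test set normalized with the training parameters.

The synthetic dataset generator draws two Gaussian classes in 50
dimensions (the size of the profiling descriptor panel) with a stated
mean shift on 10 informative features, plus class-correlated random
fingerprints for the balancing step.  It reproduces the *structure* of a
cleaned descriptor/label dataset — informative and noise features,
class imbalance on demand — but not the correlation patterns of real
molecular descriptors, so pipeline tests demonstrate parameter recovery
and null behaviour, not real-data accuracy.  The packaged checks run at
200 + 200 molecules and 10 seeds for the recovery property (mean
cross-validated accuracy ≥ 0.95 at a 3-SD effect; chance-level AUC on
permuted labels), sizes chosen to make the properties sharp while
keeping the default suite quick.

## Numerical and degenerate-input choices

* Boundary values: solubility class boundaries take the more soluble
  label; Ghose intervals are closed; Lipinski's lipophilicity rule uses
  a strict `>` (exactly 4.15 is compliant).
* Carbon-free molecules: fraction Csp3 is defined as 0 with a warning.
* Ties: cluster centres and grid-search winners break ties toward the
  lowest index / smaller hyper-parameters.
* Fingerprints of single-atom molecules have no set bits; two empty
  fingerprints have Tanimoto dissimilarity 0 by convention.
* Molecules that fail to parse inside a batch yield an error profile
  (status recorded, empty cells in the CSV); the batch never aborts.
* The rotatable-bond definition excludes amide C–N bonds and bonds to
  terminal atoms, the convention behind the flexibility rules.

## Known limitations

* The shipped alert catalogs are labelled stand-ins (above); production
  screening requires the original catalog files.
* No pre-trained P-gp/CYP models ship; the pipeline reproduces the
  *methodology* and accepts user datasets.
* MLOGP's two inspection-based dummies are heuristics; molecules relying
  heavily on intramolecular hydrogen bonding or amphoteric corrections
  may deviate from hand-computed Moriguchi values.
* TPSA of environments outside the published fragment table (isolated
  water) is 0, not extrapolated.
* The match-atom sets of SMARTS hits are not exposed (the SMARTS engine
  reports unique match counts); alert reports carry counts and
  descriptions.
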