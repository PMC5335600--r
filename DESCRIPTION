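Package: admetk
Type: Package
Title: Physicochemical, ADME, Drug-Likeness and Medicinal-Chemistry
    Profiling of Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Profiles small molecules from SMILES input: physicochemical
    descriptors (fragmental topological polar surface area with polar sulfur
    and phosphorus, Wildman-Crippen atomistic log P and molar refractivity,
    Moriguchi topological log P), water solubility models (ESOL, a
    log P/TPSA linear model, and a table-driven fragmental model) with
    qualitative solubility classes, Potts-Guy skin permeation, passive
    gastrointestinal-absorption and brain-access classification in the
    WLOGP-versus-TPSA plane, rule-based drug-likeness filters (Lipinski,
    Ghose, Veber, Egan, Muegge), the Abbott bioavailability score, a
    six-axis oral-bioavailability radar, PAINS and Brenk structural-alert
    screening, leadlikeness, a fragment-frequency synthetic-accessibility
    score built on hashed linear-path fingerprints, and a support-vector
    machine pipeline (descriptor filtering, Ward-clustering class
    balancing, RBF grid search with 10-fold cross-validation) for
    pharmacokinetics classifiers.  Molecule parsing, canonicalization and
    SMARTS matching are delegated to Open Babel through ChemmineR and
    ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
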