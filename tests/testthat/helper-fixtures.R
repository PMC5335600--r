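## Shared fixtures for the test suite.
##
## ORACLE_FIXTURES holds frozen reference values for TPSA (polar S/P
## included), Wildman-Crippen log P and MR, and molecular weight, computed
## once with an independent implementation of the same published
## contribution tables and frozen here.  Tolerance for the fragmental sums
## is 0.01 (0.05 for log P totals where atom-typing edge cases may differ).

ORACLE_FIXTURES <- data.frame(
  name = c("ethanol", "benzene", "toluene", "naphthalene", "pyridine", "pyrrole", "furan", "thiophene", "imidazole", "phenol", "anisole", "aniline", "benzaldehyde", "benzamide", "nitrobenzene", "chlorobenzene", "benzonitrile", "dmso", "dimethylsulfone", "caffeine", "aspirin", "ibuprofen", "paracetamol", "glucose", "guanidine", "trimethylphosphate", "morpholine", "sulfanilamide", "streptomycin"),
  smiles = c("CCO", "c1ccccc1", "Cc1ccccc1", "c1ccc2ccccc2c1", "c1ccncc1", "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "c1cnc[nH]1", "Oc1ccccc1", "COc1ccccc1", "Nc1ccccc1", "O=Cc1ccccc1", "NC(=O)c1ccccc1", "O=[N+]([O-])c1ccccc1", "Clc1ccccc1", "N#Cc1ccccc1", "CS(C)=O", "CS(C)(=O)=O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(=O)Oc1ccccc1C(=O)O", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CC(=O)Nc1ccc(O)cc1", "OCC1OC(O)C(O)C(O)C1O", "NC(=N)N", "COP(=O)(OC)OC", "C1COCCN1", "NS(=O)(=O)c1ccc(N)cc1", "CC1C(C(C(O1)OC2C(C(C(C(C2O)O)NC(=N)N)O)NC(=N)N)OC3C(C(C(C(O3)CO)O)O)NC)(C=O)O"),
  tpsa = c(20.2300, 0.0000, 0.0000, 0.0000, 12.8900, 15.7900, 13.1400, 28.2400, 28.6800, 20.2300, 9.2300, 26.0200, 17.0700, 43.0900, 43.1400, 0.0000, 23.7900, 36.2800, 42.5200, 61.8200, 63.6000, 37.3000, 49.3300, 110.3800, 75.8900, 54.5700, 21.2600, 94.5600, 331.4300),
  wlogp = c(-0.0014, 1.6866, 1.9950, 2.8398, 1.0816, 1.0147, 1.2796, 1.7481, 0.4097, 1.3922, 1.6952, 1.2688, 1.4991, 0.7855, 1.5948, 2.3400, 1.5583, -0.0053, -0.3392, -1.0293, 1.3101, 3.0732, 1.3506, -3.2214, -1.1614, 1.0337, -0.3938, -0.0838, -7.7418),
  mr = c(12.7598, 26.4420, 31.1790, 43.9480, 24.2370, 20.7927, 18.7080, 24.3190, 18.5877, 28.1068, 32.9940, 30.8544, 31.8295, 34.9599, 33.0964, 31.4520, 31.1570, 19.9904, 20.7678, 51.1960, 44.7103, 61.0348, 42.4105, 35.9860, 16.1015, 28.6335, 23.6887, 42.2276, 131.3989),
  mw = c(46.069, 78.114, 92.141, 128.174, 79.102, 67.091, 68.075, 84.143, 68.079, 94.113, 108.140, 93.129, 106.124, 121.139, 123.111, 112.559, 103.124, 78.136, 94.135, 194.194, 180.159, 206.285, 151.165, 180.156, 59.072, 140.075, 87.122, 172.209, 581.580),
  stringsAsFactors = FALSE)

## canonical streptomycin fixture (standard structure)
STREPTOMYCIN_SMILES <- ORACLE_FIXTURES$smiles[ORACLE_FIXTURES$name == "streptomycin"]

## quiet molecule constructor (Open Babel chatter suppressed)
qmol <- function(smiles, name = "m", ...) {
  suppressWarnings(suppressMessages(adm_molecule(smiles, name, ...)))
}

## config without alert screening (fast profiles for structural tests)
fast_config <- function(...) {
  adme_config(screen_alerts = FALSE, ...)
}

## synthetic descriptor panel for filter/radar unit tests
fake_descriptors <- function(...) {
  d <- list(
    MW = 300, heavy_atoms = 25, aromatic_heavy_atoms = 6,
    fraction_csp3 = 0.5, rotatable_bonds = 4, HBA = 4, HBD = 2,
    HBA_strict = 4, MR = 80, TPSA = 70, TPSA_no_SP = 70,
    formal_charge = 0, input_charge = 0, ring_count = 2,
    aromatic_rings = 1, aliphatic_rings = 1, macrocycles = 0,
    spiro_atoms = 0, bridgehead_atoms = 0, max_ring_size = 6,
    ring_atoms = 12, ring_bonds = 12, heteroatoms = 5, carbon_count = 20,
    nitrogen_count = 2, oxygen_count = 3, sulfur_count = 0,
    phosphorus_count = 0, halogen_count = 0, fluorine_count = 0,
    chlorine_count = 0, bromine_count = 0, iodine_count = 0,
    csp3_count = 10, sp2_carbon_count = 10, double_bonds = 1,
    triple_bonds = 0, amide_bonds = 1, h_count = 20, stereo_centres = 0,
    positive_charges = 0, negative_charges = 0, aromatic_proportion = 0.24,
    mean_atomic_mass = 12, terminal_atoms = 4, branch_atoms = 3,
    bond_count = 26, WLOGP = 2, MLOGP = 2
  )
  mods <- list(...)
  d[names(mods)] <- mods
  structure(d, class = "adm_descriptors")
}
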