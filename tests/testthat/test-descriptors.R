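test_that("fragmental TPSA reproduces reference values on the fixture set", {
  for (i in seq_len(nrow(ORACLE_FIXTURES))) {
    m <- qmol(ORACLE_FIXTURES$smiles[i], ORACLE_FIXTURES$name[i])
    expect_equal(tpsa(m), ORACLE_FIXTURES$tpsa[i], tolerance = 0.011,
                 info = ORACLE_FIXTURES$name[i])
  }
  expect_equal(tpsa(qmol("C")), 0)          # no polar atoms
  expect_equal(tpsa(qmol("CCO")), 20.23)    # one hydroxyl environment
})

test_that("TPSA is additive over disconnected fragments", {
  single <- tpsa(qmol("CCO"))
  dimer <- tpsa(qmol("CCO.CCO", strip_salts = FALSE))
  expect_equal(dimer, 2 * single, tolerance = 1e-9)
  mixed <- tpsa(qmol("CCO.NCC", strip_salts = FALSE))
  expect_equal(mixed, tpsa(qmol("CCO")) + tpsa(qmol("NCC")), tolerance = 1e-9)
})

test_that("molar refractivity matches the fragmental reference within 0.01", {
  for (i in seq_len(nrow(ORACLE_FIXTURES))) {
    m <- qmol(ORACLE_FIXTURES$smiles[i])
    expect_equal(molar_refractivity(m), ORACLE_FIXTURES$mr[i],
                 tolerance = 0.011 / max(1, abs(ORACLE_FIXTURES$mr[i])),
                 info = ORACLE_FIXTURES$name[i])
  }
  ## additivity over a disconnected dimer
  expect_equal(molar_refractivity(qmol("c1ccccc1.c1ccccc1", strip_salts = FALSE)),
               2 * molar_refractivity(qmol("c1ccccc1")), tolerance = 1e-9)
})

test_that("fraction Csp3 counts sp3 carbons over total carbons", {
  expect_equal(fraction_csp3(qmol("CC")), 1)
  expect_equal(fraction_csp3(qmol("c1ccccc1")), 0)
  expect_equal(fraction_csp3(qmol("CCc1ccccc1")), 0.25)
  expect_warning(f0 <- fraction_csp3(qmol("[NH4+]", neutralize = FALSE)),
                 class = "adm_carbon_free")
  expect_equal(f0, 0)
})

test_that("rotatable bonds: non-ring single bonds between non-terminal atoms, amides excluded", {
  expect_equal(rotatable_bonds(qmol("CC")), 0L)
  expect_equal(rotatable_bonds(qmol("CCCC")), 1L)
  expect_equal(rotatable_bonds(qmol("c1ccccc1")), 0L)
  ## acetanilide: only the N-phenyl bond rotates (amide C-N excluded)
  expect_equal(rotatable_bonds(qmol("CC(=O)Nc1ccccc1")), 1L)
  ## enumeration oracle on n-alkanes: n-2-1 internal C-C bonds... n-hexane
  expect_equal(rotatable_bonds(qmol("CCCCCC")), 3L)
})

test_that("molecular weight and descriptor panel are consistent", {
  for (i in c(1, 2, 20, 24, 29)) {
    m <- qmol(ORACLE_FIXTURES$smiles[i])
    expect_equal(molecular_weight(m), ORACLE_FIXTURES$mw[i],
                 tolerance = 0.01 / ORACLE_FIXTURES$mw[i],
                 info = ORACLE_FIXTURES$name[i])
  }
  d <- suppressWarnings(compute_descriptor_panel(qmol("CCO")))
  expect_equal(d$MW, 46.07, tolerance = 0.001)
  expect_gte(length(unclass(d)), 45L)   # the ~50-descriptor panel
  ## partition invariant over all fixtures
  for (i in seq_len(nrow(ORACLE_FIXTURES))) {
    m <- qmol(ORACLE_FIXTURES$smiles[i])
    d <- suppressWarnings(compute_descriptor_panel(m, include_logp = FALSE))
    expect_equal(d$heteroatoms + d$carbon_count, d$heavy_atoms,
                 info = ORACLE_FIXTURES$name[i])
    expect_gte(d$TPSA, 0)
    expect_true(d$fraction_csp3 >= 0 && d$fraction_csp3 <= 1)
  }
  expect_equal(suppressWarnings(
    compute_descriptor_panel(qmol("c1ccccc1")))$aromatic_heavy_atoms, 6L)
})

test_that("path fingerprint: exact small cases and invariances", {
  ## a single-atom molecule has no bond path, hence no bits
  expect_equal(sum(path_fingerprint(qmol("C"))$bits), 0L)
  expect_equal(sum(path_fingerprint(qmol("[Na+]", neutralize = FALSE))$bits), 0L)
  ## ethane: exactly the C-C path
  fp <- path_fingerprint(qmol("CC"))
  expect_equal(fp$n_paths, 1L)
  expect_equal(sum(fp$bits), 1L)
  ## atom-order permutations leave the fingerprint unchanged
  a <- path_fingerprint(qmol("Cn1cnc2c1c(=O)n(C)c(=O)n2C"))
  b <- path_fingerprint(qmol("O=c1n(C)c(=O)c2c(ncn2C)n1C"))
  expect_identical(a$bits, b$bits)
})

test_that("path enumeration agrees with the exhaustive frontier oracle", {
  small <- ORACLE_FIXTURES[ORACLE_FIXTURES$name %in%
                             c("ethanol", "benzene", "toluene", "pyridine",
                               "pyrrole", "furan", "imidazole", "phenol",
                               "anisole", "aniline", "nitrobenzene", "dmso",
                               "guanidine", "morpholine"), ]
  for (i in seq_len(nrow(small))) {
    m <- qmol(small$smiles[i])
    if (nrow(m$atoms) > 12) next
    mine <- sort(admetk:::fp_path_codes(m))
    oracle <- brute_force_paths(m)
    expect_identical(mine, oracle, info = small$name[i])
  }
})
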