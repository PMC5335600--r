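test_that("Lipinski counts violations and passes with at most one", {
  d <- fake_descriptors(MW = 600, HBD = 6, HBA = 11)
  r <- lipinski(d, mlogp_value = 5)
  expect_length(r$violations, 4L)
  expect_false(r$pass)

  eth <- compute_descriptor_panel(qmol("CCO"))
  r2 <- lipinski(eth)
  expect_length(r2$violations, 0L)
  expect_true(r2$pass)

  ## threshold is a strict inequality: exactly 4.15 is compliant
  r3 <- lipinski(fake_descriptors(), mlogp_value = 4.15)
  expect_length(r3$violations, 0L)

  ## the rule-of-five convention: one violation still passes
  r4 <- lipinski(fake_descriptors(MW = 501))
  expect_length(r4$violations, 1L)
  expect_true(r4$pass)
})

test_that("Ghose checks closed intervals (boundaries pass)", {
  ok <- fake_descriptors(MW = 300, MR = 80, heavy_atoms = 30)
  expect_true(ghose(ok, wlogp_value = 2)$pass)
  low_mr <- ghose(fake_descriptors(MR = 39), wlogp_value = 2)
  expect_false(low_mr$pass)
  expect_length(low_mr$violations, 1L)
  expect_match(low_mr$violations, "MR")
  ## boundary values are compliant
  edge <- fake_descriptors(MW = 480, MR = 130, heavy_atoms = 70)
  expect_true(ghose(edge, wlogp_value = 5.6)$pass)
  expect_true(ghose(fake_descriptors(MW = 160, MR = 40, heavy_atoms = 20),
                    wlogp_value = -0.4)$pass)
})

test_that("Veber, Egan and Muegge behave per their thresholds", {
  expect_false(veber(fake_descriptors(rotatable_bonds = 11))$pass)
  expect_true(veber(fake_descriptors(rotatable_bonds = 10))$pass)

  ## extreme polarity fails all three
  polar <- fake_descriptors(TPSA = 500)
  expect_false(veber(polar)$pass)
  expect_false(egan(polar, wlogp_value = 2)$pass)
  expect_false(muegge(polar, logp_value = 2)$pass)

  ## ethanol fails the Muegge lower bounds while Lipinski passes
  eth <- compute_descriptor_panel(qmol("CCO"))
  expect_true(lipinski(eth)$pass)
  mg <- muegge(eth)
  expect_false(mg$pass)
  expect_true(any(grepl("MW <", mg$violations)))
  expect_true(any(grepl("carbons", mg$violations)))
})

test_that("violation lists enumerate exactly the breached sub-rules", {
  rules <- druglikeness_rules()
  set.seed(21)
  for (k in 1:200) {
    d <- fake_descriptors(
      MW = runif(1, 50, 800), TPSA = runif(1, 0, 300),
      rotatable_bonds = sample(0:20, 1), HBA = sample(0:15, 1),
      HBD = sample(0:10, 1), MR = runif(1, 10, 200),
      heavy_atoms = sample(5:100, 1), ring_count = sample(0:10, 1),
      carbon_count = sample(1:40, 1), heteroatoms = sample(0:15, 1))
    ml <- runif(1, -3, 8); wl <- runif(1, -3, 8)
    ## brute-force recount of breached thresholds per filter
    expect_length(lipinski(d, ml)$violations,
                  sum(d$MW > 500, ml > 4.15, d$HBD > 5, d$HBA > 10))
    expect_length(veber(d)$violations,
                  sum(d$rotatable_bonds > 10, d$TPSA > 140))
    expect_length(egan(d, wl)$violations,
                  sum(wl > 5.88, d$TPSA > 131.6))
    expect_length(ghose(d, wl)$violations,
                  sum(d$MW < 160 | d$MW > 480, wl < -0.4 | wl > 5.6,
                      d$MR < 40 | d$MR > 130,
                      d$heavy_atoms < 20 | d$heavy_atoms > 70))
    expect_length(muegge(d, wl)$violations,
                  sum(d$MW < 200, d$MW > 600, wl < -2, wl > 5,
                      d$TPSA > 150, d$ring_count > 7, d$carbon_count <= 4,
                      d$heteroatoms <= 1, d$rotatable_bonds > 15,
                      d$HBA > 10, d$HBD > 5))
  }
})

test_that("bioavailability score implements the four-class decision tree", {
  rules <- druglikeness_rules()
  pass <- structure(list(pass = TRUE), class = "adm_filter")
  fail <- structure(list(pass = FALSE), class = "adm_filter")
  ## anion branches by TPSA
  expect_equal(bioavailability_score(-1, 40, pass), 0.85)
  expect_equal(bioavailability_score(-1, 100, pass), 0.56)
  expect_equal(bioavailability_score(-1, 200, pass), 0.11)
  ## neutral molecules branch on Lipinski
  expect_equal(bioavailability_score(0, 70, pass), 0.56)
  expect_equal(bioavailability_score(0, 70, fail), 0.17)
  expect_equal(bioavailability_score(1, 70, fail), 0.17)
  ## the class set is exactly the four printed probabilities
  classes <- unique(c(
    bioavailability_score(-1, 40, pass), bioavailability_score(-1, 100, pass),
    bioavailability_score(-1, 200, pass), bioavailability_score(0, 70, pass),
    bioavailability_score(0, 70, fail)))
  expect_setequal(classes, c(0.11, 0.17, 0.56, 0.85))
  ## acetate end-to-end: mono-anion, low TPSA
  p <- adme_profile("CC(=O)[O-]", "acetate", fast_config())
  expect_equal(p$bioavailability_score, 0.85)
  expect_lte(p$descriptors$TPSA, 75)
})

test_that("radar flags exactly the out-of-range axes", {
  ## too flexible and too polar, everything else mid-range
  d <- fake_descriptors(rotatable_bonds = 12, TPSA = 180, MW = 350,
                        fraction_csp3 = 0.5)
  r <- radar(d, lipo = 2, esol = -3)
  expect_false(r$drug_like)
  expect_identical(names(which(!r$pass)), c("POLAR", "FLEX"))

  r2 <- radar(fake_descriptors(MW = 350, fraction_csp3 = 0.5),
              lipo = 2, esol = -3)
  expect_true(r2$drug_like)

  r3 <- radar(fake_descriptors(MW = 149.9, fraction_csp3 = 0.5),
              lipo = 2, esol = -3)
  expect_identical(names(which(!r3$pass)), "SIZE")
})

test_that("radar overall flag is the conjunction of the six axes", {
  set.seed(31)
  for (k in 1:1000) {
    d <- fake_descriptors(MW = runif(1, 50, 700), TPSA = runif(1, 0, 250),
                          fraction_csp3 = runif(1),
                          rotatable_bonds = sample(0:15, 1))
    r <- radar(d, lipo = runif(1, -3, 8), esol = runif(1, -9, 1))
    expect_identical(r$drug_like, all(r$pass))
    expect_length(r$pass, 6L)
  }
})
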