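test_that("solubility models are the published linear forms", {
  zero <- fake_descriptors(MW = 0, rotatable_bonds = 0,
                           aromatic_proportion = 0, TPSA = 0)
  ## intercepts at all-zero inputs
  expect_equal(esol_logs(zero, 0), 0.16)
  expect_equal(ali_logs(zero, 0), -1.0323)
  ## hand plug-in for ethanol descriptors with its atomistic log P
  m <- qmol("CCO")
  d <- compute_descriptor_panel(m)
  lp <- wlogp(m)
  expect_equal(esol_logs(d, lp),
               0.16 - 0.63 * lp - 0.0062 * d$MW + 0.066 * d$rotatable_bonds -
                 0.74 * d$aromatic_proportion)
  expect_equal(ali_logs(d, lp),
               -1.0323 - 1.0148 * lp - 0.0056 * d$TPSA)
  ## higher lipophilicity -> lower predicted solubility (negative slope)
  expect_lt(esol_logs(d, lp + 1), esol_logs(d, lp))
  expect_lt(ali_logs(d, lp + 1), ali_logs(d, lp))
  ## TPSA difference enters linearly with the model coefficient
  d2 <- fake_descriptors(TPSA = 100)
  d3 <- fake_descriptors(TPSA = 150)
  expect_equal(ali_logs(d3, 2) - ali_logs(d2, 2), -0.0056 * 50)
})

test_that("all three log S models satisfy superposition on random inputs", {
  set.seed(11)
  tab <- data.frame(kind = c("fragment", "sqrt_mw", "intercept"),
                    key = c("[OX2H]", "", ""), coef = c(-0.6, -0.1, 0.4))
  for (k in 1:25) {
    mw <- runif(2, 50, 500); rb <- sample(0:10, 2); ap <- runif(2)
    tp <- runif(2, 0, 200); lp <- rnorm(2, 1, 2); a <- runif(1)
    dA <- fake_descriptors(MW = mw[1], rotatable_bonds = rb[1],
                           aromatic_proportion = ap[1], TPSA = tp[1])
    dB <- fake_descriptors(MW = mw[2], rotatable_bonds = rb[2],
                           aromatic_proportion = ap[2], TPSA = tp[2])
    dMix <- fake_descriptors(
      MW = a * mw[1] + (1 - a) * mw[2],
      rotatable_bonds = a * rb[1] + (1 - a) * rb[2],
      aromatic_proportion = a * ap[1] + (1 - a) * ap[2],
      TPSA = a * tp[1] + (1 - a) * tp[2])
    lmix <- a * lp[1] + (1 - a) * lp[2]
    expect_equal(esol_logs(dMix, lmix),
                 a * esol_logs(dA, lp[1]) + (1 - a) * esol_logs(dB, lp[2]),
                 tolerance = 1e-9)
    expect_equal(ali_logs(dMix, lmix),
                 a * ali_logs(dA, lp[1]) + (1 - a) * ali_logs(dB, lp[2]),
                 tolerance = 1e-9)
  }
  ## fragmental model: doubling a fragment count doubles the fragment term
  mono <- fragment_logs(qmol("OCC"), tab) # 1 hydroxyl
  diol <- fragment_logs(qmol("OCCO"), tab) # 2 hydroxyls
  mw1 <- molecular_weight(qmol("OCC")); mw2 <- molecular_weight(qmol("OCCO"))
  expect_equal(diol - (0.4 - 0.1 * sqrt(mw2)),
               2 * (mono - (0.4 - 0.1 * sqrt(mw1))), tolerance = 1e-9)
  ## empty-match molecule: intercept + sqrt(MW) term only
  eth <- qmol("CC")
  expect_equal(fragment_logs(eth, tab),
               0.4 - 0.1 * sqrt(molecular_weight(eth)))
  expect_error(fragment_logs(eth, NULL), class = "adm_missing_table")
})

test_that("solubility classes reproduce the printed scale", {
  expect_equal(solubility_class(-11), "insoluble")
  expect_equal(solubility_class(-5), "moderately")
  expect_equal(solubility_class(0.5), "highly")
  expect_equal(solubility_class(-7), "poorly")
  expect_equal(solubility_class(-3), "soluble")
  expect_equal(solubility_class(-1), "very")
  ## boundaries take the more soluble side
  expect_equal(solubility_class(-10), "poorly")
  expect_equal(solubility_class(-4), "soluble")
  expect_equal(solubility_class(0), "highly")
  ## monotone non-decreasing over the label order
  lv <- match(vapply(seq(-12, 1, by = 0.25), solubility_class, ""),
              admetk:::SOLUBILITY_CLASS_LEVELS)
  expect_true(all(diff(lv) >= 0))
})

test_that("log S converts exactly to molar and mass amounts", {
  expect_equal(logs_to_amounts(0, 100),
               c(mol_per_l = 1, mg_per_ml = 100))
  expect_equal(logs_to_amounts(-3, 200),
               c(mol_per_l = 1e-3, mg_per_ml = 0.2))
  expect_equal(logs_to_amounts(-10, 500),
               c(mol_per_l = 1e-10, mg_per_ml = 5e-8))
  p <- solubility_prediction(-2.5, 250)
  expect_equal(p$mol_per_l, 10^-2.5)
  expect_equal(p$mg_per_ml, 10^-2.5 * 250)
  expect_equal(p$class_label, "soluble")
})

test_that("skin permeation is linear with the stated signs and cm/s units", {
  d300 <- fake_descriptors(MW = 300)
  ## hand evaluation: -2.74 + 0.71*2 - 0.0061*300, minus log10(3600)
  expect_equal(skin_log_kp(d300, 2),
               -2.74 + 0.71 * 2 - 0.0061 * 300 - log10(3600))
  ## heavier -> less permeant; more lipophilic -> more permeant
  expect_lt(skin_log_kp(fake_descriptors(MW = 400), 2),
            skin_log_kp(d300, 2))
  expect_gt(skin_log_kp(d300, 3), skin_log_kp(d300, 2))
})

test_that("egg classification: geometry, membership and range flags", {
  g <- load_egg_geometry()
  ## the yolk centre is brain-penetrant by construction
  r <- boiled_egg(g$yolk$cx, g$yolk$cy, g)
  expect_true(r$bbb)
  ## far exterior point
  expect_false(boiled_egg(199, 7.9, g)$bbb &&
                 boiled_egg(199, 7.9, g)$hia)
  ## extreme polarity is out of the plot range entirely
  r2 <- boiled_egg(1e6, 0, g)
  expect_false(r2$in_plot_range || r2$hia || r2$bbb)
  ## the white and yolk overlap (not mutually exclusive)
  r3 <- boiled_egg(g$yolk$cx, g$yolk$cy, g)
  expect_true(r3$bbb && r3$hia)
})

test_that("point-in-ellipse matches the quadratic-form oracle on random points", {
  g <- load_egg_geometry()
  set.seed(4)
  x <- runif(1000, -50, 250)
  y <- runif(1000, -10, 12)
  for (ell in list(g$white, g$yolk)) {
    mine <- mapply(function(a, b) in_ellipse(a, b, ell), x, y)
    oracle <- mapply(function(a, b) in_ellipse_bruteforce(a, b, ell), x, y)
    expect_identical(mine, oracle)
  }
})

test_that("out-of-range molecules are never classified positive", {
  g <- load_egg_geometry()
  set.seed(5)
  for (k in 1:200) {
    tp <- runif(1, -100, 400); wl <- runif(1, -10, 15)
    r <- boiled_egg(tp, wl, g)
    if (!r$in_plot_range) expect_false(r$hia || r$bbb)
  }
})
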