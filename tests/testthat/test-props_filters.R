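test_that("rule-of-five descriptors and thresholds behave as defined", {
  methane <- growkit:::mol_from_smiles("C", gen3d = FALSE)
  r <- ro5_report(methane)
  expect_equal(r$ro5_violations, 0)
  expect_true(r$ro5_compliant)
  expect_equal(r$hbd, 0)
  expect_equal(r$hba, 0)

  aspirin <- growkit:::mol_from_smiles("CC(=O)Oc1ccccc1C(=O)O", gen3d = FALSE)
  ra <- ro5_report(aspirin)
  expect_equal(ra$mw, 180.16, tolerance = 1e-3)
  expect_equal(ra$hbd, 1)
  expect_equal(ra$hba, 4)
  expect_equal(ra$ro5_violations, 0)

  # all four thresholds crossed
  worst <- growkit:::.ro5_from_descriptors(mw = 600, clogp = 6,
                                           hbd = 6, hba = 11)
  expect_equal(worst$ro5_violations, 4)
  expect_false(worst$ro5_compliant)
  # exactly one violation still counts as compliant
  one <- growkit:::.ro5_from_descriptors(mw = 550, clogp = 2, hbd = 1, hba = 4)
  expect_equal(one$ro5_violations, 1)
  expect_true(one$ro5_compliant)
})

test_that("violation counts equal brute-force re-evaluation on grown ligands", {
  core <- fx_core()
  for (lab in c("methyl", "propoxy", "trifluoromethyl", "uracil-1-yl")) {
    r <- ro5_report(attach_rgroup(core, fx_library()[[lab]]))
    expect_equal(r$ro5_violations,
                 (r$mw > 500) + (r$clogp > 5) + (r$hbd > 5) + (r$hba > 10),
                 info = lab)
  }
})

test_that("synthetic accessibility scores common fragments as easy", {
  benzene <- growkit:::mol_from_smiles("c1ccccc1", gen3d = FALSE)
  expect_lt(as.numeric(sa_score(benzene)), 3)
  expect_error(sa_score(growkit:::mol_from_smiles("[H][H]", gen3d = FALSE)),
               "no heavy atoms")
})

test_that("synthetic accessibility stays in [1, 10] across combinations", {
  core <- fx_core()
  for (rg in fx_library()) {
    s <- as.numeric(sa_score(attach_rgroup(core, rg)))
    expect_gte(s, 1)
    expect_lte(s, 10)
  }
})

test_that("stereo centres are detected and penalise the score monotonically", {
  chiral <- growkit:::mol_from_smiles("CC(Cl)CC", gen3d = FALSE)
  achiral <- growkit:::mol_from_smiles("CCCCCl", gen3d = FALSE)
  expect_equal(growkit:::.sa_stereo_count(chiral), 1)
  expect_equal(growkit:::.sa_stereo_count(achiral), 0)

  # removing the stereo penalty from the total can only lower the score
  s <- sa_score(chiral)
  terms <- attr(s, "terms")
  expect_gt(terms[["stereo_pen"]], 0)
  without <- 1 + 9 * (-(terms[["frag_mean"]] - terms[["size_pen"]] -
                          terms[["macro_pen"]] - terms[["ring_pen"]])) / 6
  expect_gte(as.numeric(s), min(10, max(1, without)))
})

test_that("substructure catalogs flag liabilities and stay monotone", {
  methane <- growkit:::mol_from_smiles("C", gen3d = FALSE)
  f0 <- substructure_flags(methane)
  expect_false(f0$pains || f0$nih || f0$unwanted)
  expect_length(f0$matched_patterns, 0)

  rhod <- growkit:::mol_from_smiles("O=C1CSC(=S)N1", gen3d = FALSE)
  f1 <- substructure_flags(rhod)
  expect_true(f1$pains)
  expect_true(any(grepl("rhodanine", f1$matched_patterns)))

  # a supermolecule containing the flagged substructure is also flagged
  super <- growkit:::mol_from_smiles("O=C1CSC(=S)N1Cc1ccccc1", gen3d = FALSE)
  expect_true(substructure_flags(super)$pains)

  expect_error(substructure_flags(methane, catalog_dir = tempdir()),
               "missing")
})

test_that("reports are deterministic for the same molecule", {
  lig <- attach_rgroup(fx_core(), fx_library()$methoxy)
  expect_identical(property_report(lig), property_report(lig))
})
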