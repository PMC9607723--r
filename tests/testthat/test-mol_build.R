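test_that("load_core validates the attachment hydrogen", {
  core <- fx_core()
  expect_s3_class(core, "gk_template")
  expect_equal(growkit:::mol_natoms(core$mol), 12)  # 6 C + 6 H
  expect_equal(core$mol$atoms$elem[core$attachment_h], "H")
  expect_length(core$flexible_atoms, 0)

  expect_error(load_core(growkit_example("core_benzene.sdf"), 1),
               "hydrogen")
  expect_error(load_core(growkit_example("core_benzene.sdf"), 99),
               "out of range")
})

test_that("load_core rejects structures without 3D coordinates", {
  flat <- ChemmineOB::convertFormat(
    "SMI", "SDF", source = "c1ccccc1 flat",
    options = data.frame(names = c("h", "gen2d"), args = c("", "")))
  f <- tempfile(fileext = ".sdf")
  writeLines(flat, f)
  expect_error(load_core(f, 7), "3D|2D")
})

test_that("attachment performs clean bond surgery", {
  core <- fx_core()
  lib <- fx_library()

  tol <- attach_rgroup(core, lib$methyl)
  expect_equal(growkit:::mol_formula(tol$mol), "C7H8")  # toluene
  # conservation: template - 1 H + rgroup - 1 H
  expect_equal(growkit:::mol_natoms(tol$mol),
               12 - 1 + growkit:::mol_natoms(lib$methyl$mol) - 1)
  # core map is injective over the kept template atoms and disjoint from
  # the grown atoms
  expect_false(any(duplicated(tol$core_map)))
  expect_length(intersect(tol$rgroup_atoms, tol$core_map), 0)
  # template coordinates copied onto core atoms unchanged
  tco <- growkit:::mol_coords(core$mol)
  mco <- growkit:::mol_coords(tol$mol)
  keep <- as.integer(names(tol$core_map))
  expect_equal(mco[unname(tol$core_map), ], tco[keep, ], tolerance = 1e-12)
  # total formal charge is additive
  expect_equal(growkit:::mol_total_charge(tol$mol),
               growkit:::mol_total_charge(core$mol) +
                 growkit:::mol_total_charge(lib$methyl$mol))

  # hydrogen "R-group" reproduces benzene
  hh <- attach_rgroup(core, lib$H)
  expect_equal(growkit:::mol_formula(hh$mol), "C6H6")
})

test_that("an R-group with a fully substituted attachment atom is rejected", {
  # CF4-like fragment: attachment carbon has no hydrogen left to consume
  m <- growkit:::mol_from_smiles("FC(F)(F)F", gen3d = FALSE)
  expect_error(rgroup(m, attachment_atom = 2L, label = "bad"), "no hydrogen")
})

test_that("conservation law holds across the whole library", {
  core <- fx_core()
  for (rg in fx_library()) {
    lig <- attach_rgroup(core, rg)
    expect_equal(growkit:::mol_natoms(lig$mol),
                 12 - 1 + growkit:::mol_natoms(rg$mol) - 1,
                 info = rg$label)
  }
})

test_that("extend_flexible edits the restrained set and validates input", {
  lig <- attach_rgroup(fx_core(), fx_library()$benzyl)
  r0 <- growkit:::restrained_atoms(lig)

  expect_identical(growkit:::restrained_atoms(extend_flexible(lig, integer(0))),
                   r0)
  # core atom adjacent to the growth vector becomes unrestrained
  anchor <- unname(lig$core_map[1])
  lig2 <- extend_flexible(lig, anchor)
  expect_false(anchor %in% growkit:::restrained_atoms(lig2))
  expect_setequal(growkit:::restrained_atoms(lig2), setdiff(r0, anchor))

  expect_error(extend_flexible(lig, lig$rgroup_atoms[1]), "already flexible")
  expect_error(extend_flexible(lig, 999L), "not part of the core")
})

test_that("restrained conformers stay on the template core", {
  core <- fx_core()
  lig <- attach_rgroup(core, fx_library()$propoxy)
  lig <- enumerate_conformers(lig, embed_config(n_conformers = 5, seed = 7))
  expect_gte(length(lig$ensemble$coords), 1)
  expect_true(all(lig$ensemble$flags$vacuum_minimised))
  expect_true(all(is.finite(lig$ensemble$energy)))

  ra <- growkit:::restrained_atoms(lig)
  tco <- growkit:::mol_coords(core$mol)
  ti <- as.integer(names(lig$core_map))[match(ra, lig$core_map)]
  for (co in lig$ensemble$coords) {
    d <- co[ra, , drop = FALSE] - tco[ti, , drop = FALSE]
    expect_lt(sqrt(mean(rowSums(d * d))), 0.1)
  }
})

test_that("rigid growth yields a single conformer after deduplication", {
  lig <- attach_rgroup(fx_core(), fx_library()$fluoro)
  lig <- enumerate_conformers(lig, embed_config(n_conformers = 8, seed = 3))
  expect_equal(length(lig$ensemble$coords), 1)
})

test_that("embedding config validates its arguments", {
  expect_error(embed_config(n_conformers = 0), "positive")
  expect_error(embed_config(restraint_k = -1), "restraint_k")
})

test_that("conformer enumeration is deterministic and dedup is idempotent", {
  core <- fx_core()
  run <- function() {
    enumerate_conformers(attach_rgroup(core, fx_library()$ethoxy),
                         embed_config(n_conformers = 6, seed = 11))
  }
  a <- run(); b <- run()
  expect_identical(a$ensemble$coords, b$ensemble$coords)
  expect_identical(a$ensemble$energy, b$ensemble$energy)

  again <- growkit:::ensemble_dedup(a$ensemble, a, 0.5)
  expect_identical(again$coords, a$ensemble$coords)
})

test_that("core_map recovers the template embedding by MCS", {
  core <- fx_core()
  tol <- attach_rgroup(core, fx_library()$methyl)
  cm <- core_map(tol, core)
  expect_length(cm, 6)  # six ring carbons
  # agrees with the mapping recorded at attach time
  rec <- tol$core_map[names(cm)]
  expect_equal(unname(cm), unname(rec))

  # identity mapping on the same molecule
  idm <- mcs_map(core$mol, core$mol)
  expect_equal(idm[, "a"], idm[, "b"])

  # disjoint chemistry: core mismatch error
  ethane <- growkit:::mol_from_smiles("CC", gen3d = FALSE)
  expect_error(mcs_map(core$mol, ethane), "core mismatch")
})

test_that("MCS size agrees with exhaustive enumeration on small molecules", {
  smi <- list(
    c("c1ccccc1C", "c1ccccc1CC"),     # toluene vs ethylbenzene
    c("c1ccncc1", "c1ccccc1"),        # pyridine vs benzene
    c("CCO", "CCCO"),                 # ethanol vs propanol
    c("C1CC1C", "C1CC1CC"),           # cyclopropane derivatives
    c("CC(=O)O", "CC(=O)N"))          # acid vs amide
  for (pair in smi) {
    a <- growkit:::mol_from_smiles(pair[1], gen3d = FALSE)
    b <- growkit:::mol_from_smiles(pair[2], gen3d = FALSE)
    m <- mcs_map(a, b, min_size = 1)
    expect_equal(nrow(m), oracle_mcs_size(a, b),
                 info = paste(pair, collapse = " vs "))
  }
})
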