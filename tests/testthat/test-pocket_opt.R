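test_that("scaling parameters derive the charge scale and validate input", {
  s <- scaling_params()
  expect_equal(s$lj_scale, 0.8)
  expect_equal(s$epsilon, 4)
  expect_identical(s$charge_scale, 4^(-0.5))
  expect_error(scaling_params(lj_scale = 0), "lj_scale")
  expect_error(scaling_params(epsilon = 0.5), "epsilon")
})

test_that("clash filter applies a strict 1 A cutoff", {
  # two-atom "ligand" conformers at controlled distances from one receptor atom
  lig <- fx_point_ligand()
  rec <- make_point_receptor(matrix(c(0, 0, 0), 1, 3))
  ens <- growkit:::.new_ensemble()
  ens <- growkit:::ensemble_add(ens, matrix(c(0.9, 0, 0), 1, 3))   # clash
  ens <- growkit:::ensemble_add(ens, matrix(c(1.0, 0, 0), 1, 3))   # boundary
  ens <- growkit:::ensemble_add(ens, matrix(c(5.0, 0, 0), 1, 3))   # free
  out <- clash_filter(ens, rec, cutoff = 1.0)
  expect_identical(out$flags$clash_rejected, c(TRUE, FALSE, FALSE))

  # an empty receptor rejects nothing
  empty <- make_point_receptor(matrix(numeric(0), 0, 3))
  out2 <- clash_filter(ens, empty)
  expect_false(any(out2$flags$clash_rejected))
})

test_that("clash filter agrees with the brute-force oracle on random sets", {
  set.seed(101)
  for (k in 1:100) {
    nl <- sample(2:6, 1); nr <- sample(2:8, 1)
    lig_xyz <- matrix(runif(nl * 3, 0, 4), nl, 3)
    rec_xyz <- matrix(runif(nr * 3, 0, 4), nr, 3)
    rec <- make_point_receptor(rec_xyz)
    ens <- growkit:::ensemble_add(growkit:::.new_ensemble(), lig_xyz)
    got <- clash_filter(ens, rec, cutoff = 1.0)$flags$clash_rejected
    want <- oracle_pairwise_min_distance(lig_xyz, rec_xyz) < 1.0
    expect_identical(got, want)
  }
})

test_that("the ML element gate falls back to MM for uncovered elements", {
  lig_ok <- attach_rgroup(fx_core(), fx_library()$amino)
  expect_identical(backend_select(lig_ok, want_ml = TRUE), "ml")
  expect_identical(backend_select(lig_ok, want_ml = FALSE), "mm")

  lig_br <- attach_rgroup(fx_core(), fx_library()$bromo)
  expect_warning(b <- backend_select(lig_br, want_ml = TRUE), "Br")
  expect_identical(b, "mm")
})

test_that("the coupling term obeys the Coulomb and dielectric scaling laws", {
  # two unit charges 10 A apart: k_C * (0.5 * 0.5) / 10 at epsilon = 4
  lig <- fx_point_ligand(pcharge = 1)
  rec <- make_point_receptor(matrix(c(10, 0, 0), 1, 3), pcharge = 1)
  pot4 <- build_hybrid_potential(lig, rec, scaling = scaling_params(0.8, 4))
  c4 <- pot_e_coupling(pot4, matrix(0, 1, 3), parts = TRUE)$coulomb
  expect_equal(c4, 332.0637 * 0.25 / 10, tolerance = 1e-10)
  expect_equal(c4, 8.3016, tolerance = 1e-4)

  pot1 <- build_hybrid_potential(lig, rec, scaling = scaling_params(0.8, 1))
  c1 <- pot_e_coupling(pot1, matrix(0, 1, 3), parts = TRUE)$coulomb
  expect_equal(c4 / c1, 0.25, tolerance = 1e-12)

  # the law holds for an arbitrary fixed geometry of a real ligand
  ref <- fx_refined()
  x <- ref$ligand$ensemble$coords[[1]]
  p1 <- build_hybrid_potential(ref$ligand, ref$receptor,
                               scaling = scaling_params(0.8, 1))
  p4 <- build_hybrid_potential(ref$ligand, ref$receptor,
                               scaling = scaling_params(0.8, 4))
  expect_equal(pot_e_coupling(p4, x, parts = TRUE)$coulomb,
               pot_e_coupling(p1, x, parts = TRUE)$coulomb / 4,
               tolerance = 1e-12)
})

test_that("LJ scaling moves every pair minimum to lj_scale times r_min", {
  # 1-D scan oracle on the scaled 12-6 function
  lig <- fx_point_ligand(elem = "O")  # vdW x = 3.5 -> combined r_min 3.5
  rec <- make_point_receptor(matrix(0, 1, 3), rmin = 3.5, eps = 0.15)
  for (s in c(1, 0.9, 0.8, 0.5)) {
    pot <- build_hybrid_potential(lig, rec,
                                  scaling = scaling_params(s, 4))
    r <- seq(1.5, 6, by = 1e-3)
    e <- vapply(r, function(d) {
      pot_e_coupling(pot, matrix(c(d, 0, 0), 1, 3))
    }, numeric(1))
    expect_equal(r[which.min(e)], s * 3.5, tolerance = 1e-3)
  }
})

test_that("a single atom minimises to the scaled contact distance", {
  lig <- fx_point_ligand(elem = "O", xyz = c(4, 0, 0))
  rec <- make_point_receptor(matrix(0, 1, 3), rmin = 3.5, eps = 0.15)
  pot <- build_hybrid_potential(lig, rec, scaling = scaling_params(0.8, 4))
  out <- minimise_in_pocket(lig$ensemble, pot, core_restraints = FALSE)
  expect_equal(sqrt(sum(out$coords[[1]]^2)), 2.80, tolerance = 0.01)
  expect_true(out$flags$pocket_minimised[1])
})

test_that("the mechanical-embedding partition of E_tot is exact", {
  ref <- fx_refined()
  lig <- ref$ligand; rec <- ref$receptor
  x <- lig$ensemble$coords[[1]]

  pot <- build_hybrid_potential(lig, rec, backend = "mm")
  parts <- pot$e_receptor + pot_e_coupling(pot, x) + pot_e_ligand(pot, x)
  expect_lt(abs(pot_e_total(pot, x) - parts), 1e-6)

  # "ML" slot configured with the same MM force field reproduces the plain
  # MM complex single point
  mm_intra <- pot$intra
  ml_fn <- function(xyz) growkit:::ff_eval(xyz, mm_intra,
                                           want_grad = FALSE)$E
  pot_ml <- build_hybrid_potential(lig, rec, backend = "ml",
                                   ml_energy = ml_fn)
  expect_lt(abs(pot_e_total(pot_ml, x) - pot_e_complex_mm(pot, x)), 1e-6)

  # identity scaling: hybrid total equals the unscaled complex single point
  pot_id <- build_hybrid_potential(lig, rec,
                                   scaling = scaling_params(1, 1))
  expect_lt(abs(pot_e_total(pot_id, x) - pot_e_complex_mm(pot_id, x)), 1e-6)
})

test_that("pocket minimisation lowers energy, keeps receptor and core fixed", {
  ref <- fx_refined()
  lig <- ref$ligand; rec <- ref$receptor; pot <- ref$potential
  rec_before <- receptor_coords(rec)

  ens0 <- clash_filter(lig$ensemble, rec)
  e_before <- vapply(ens0$coords, function(x) pot_e_total(pot, x), numeric(1))
  ens <- minimise_in_pocket(ens0, pot)
  expect_true(all(ens$energy <= e_before + 1e-9))
  expect_identical(receptor_coords(rec), rec_before)

  # restrained core heavy atoms stay at the template position
  ra <- growkit:::restrained_atoms(lig)
  tco <- growkit:::mol_coords(lig$template$mol)
  ti <- as.integer(names(lig$core_map))[match(ra, lig$core_map)]
  for (co in ens$coords) {
    d <- co[ra, , drop = FALSE] - tco[ti, , drop = FALSE]
    expect_lt(sqrt(mean(rowSums(d * d))), 0.1)
  }

  # re-minimising an already-minimised ensemble changes energies marginally
  ens2 <- minimise_in_pocket(ens, pot)
  expect_true(all(ens$energy - ens2$energy <= 1e-4 + 1e-9))
})

test_that("energy-window selection keeps the window boundary inclusive", {
  ens <- growkit:::.new_ensemble()
  for (e in c(0.0, 3.2, 4.9, 5.1)) {
    ens <- growkit:::ensemble_add(ens, matrix(e, 1, 3), energy = e)
  }
  sel <- select_low_energy(ens, window = 5.0)
  expect_equal(sum(sel$flags$selected), 3)
  expect_equal(attr(sel, "selection"), c(1, 2, 3))

  # exact boundary is selected
  ens2 <- growkit:::ensemble_add(ens, matrix(5, 1, 3), energy = 5.0)
  expect_equal(sum(select_low_energy(ens2, 5)$flags$selected), 4)

  # single conformer selects itself
  one <- growkit:::ensemble_add(growkit:::.new_ensemble(),
                                matrix(0, 1, 3), energy = -2)
  expect_equal(sum(select_low_energy(one)$flags$selected), 1)

  # monotone in the window
  counts <- vapply(c(6, 5, 4, 3, 1, 0.5), function(w) {
    sum(select_low_energy(ens, w)$flags$selected)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # no energies at all is an error
  none <- growkit:::ensemble_add(growkit:::.new_ensemble(), matrix(0, 1, 3))
  expect_error(select_low_energy(none), "no conformer energies")
})

test_that("R-group RMSD measures displacement without superposition", {
  lig <- attach_rgroup(fx_core(), fx_library()$methyl)
  x <- growkit:::mol_coords(lig$mol)
  rg <- lig$rgroup_atoms

  expect_equal(rgroup_rmsd(x, x, rg, mol = lig$mol), 0)
  shifted <- x
  shifted[rg, ] <- shifted[rg, ] + matrix(c(1, 0, 0), length(rg), 3,
                                          byrow = TRUE)
  expect_equal(rgroup_rmsd(x, shifted, rg, mol = lig$mol), 1.0,
               tolerance = 1e-12)
  expect_equal(rgroup_rmsd(shifted, x, rg, mol = lig$mol), 1.0,
               tolerance = 1e-12)  # symmetric in argument order
  expect_error(rgroup_rmsd(x, x, integer(0)), "empty")
})

test_that("symmetry-aware RMSD recognises the phenyl two-fold flip", {
  lig <- attach_rgroup(fx_core(), fx_library()$phenyl)
  x <- growkit:::mol_coords(lig$mol)
  rg <- lig$rgroup_atoms

  # rotate the grown phenyl 180 degrees about its attachment axis
  anchor <- growkit:::mol_neighbors(lig$mol, lig$rgroup_atoms[1])
  anchor <- anchor[!(anchor %in% lig$rgroup_atoms)][1]
  a_pos <- x[lig$rgroup_atoms[1], ]
  axis <- a_pos - x[anchor, ]
  flipped <- x
  flipped[rg, ] <- growkit:::.rotate_about_axis(x[rg, , drop = FALSE],
                                                a_pos, axis, pi)
  plain <- rgroup_rmsd(x, flipped, rg, symmetry = FALSE, mol = lig$mol)
  sym <- rgroup_rmsd(x, flipped, rg, symmetry = TRUE, mol = lig$mol)
  expect_gt(plain, 0.5)
  expect_lt(sym, 0.05)
})

test_that("dihedrals follow the sign convention and are rotation invariant", {
  # ideal anti butane backbone
  anti <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0), c(3.5, 1.4, 0))
  expect_equal(abs(dihedral(anti, 1:4)), 180, tolerance = 1e-6)
  # planar cis
  cis <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0), c(1.5, 2.8, 0))
  expect_equal(dihedral(cis, 1:4), 0, tolerance = 1e-6)

  set.seed(7)
  for (k in 1:20) {
    x <- matrix(rnorm(12), 4, 3)
    d0 <- tryCatch(dihedral(x, 1:4), error = function(e) NA)
    if (is.na(d0)) next
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                   sin(th[2]), 0, cos(th[2])), 3, 3)
    xr <- x %*% (Rz %*% Ry) + matrix(rnorm(3), 4, 3, byrow = TRUE)
    expect_equal(dihedral(xr, 1:4), d0, tolerance = 1e-6)
  }

  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral(collinear, 1:4), "collinear")
  expect_error(dihedral(anti, c(1, 1, 2, 3)), "distinct")
})
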