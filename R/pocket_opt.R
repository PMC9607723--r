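# Refinement of ligand conformers inside the rigid pocket under the hybrid
# mechanical-embedding potential
#
#     E_tot = E_MM(R) + E_MM(RL) + E_lig(L)
#
# where the receptor term is constant (rigid receptor), the coupling term is
# Coulomb + Lennard-Jones 12-6 with the pocket scaling rules applied, and the
# ligand intramolecular term comes from either the built-in MM backend or a
# pluggable ML-style callable.

#' Pocket scaling parameters
#'
#' During optimisation Lennard-Jones minimum-energy distances of
#' receptor-ligand pairs are multiplied by `lj_scale` (making extra room in
#' the rigid pocket) and all atomic charges entering the coupling term are
#' multiplied by `1/sqrt(epsilon)`, so pairwise Coulomb energies scale by
#' `1/epsilon` (implicit dielectric screening).
#'
#' @param lj_scale dimensionless factor in (0, 1], default 0.8.
#' @param epsilon relative permittivity >= 1, default 4.
#' @return a `gk_scaling` with the derived `charge_scale = epsilon^(-1/2)`.
#' @export
scaling_params <- function(lj_scale = 0.8, epsilon = 4) {
  if (lj_scale <= 0 || lj_scale > 1) stop("lj_scale must be in (0, 1]")
  if (epsilon < 1) stop("epsilon must be >= 1")
  structure(list(lj_scale = lj_scale, epsilon = epsilon,
                 charge_scale = epsilon^(-0.5)),
            class = "gk_scaling")
}

#' Minimum ligand-receptor atom pair distance per conformer
#' @keywords internal
.min_cross_dist <- function(lig_xyz, rec_xyz) {
  if (nrow(rec_xyz) == 0 || nrow(lig_xyz) == 0) return(Inf)
  d2 <- outer(rowSums(lig_xyz^2), rowSums(rec_xyz^2), "+") -
    2 * lig_xyz %*% t(rec_xyz)
  sqrt(max(0, min(d2)))
}

#' Reject conformers that clash sterically with the receptor
#'
#' A conformer is rejected when any ligand-receptor atom pair (hydrogens
#' included) is closer than `cutoff`; the comparison is strictly `<`, so a
#' contact at exactly the cutoff is retained.
#'
#' @param ensemble a `gk_ensemble`.
#' @param receptor a `gk_receptor` (its coordinates are used as-is).
#' @param cutoff clash distance in Angstrom (default 1.0).
#' @return the ensemble with `clash_rejected` flags set.
#' @export
clash_filter <- function(ensemble, receptor, cutoff = 1.0) {
  stopifnot(inherits(ensemble, "gk_ensemble"))
  rec <- receptor_coords(receptor)
  for (k in seq_along(ensemble$coords)) {
    ensemble$flags$clash_rejected[k] <-
      .min_cross_dist(ensemble$coords[[k]], rec) < cutoff
  }
  ensemble
}

#' Choose the ligand intramolecular backend
#'
#' The ML backend is used only when requested and when every element of the
#' ligand is covered by the model (H, C, N, O, F, S, Cl); otherwise the
#' classical MM backend is selected, with a warning naming the uncovered
#' elements when ML was requested.
#'
#' @param ligand a `gk_ligand` or `gk_mol`.
#' @param want_ml logical.
#' @return `"ml"` or `"mm"`.
#' @export
backend_select <- function(ligand, want_ml = FALSE) {
  mol <- if (inherits(ligand, "gk_ligand")) ligand$mol else ligand
  if (!want_ml) return("mm")
  off <- setdiff(mol_elements(mol), .gk_ml_elements)
  if (length(off) > 0) {
    warning("ML backend unavailable: element(s) ",
            paste(off, collapse = ", "),
            " not covered; falling back to the classical force field")
    return("mm")
  }
  "ml"
}

#' Build the hybrid mechanical-embedding potential for a ligand in a pocket
#'
#' @param ligand a `gk_ligand` with partial charges (assigned if missing).
#' @param receptor a parameterised `gk_receptor`.
#' @param backend `"mm"` or `"ml"` (see [backend_select()]).
#' @param scaling a [scaling_params()].
#' @param ml_energy optional callable `function(xyz) -> kcal/mol` for the
#'   ligand term when `backend == "ml"`; by default the built-in MM backend
#'   fills the slot, which makes the term partition exactly recoverable.
#' @return a `gk_potential`.
#' @export
build_hybrid_potential <- function(ligand, receptor, backend = "mm",
                                   scaling = scaling_params(),
                                   ml_energy = NULL) {
  stopifnot(inherits(ligand, "gk_ligand"), inherits(receptor, "gk_receptor"))
  if (!receptor$parameterised) stop("receptor is not parameterised")
  if (!backend %in% c("mm", "ml")) stop("backend must be 'mm' or 'ml'")
  mol <- ligand$mol
  if (anyNA(mol$atoms$pcharge)) {
    mol <- mol_assign_charges(mol)
    ligand$mol <- mol
  }
  nl <- mol_natoms(mol); nr <- nrow(receptor$atoms)

  intra <- ff_intra_terms(mol, ref_coords = mol_coords(mol))

  # coupling pairs: every ligand atom against every receptor atom
  ext <- NULL
  if (nr > 0) {
    li <- rep(seq_len(nl), times = nr)
    rj <- rep(seq_len(nr), each = nl)
    xl <- .gk_elem_prop(mol$atoms$elem, "vdw_x")[li]
    dl <- .gk_elem_prop(mol$atoms$elem, "vdw_d")[li]
    ext <- list(
      i = li, j = rj, xyz = receptor_coords(receptor),
      rmin = scaling$lj_scale * sqrt(xl * receptor$atoms$rmin[rj]),
      eps = sqrt(dl * receptor$atoms$eps[rj]),
      qq = .gk_kcoul * (mol$atoms$pcharge[li] * scaling$charge_scale) *
        (receptor$atoms$pcharge[rj] * scaling$charge_scale))
  }

  # constant receptor-receptor nonbonded energy (rigid receptor)
  e_r <- 0
  if (nr > 1) {
    rxyz <- receptor_coords(receptor)
    idx <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
    dvec <- rxyz[idx[, 1], , drop = FALSE] - rxyz[idx[, 2], , drop = FALSE]
    r <- pmax(sqrt(rowSums(dvec^2)), 0.05)
    rmin <- sqrt(receptor$atoms$rmin[idx[, 1]] * receptor$atoms$rmin[idx[, 2]])
    eps <- sqrt(receptor$atoms$eps[idx[, 1]] * receptor$atoms$eps[idx[, 2]])
    qq <- .gk_kcoul * receptor$atoms$pcharge[idx[, 1]] *
      receptor$atoms$pcharge[idx[, 2]]
    s6 <- (rmin / r)^6
    e_r <- sum(eps * (s6^2 - 2 * s6)) + sum(qq / r)
  }

  structure(list(ligand = ligand, receptor = receptor, backend = backend,
                 scaling = scaling, intra = intra, ext = ext, e_receptor = e_r,
                 ml_energy = ml_energy),
            class = "gk_potential")
}

#' @export
print.gk_potential <- function(x, ...) {
  cat(sprintf(
    "<gk_potential> backend=%s, lj_scale=%.2f, epsilon=%.1f, E_MM(R)=%.4f\n",
    x$backend, x$scaling$lj_scale, x$scaling$epsilon, x$e_receptor))
  invisible(x)
}

#' Ligand intramolecular energy term of a hybrid potential
#' @param potential a `gk_potential`.
#' @param xyz ligand coordinates.
#' @export
pot_e_ligand <- function(potential, xyz) {
  if (potential$backend == "ml" && !is.null(potential$ml_energy)) {
    return(potential$ml_energy(xyz))
  }
  sys <- potential$intra
  sys$ext <- NULL; sys$restr <- NULL
  ff_eval(xyz, sys, want_grad = FALSE)$E
}

#' Receptor-ligand coupling energy (scaled Coulomb + Lennard-Jones)
#' @param potential a `gk_potential`.
#' @param xyz ligand coordinates.
#' @param parts return a list with `coulomb` and `lj` components.
#' @export
pot_e_coupling <- function(potential, xyz, parts = FALSE) {
  p <- potential$ext
  if (is.null(p)) {
    return(if (parts) list(coulomb = 0, lj = 0, total = 0) else 0)
  }
  dvec <- xyz[p$i, , drop = FALSE] - p$xyz[p$j, , drop = FALSE]
  r <- pmax(sqrt(rowSums(dvec^2)), 0.05)
  s6 <- (p$rmin / r)^6
  lj <- sum(p$eps * (s6^2 - 2 * s6))
  coul <- sum(p$qq / r)
  if (parts) list(coulomb = coul, lj = lj, total = coul + lj) else coul + lj
}

#' Total hybrid energy E_tot = E_MM(R) + E_MM(RL) + E_lig(L)
#' @param potential a `gk_potential`.
#' @param xyz ligand coordinates.
#' @export
pot_e_total <- function(potential, xyz) {
  potential$e_receptor + pot_e_coupling(potential, xyz) +
    pot_e_ligand(potential, xyz)
}

#' Plain MM single-point energy of the whole complex
#'
#' Independent of the term decomposition: evaluates one combined system
#' (ligand intramolecular + all cross pairs + receptor internal) in a single
#' pass, for verifying that the mechanical-embedding partition is exact.
#' @param potential a `gk_potential`.
#' @param xyz ligand coordinates.
#' @export
pot_e_complex_mm <- function(potential, xyz) {
  sys <- potential$intra
  sys$ext <- potential$ext
  sys$restr <- NULL
  ff_eval(xyz, sys, want_grad = FALSE)$E + potential$e_receptor
}

# combined minimisation system for a potential (+ optional core restraints)
.pot_system <- function(potential, core_restraints) {
  sys <- potential$intra
  sys$ext <- potential$ext
  if (core_restraints) {
    lig <- potential$ligand
    idx <- restrained_atoms(lig)
    if (length(idx) > 0) {
      tco <- mol_coords(lig$template$mol)
      ti <- as.integer(names(lig$core_map))[match(idx, lig$core_map)]
      sys$restr <- list(idx = idx, ref = tco[ti, , drop = FALSE],
                        k = rep(1e4, length(idx)))
    }
  }
  sys
}

#' Minimise conformers in the rigid pocket
#'
#' Each conformer that passed the clash filter is locally minimised with the
#' receptor fixed; when `core_restraints` is TRUE (default) stiff harmonic
#' restraints (1e4 kcal/mol/A^2) hold the restrained core heavy atoms at the
#' template position. Final energies are the unrestrained `E_tot` at the
#' minimised geometry. Conformers with non-finite energies are dropped.
#'
#' @param ensemble a `gk_ensemble` after [clash_filter()].
#' @param potential a `gk_potential`.
#' @param core_restraints keep the core at the template coordinates.
#' @param maxit optimiser iteration cap.
#' @return the refined ensemble (energies now `E_tot`).
#' @export
minimise_in_pocket <- function(ensemble, potential, core_restraints = TRUE,
                               maxit = 2000) {
  stopifnot(inherits(ensemble, "gk_ensemble"), inherits(potential, "gk_potential"))
  sys <- .pot_system(potential, core_restraints)
  custom_ml <- potential$backend == "ml" && !is.null(potential$ml_energy)
  drop <- integer(0)
  for (k in seq_along(ensemble$coords)) {
    if (ensemble$flags$clash_rejected[k]) next
    x0 <- ensemble$coords[[k]]
    e_before <- pot_e_total(potential, x0)
    if (custom_ml) {
      # pluggable ligand term: optimise numerically on top of the MM coupling
      n <- nrow(x0)
      aux <- sys; aux$bonds <- NULL; aux$angles <- NULL; aux$tors <- NULL
      aux$nb <- NULL
      fn <- function(p) {
        m <- matrix(p, n, 3)
        potential$ml_energy(m) + ff_eval(m, aux, want_grad = FALSE)$E
      }
      res <- stats::optim(as.vector(x0), fn, method = "L-BFGS-B",
                          control = list(maxit = maxit))
      xmin <- matrix(res$par, n, 3)
    } else {
      xmin <- ff_minimise_restrained(x0, sys, maxit = maxit)$xyz
    }
    e_after <- pot_e_total(potential, xmin)
    if (!is.finite(e_after)) {
      message("dropping conformer ", k, ": non-finite energy after refinement")
      drop <- c(drop, k)
      next
    }
    if (e_after > e_before) {
      xmin <- x0; e_after <- e_before
    }
    ensemble$coords[[k]] <- xmin
    ensemble$energy[k] <- e_after
    ensemble$flags$pocket_minimised[k] <- TRUE
  }
  if (length(drop) > 0) {
    keep <- setdiff(seq_along(ensemble$coords), drop)
    ensemble$coords <- ensemble$coords[keep]
    ensemble$energy <- ensemble$energy[keep]
    ensemble$flags <- ensemble$flags[keep, , drop = FALSE]
    rownames(ensemble$flags) <- NULL
  }
  ensemble
}

#' Select the low-energy conformers within an energy window
#'
#' The lowest-energy refined conformer and every conformer within `window`
#' kcal/mol of it (boundary inclusive) are flagged `selected`. The returned
#' ensemble carries a `selection` attribute with the selected indices sorted
#' by ascending energy (ties by conformer index).
#'
#' @param ensemble a `gk_ensemble` with energies set.
#' @param window energy window in kcal/mol (default 5.0).
#' @return the ensemble with selection flags.
#' @export
select_low_energy <- function(ensemble, window = 5.0) {
  stopifnot(inherits(ensemble, "gk_ensemble"))
  elig <- which(!ensemble$flags$clash_rejected & is.finite(ensemble$energy))
  if (length(elig) == 0) stop("no conformer energies set")
  emin <- min(ensemble$energy[elig])
  sel <- elig[ensemble$energy[elig] - emin <= window]
  ensemble$flags$selected <- seq_along(ensemble$coords) %in% sel
  ord <- sel[order(ensemble$energy[sel], sel)]
  attr(ensemble, "selection") <- ord
  ensemble
}

#' R-group heavy-atom RMSD between two poses of the same molecule
#'
#' No superposition is applied: the shared core already places both poses in
#' a common frame. With `symmetry = TRUE` the RMSD is minimised over the
#' topological automorphisms of the molecule that fix all non-R-group atoms
#' (e.g. the two-fold flip of a para-substituted phenyl).
#'
#' @param pose_a,pose_b n x 3 coordinate matrices with identical atom order.
#' @param rgroup_atoms indices of the grown atoms.
#' @param symmetry minimise over symmetry-equivalent permutations.
#' @param mol the `gk_mol` (required when `symmetry = TRUE`, and used to
#'   restrict to heavy atoms).
#' @return RMSD in Angstrom.
#' @export
rgroup_rmsd <- function(pose_a, pose_b, rgroup_atoms, symmetry = FALSE,
                        mol = NULL) {
  if (length(rgroup_atoms) == 0) stop("rgroup_atoms must not be empty")
  sub <- rgroup_atoms
  if (!is.null(mol)) {
    heavy <- sub[mol$atoms$elem[sub] != "H"]
    if (length(heavy) > 0) sub <- heavy
  }
  plain <- function(perm) {
    d <- pose_a[sub, , drop = FALSE] - pose_b[perm, , drop = FALSE]
    sqrt(mean(rowSums(d * d)))
  }
  best <- plain(sub)
  if (symmetry) {
    if (is.null(mol)) stop("symmetry = TRUE requires the molecule graph")
    for (perm in mol_automorphisms(mol, fixed = setdiff(seq_len(mol_natoms(mol)),
                                                        rgroup_atoms))) {
      best <- min(best, plain(perm[sub]))
    }
  }
  best
}

#' Topological automorphisms of a molecule (element- and bond-class-aware)
#'
#' @param mol a `gk_mol`.
#' @param fixed atom indices every returned permutation must map to itself.
#' @return list of permutation vectors (image of atom i at position i).
#' @keywords internal
mol_automorphisms <- function(mol, fixed = integer(0)) {
  g <- mol_graph(mol)
  col <- as.integer(factor(mol$atoms$elem))
  # pin fixed atoms with unique colours so VF2 cannot move them
  if (length(fixed) > 0) col[fixed] <- max(col) + seq_along(fixed)
  ecol <- as.integer(factor(mol_bond_class(mol)))
  maps <- igraph::subgraph_isomorphisms(g, g, method = "vf2",
                                        vertex.color1 = col,
                                        vertex.color2 = col,
                                        edge.color1 = ecol,
                                        edge.color2 = ecol)
  lapply(maps, as.integer)
}

#' Signed dihedral angle of four atoms, in degrees
#'
#' IUPAC sign convention, result in (-180, 180].
#'
#' @param pose n x 3 coordinate matrix.
#' @param atoms four distinct atom indices.
#' @return angle in degrees.
#' @export
dihedral <- function(pose, atoms) {
  if (length(unique(atoms)) != 4) stop("need 4 distinct atom indices")
  x <- pose[atoms, , drop = FALSE]
  b1 <- x[2, ] - x[1, ]; b2 <- x[3, ] - x[2, ]; b3 <- x[4, ] - x[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    stop("dihedral undefined: collinear atoms")
  }
  b2n <- b2 / sqrt(sum(b2^2))
  m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(m * b2n), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
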