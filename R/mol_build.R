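# Core/R-group definition, merging, and core-constrained conformer
# enumeration with restrained vacuum minimisation.

#' Load a ligand core with a marked attachment hydrogen
#'
#' The core supplies the fixed binding-mode coordinates; growth is only
#' supported from a hydrogen atom, which the merge replaces.
#'
#' @param structure_file SDF, MOL or PDB file with 3D coordinates.
#' @param attachment_h 1-based index of the hydrogen to replace.
#' @return a `gk_template` object.
#' @export
#' @examples
#' core <- load_core(growkit_example("core_benzene.sdf"), attachment_h = 7)
load_core <- function(structure_file, attachment_h) {
  mol <- mol_read_file(structure_file)
  if (identical(attr(mol, "dim_flag"), "2D") ||
      (mol_natoms(mol) > 3 && all(mol$atoms$z == 0) && all(mol$atoms$y == 0))) {
    stop("core structure must have 3D coordinates; got a flat/2D record")
  }
  attachment_h <- as.integer(attachment_h)
  if (length(attachment_h) != 1 || is.na(attachment_h) ||
      attachment_h < 1 || attachment_h > mol_natoms(mol)) {
    stop("attachment index out of range (1..", mol_natoms(mol), ")")
  }
  if (mol$atoms$elem[attachment_h] != "H") {
    stop("attachment atom must be hydrogen: growth only from hydrogen is supported")
  }
  if (length(mol_neighbors(mol, attachment_h)) != 1) {
    stop("attachment hydrogen must have exactly one bond")
  }
  structure(list(mol = mol, attachment_h = attachment_h,
                 flexible_atoms = integer(0)),
            class = "gk_template")
}

#' @export
print.gk_template <- function(x, ...) {
  cat(sprintf("<gk_template> %s: %d atoms, attachment H at %d, %d flexible\n",
              x$mol$name, mol_natoms(x$mol), x$attachment_h,
              length(x$flexible_atoms)))
  invisible(x)
}

#' Define an R-group fragment
#'
#' @param mol a `gk_mol` (explicit hydrogens).
#' @param attachment_atom heavy-atom index that bonds to the core; must carry
#'   at least one hydrogen (or an explicit dummy) to consume.
#' @param label short name.
#' @return a `gk_rgroup`.
#' @export
rgroup <- function(mol, attachment_atom = 1L, label = mol$name) {
  attachment_atom <- as.integer(attachment_atom)
  if (attachment_atom < 1 || attachment_atom > mol_natoms(mol)) {
    stop("attachment_atom out of range")
  }
  if (!mol_is_connected(mol)) stop("R-group must be a single connected fragment")
  nb <- mol_neighbors(mol, attachment_atom)
  cons <- nb[mol$atoms$elem[nb] %in% c("H", "*")]
  if (length(cons) == 0 && mol_natoms(mol) > 1) {
    stop("attachment atom has no hydrogen (or attachment-vector dummy) to consume")
  }
  structure(list(mol = mol, attachment_atom = attachment_atom, label = label),
            class = "gk_rgroup")
}

#' R-group from SMILES
#'
#' The attachment atom is the first heavy atom of the SMILES; a leading
#' `[*]` dummy (with optional bond symbol) marks it explicitly and is
#' stripped before 3D generation.
#' @param smiles SMILES string.
#' @param label short name (defaults to the SMILES).
#' @export
rgroup_from_smiles <- function(smiles, label = smiles) {
  smi <- sub("^\\[\\*\\]([-=#]?)", "", smiles)
  mol <- mol_from_smiles(smi, name = label)
  rgroup(mol, attachment_atom = 1L, label = label)
}

#' R-group from an SDF file
#' @param path SDF/MOL file.
#' @param attachment_atom index of the linking atom (default 1).
#' @param label short name (defaults to the record title or filename).
#' @export
rgroup_from_sdf <- function(path, attachment_atom = 1L, label = NULL) {
  mol <- mol_read_file(path)
  if (is.null(label)) {
    label <- if (nzchar(mol$name)) mol$name else
      tools::file_path_sans_ext(basename(path))
  }
  rgroup(mol, attachment_atom = attachment_atom, label = label)
}

# rotation matrix taking unit vector a onto unit vector b
.rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

.gk_valence_ok <- function(mol, idx) {
  deg <- sum(mol$bonds$order[mol$bonds$i == idx | mol$bonds$j == idx])
  vmax <- .gk_elem_prop(mol$atoms$elem[idx], "valence") + mol$atoms$fcharge[idx] *
    (if (mol$atoms$elem[idx] %in% c("N", "O")) 1 else 0)
  deg <= vmax
}

#' Attach an R-group to a core template
#'
#' Deletes the template's attachment hydrogen and one hydrogen (or dummy) on
#' the R-group's linking atom, forms the new single bond, and places the
#' R-group along the former C-H vector at the covalent-radius distance. Core
#' coordinates are copied unchanged.
#'
#' @param template a `gk_template`.
#' @param rg a `gk_rgroup`.
#' @return a `gk_ligand` (grown ligand) with `core_map`, `rgroup_atoms`, and
#'   an empty conformer ensemble.
#' @export
attach_rgroup <- function(template, rg) {
  stopifnot(inherits(template, "gk_template"), inherits(rg, "gk_rgroup"))
  tmol <- template$mol
  rmol <- rg$mol
  h <- template$attachment_h
  x_idx <- mol_neighbors(tmol, h)[1]
  a_idx <- rg$attachment_atom

  # hydrogen/dummy to consume on the R-group side (dummy preferred)
  nb <- mol_neighbors(rmol, a_idx)
  dummy <- nb[rmol$atoms$elem[nb] == "*"]
  hr <- if (length(dummy) > 0) dummy[1] else {
    hs <- nb[rmol$atoms$elem[nb] == "H"]
    if (length(hs) == 0) {
      stop("valence error: R-group attachment atom has no hydrogen to consume")
    }
    hs[1]
  }

  tco <- mol_coords(tmol); rco <- mol_coords(rmol)
  u <- tco[h, ] - tco[x_idx, ]; u <- u / sqrt(sum(u^2))
  v <- rco[hr, ] - rco[a_idx, ]; v <- v / sqrt(sum(v^2))
  d <- .gk_elem_prop(tmol$atoms$elem[x_idx], "rcov") +
    .gk_elem_prop(rmol$atoms$elem[a_idx], "rcov")
  rot <- .rot_between(v, -u)
  shifted <- sweep(rco, 2, rco[a_idx, ])
  placed <- t(rot %*% t(shifted)) + matrix(tco[x_idx, ] + d * u,
                                           nrow(rco), 3, byrow = TRUE)

  keep_t <- setdiff(seq_len(mol_natoms(tmol)), h)
  keep_r <- setdiff(seq_len(mol_natoms(rmol)), hr)
  tmap <- integer(mol_natoms(tmol)); tmap[keep_t] <- seq_along(keep_t)
  rmap <- integer(mol_natoms(rmol)); rmap[keep_r] <- length(keep_t) + seq_along(keep_r)

  atoms <- rbind(
    data.frame(elem = tmol$atoms$elem[keep_t], fcharge = tmol$atoms$fcharge[keep_t],
               x = tco[keep_t, 1], y = tco[keep_t, 2], z = tco[keep_t, 3],
               pcharge = NA_real_),
    data.frame(elem = rmol$atoms$elem[keep_r], fcharge = rmol$atoms$fcharge[keep_r],
               x = placed[keep_r, 1], y = placed[keep_r, 2], z = placed[keep_r, 3],
               pcharge = NA_real_))
  tb <- tmol$bonds[tmol$bonds$i != h & tmol$bonds$j != h, , drop = FALSE]
  rb <- rmol$bonds[rmol$bonds$i != hr & rmol$bonds$j != hr, , drop = FALSE]
  bonds <- rbind(
    data.frame(i = tmap[tb$i], j = tmap[tb$j], order = tb$order),
    data.frame(i = rmap[rb$i], j = rmap[rb$j], order = rb$order),
    data.frame(i = tmap[x_idx], j = rmap[a_idx], order = 1L))

  name <- paste0(if (nzchar(tmol$name)) tmol$name else "core", "_", rg$label)
  mol <- gk_mol(atoms, bonds, name = name)
  if (!mol_is_connected(mol)) stop("merge produced a disconnected molecule")
  if (!.gk_valence_ok(mol, tmap[x_idx]) || !.gk_valence_ok(mol, rmap[a_idx])) {
    stop("valence violation at the new bond")
  }

  core_map <- tmap[keep_t]
  names(core_map) <- keep_t
  structure(list(
    mol = mol,
    core_map = core_map,                      # template idx (names) -> merged idx
    rgroup_atoms = rmap[keep_r],
    template = template,
    flexible_core = unname(core_map[as.character(
      intersect(template$flexible_atoms, keep_t))]),
    ensemble = NULL,
    meta = list(label = rg$label,
                provenance = sprintf("attach(%s + %s)", tmol$name, rg$label))
  ), class = "gk_ligand")
}

#' @export
print.gk_ligand <- function(x, ...) {
  cat(sprintf("<gk_ligand> %s (%s): %d atoms, %d grown, ensemble: %s\n",
              x$mol$name, mol_formula(x$mol), mol_natoms(x$mol),
              length(x$rgroup_atoms),
              if (is.null(x$ensemble)) "none" else
                paste0(length(x$ensemble$coords), " conformers")))
  invisible(x)
}

#' Move core atoms into the flexible (unrestrained) region
#'
#' @param ligand a `gk_ligand`.
#' @param atom_ids merged-molecule indices that must belong to the core.
#' @return the ligand with an enlarged flexible set.
#' @export
extend_flexible <- function(ligand, atom_ids) {
  atom_ids <- as.integer(atom_ids)
  if (length(atom_ids) == 0) return(ligand)
  if (any(atom_ids %in% ligand$rgroup_atoms)) {
    stop("atom(s) belong to the grown R-group and are already flexible")
  }
  if (!all(atom_ids %in% ligand$core_map)) {
    stop("atom(s) not part of the core: ",
         paste(setdiff(atom_ids, ligand$core_map), collapse = ", "))
  }
  ligand$flexible_core <- sort(unique(c(ligand$flexible_core, atom_ids)))
  ligand
}

#' Indices of restrained core heavy atoms (merged numbering)
#' @keywords internal
restrained_atoms <- function(ligand) {
  core <- unname(ligand$core_map)
  core <- core[ligand$mol$atoms$elem[core] != "H"]
  setdiff(core, ligand$flexible_core)
}

#' Embedding/minimisation configuration
#'
#' @param n_conformers number of torsion-sampled starting geometries.
#' @param seed RNG seed for torsion sampling.
#' @param restraint_k harmonic restraint force constant, kcal/mol/A^2.
#' @param dedup_rmsd near-duplicate threshold on R-group heavy-atom RMSD (A).
#' @export
embed_config <- function(n_conformers = 20L, seed = 42L,
                         restraint_k = 1e4, dedup_rmsd = 0.5) {
  n_conformers <- as.integer(n_conformers)
  if (is.na(n_conformers) || n_conformers < 1) {
    stop("n_conformers must be a positive integer")
  }
  if (restraint_k <= 0) stop("restraint_k must be > 0")
  structure(list(n_conformers = n_conformers, seed = as.integer(seed),
                 restraint_k = restraint_k, dedup_rmsd = dedup_rmsd),
            class = "gk_embed_config")
}

# empty conformer ensemble
.new_ensemble <- function() {
  structure(list(coords = list(), energy = numeric(0),
                 flags = data.frame(embedded = logical(0),
                                    vacuum_minimised = logical(0),
                                    clash_rejected = logical(0),
                                    pocket_minimised = logical(0),
                                    selected = logical(0))),
            class = "gk_ensemble")
}

ensemble_add <- function(ens, coords, energy = NA_real_,
                         flags = c(embedded = TRUE)) {
  ens$coords[[length(ens$coords) + 1]] <- coords
  ens$energy <- c(ens$energy, energy)
  row <- data.frame(embedded = FALSE, vacuum_minimised = FALSE,
                    clash_rejected = FALSE, pocket_minimised = FALSE,
                    selected = FALSE)
  row[names(flags)] <- as.logical(flags)
  ens$flags <- rbind(ens$flags, row)
  ens
}

#' @export
print.gk_ensemble <- function(x, ...) {
  cat(sprintf(
    "<gk_ensemble> %d conformers (%d clash-rejected, %d selected)\n",
    length(x$coords), sum(x$flags$clash_rejected), sum(x$flags$selected)))
  invisible(x)
}

#' Rotatable bonds whose rotation moves only flexible/grown atoms
#' @return list of list(axis = c(a, b), moving = atom indices)
#' @keywords internal
.gk_rotors <- function(ligand) {
  mol <- ligand$mol
  n <- mol_natoms(mol)
  restrained <- restrained_atoms(ligand)
  ring <- mol_rings(mol)$bond
  deg <- mol_degree(mol)
  g <- mol_graph(mol)
  rotors <- list()
  for (b in seq_len(nrow(mol$bonds))) {
    if (ring[b] || mol$bonds$order[b] != 1) next
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    if (deg[i] < 2 || deg[j] < 2) next
    g2 <- igraph::delete_edges(g, b)
    comp <- igraph::components(g2)$membership
    side_j <- which(comp == comp[j])
    side_i <- which(comp == comp[i])
    if (!any(side_j %in% restrained)) {
      rotors[[length(rotors) + 1]] <- list(axis = c(i, j),
                                           moving = setdiff(side_j, j))
    } else if (!any(side_i %in% restrained)) {
      rotors[[length(rotors) + 1]] <- list(axis = c(j, i),
                                           moving = setdiff(side_i, i))
    }
  }
  rotors
}

.rotate_about_axis <- function(coords, p0, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(t(R %*% t(sweep(coords, 2, p0))), 2, -p0)
}

#' Enumerate core-constrained conformers
#'
#' Starting geometries are produced by seeded uniform sampling of the
#' torsions of rotatable bonds in the flexible region (the first conformer
#' keeps the build geometry). Each is minimised in vacuum under the compact
#' force field with harmonic positional restraints (force constant
#' `cfg$restraint_k`) holding the restrained core heavy atoms at the template
#' coordinates; near-duplicates are then removed by R-group heavy-atom RMSD.
#'
#' @param ligand a `gk_ligand`.
#' @param cfg an [embed_config()].
#' @return the ligand with a populated `ensemble`.
#' @export
enumerate_conformers <- function(ligand, cfg = embed_config()) {
  stopifnot(inherits(ligand, "gk_ligand"))
  if (!inherits(cfg, "gk_embed_config")) stop("cfg must be an embed_config()")
  mol <- ligand$mol
  if (anyNA(mol$atoms$pcharge)) mol <- mol_assign_charges(mol)
  ligand$mol <- mol

  rotors <- .gk_rotors(ligand)
  base <- mol_coords(mol)

  # seeded torsion sampling with the caller's RNG state preserved
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  starts <- list(base)
  if (length(rotors) > 0 && cfg$n_conformers > 1) {
    for (k in seq_len(cfg$n_conformers - 1)) {
      co <- base
      for (rt in rotors) {
        ang <- stats::runif(1, -pi, pi)
        ax <- co[rt$axis[2], ] - co[rt$axis[1], ]
        co[rt$moving, ] <- .rotate_about_axis(co[rt$moving, , drop = FALSE],
                                              co[rt$axis[2], ], ax, ang)
      }
      starts[[k + 1]] <- co
    }
  } else if (cfg$n_conformers > 1) {
    starts <- rep(starts, cfg$n_conformers)
  }

  restr_idx <- restrained_atoms(ligand)
  tco <- mol_coords(ligand$template$mol)
  tmpl_idx <- as.integer(names(ligand$core_map))[match(restr_idx, ligand$core_map)]
  sys <- ff_intra_terms(mol, ref_coords = base)
  if (length(restr_idx) > 0) {
    sys$restr <- list(idx = restr_idx, ref = tco[tmpl_idx, , drop = FALSE],
                      k = rep(cfg$restraint_k, length(restr_idx)))
  }

  ens <- .new_ensemble()
  for (co in starts) {
    res <- ff_minimise_restrained(co, sys)
    if (!is.finite(res$E)) next
    ens <- ensemble_add(ens, res$xyz, energy = res$E,
                        flags = c(embedded = TRUE, vacuum_minimised = TRUE))
  }
  if (length(ens$coords) == 0) {
    stop("conformer embedding failed for all attempts (",
         length(starts), " starts)")
  }
  ligand$ensemble <- ensemble_dedup(ens, ligand, cfg$dedup_rmsd)
  ligand
}

#' Remove near-duplicate conformers (greedy, lowest energy kept first)
#' @keywords internal
ensemble_dedup <- function(ens, ligand, dedup_rmsd = 0.5) {
  m <- length(ens$coords)
  if (m <= 1) return(ens)
  rg <- ligand$rgroup_atoms
  heavy <- rg[ligand$mol$atoms$elem[rg] != "H"]
  if (length(heavy) == 0) heavy <- rg
  ord <- order(ens$energy, seq_len(m))
  keep <- integer(0)
  for (k in ord) {
    dup <- any(vapply(keep, function(p) {
      d <- ens$coords[[k]][heavy, , drop = FALSE] -
        ens$coords[[p]][heavy, , drop = FALSE]
      sqrt(mean(rowSums(d * d))) < dedup_rmsd
    }, logical(1)))
    if (!dup) keep <- c(keep, k)
  }
  keep <- sort(keep)
  ens$coords <- ens$coords[keep]
  ens$energy <- ens$energy[keep]
  ens$flags <- ens$flags[keep, , drop = FALSE]
  rownames(ens$flags) <- NULL
  ens
}

# ---- maximum common substructure -------------------------------------------

#' Maximum common substructure map between two molecules (heavy atoms)
#'
#' Induced connected MCS found as a maximum clique of the modular product
#' graph. Atoms match on element; bonds match on compatibility class (order,
#' with aromatic ring bonds pooled) and ring bonds only map to ring bonds.
#' Ties are broken deterministically by the lowest sum of atom indices.
#'
#' @param mol_a,mol_b `gk_mol` objects.
#' @param min_size minimum acceptable common-substructure size; below it a
#'   core-mismatch error is raised (default: half of mol_a's heavy atoms).
#' @return two-column matrix (`a`, `b`) of matched heavy-atom indices.
#' @export
mcs_map <- function(mol_a, mol_b, min_size = NULL) {
  ha <- mol_heavy(mol_a); hb <- mol_heavy(mol_b)
  if (is.null(min_size)) min_size <- ceiling(length(ha) / 2)
  bond_key <- function(mol, heavy) {
    cls <- mol_bond_class(mol)
    ring <- mol_rings(mol)$bond
    keep <- mol$bonds$i %in% heavy & mol$bonds$j %in% heavy
    k <- paste(pmin(mol$bonds$i, mol$bonds$j)[keep],
               pmax(mol$bonds$i, mol$bonds$j)[keep])
    stats::setNames(paste(cls[keep], ring[keep]), k)
  }
  ba <- bond_key(mol_a, ha); bb <- bond_key(mol_b, hb)
  ring_a <- mol_rings(mol_a)$atom; ring_b <- mol_rings(mol_b)$atom

  pairs <- expand.grid(a = ha, b = hb)
  pairs <- pairs[mol_a$atoms$elem[pairs$a] == mol_b$atoms$elem[pairs$b] &
                   ring_a[pairs$a] == ring_b[pairs$b], , drop = FALSE]
  np <- nrow(pairs)
  if (np == 0) stop("core mismatch: no common substructure")

  edges <- integer(0)
  for (p in seq_len(np - 1)) {
    a1 <- pairs$a[p]; b1 <- pairs$b[p]
    q <- (p + 1):np
    a2 <- pairs$a[q]; b2 <- pairs$b[q]
    ka <- paste(pmin(a1, a2), pmax(a1, a2))
    kb <- paste(pmin(b1, b2), pmax(b1, b2))
    ea <- ba[ka]; eb <- bb[kb]
    ok <- (a2 != a1) & (b2 != b1) &
      ((!is.na(ea) & !is.na(eb) & ea == eb) | (is.na(ea) & is.na(eb)))
    if (any(ok)) edges <- c(edges, rbind(p, q[ok]))
  }
  gp <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (length(edges) > 0) gp <- igraph::add_edges(gp, edges)

  cl <- igraph::largest_cliques(gp)
  # prefer cliques whose mapped-subgraph (on mol_a) is connected
  is_conn <- vapply(cl, function(v) {
    av <- pairs$a[as.integer(v)]
    sub <- igraph::induced_subgraph(mol_graph(mol_a), av)
    igraph::is_connected(sub)
  }, logical(1))
  if (any(is_conn)) cl <- cl[is_conn]
  # deterministic tie-break: lowest index sum, then lexicographically
  # smallest b-sequence (ordered by a) so identity-like maps win among
  # symmetry-equivalent alternatives
  keys <- vapply(cl, function(v) {
    v <- as.integer(v)
    m <- cbind(pairs$a[v], pairs$b[v])
    m <- m[order(m[, 1]), , drop = FALSE]
    paste(sprintf("%06d", c(sum(m), m[, 2])), collapse = " ")
  }, character(1))
  best <- as.integer(cl[[order(keys)[1]]])
  if (length(best) < min_size) {
    stop("core mismatch: common substructure has only ", length(best),
         " atoms (need >= ", min_size, ")")
  }
  map <- cbind(a = pairs$a[best], b = pairs$b[best])
  map[order(map[, 1]), , drop = FALSE]
}

#' Map template heavy atoms into a grown ligand by MCS
#'
#' @param ligand a `gk_ligand` (or bare `gk_mol`).
#' @param template a `gk_template` (or bare `gk_mol`).
#' @return named integer vector: template heavy-atom index -> ligand index.
#' @export
core_map <- function(ligand, template) {
  la <- if (inherits(ligand, "gk_ligand")) ligand$mol else ligand
  tm <- if (inherits(template, "gk_template")) template$mol else template
  m <- mcs_map(tm, la)
  stats::setNames(m[, "b"], m[, "a"])
}
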