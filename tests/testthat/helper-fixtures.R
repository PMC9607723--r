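# Shared fixtures, memoised so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

fx_core <- function() {
  if (is.null(.fx$core)) {
    .fx$core <- load_core(growkit_example("core_benzene.sdf"), attachment_h = 7)
  }
  .fx$core
}

fx_library <- function() {
  if (is.null(.fx$lib)) .fx$lib <- toy_rgroup_library()
  .fx$lib
}

fx_pocket <- function() {
  if (is.null(.fx$pocket)) .fx$pocket <- make_toy_pocket(seed = 1)
  .fx$pocket
}

# a small refined ligand (benzene + propoxy in the toy pocket)
fx_refined <- function() {
  if (is.null(.fx$refined)) {
    lig <- attach_rgroup(fx_core(), fx_library()$propoxy)
    lig <- enumerate_conformers(lig, embed_config(n_conformers = 5, seed = 7))
    rec <- fx_pocket()$receptor
    pot <- build_hybrid_potential(lig, rec)
    ens <- clash_filter(lig$ensemble, rec)
    ens <- minimise_in_pocket(ens, pot)
    lig$ensemble <- select_low_energy(ens)
    .fx$refined <- list(ligand = lig, receptor = rec, potential = pot)
  }
  .fx$refined
}

# bare one-atom "ligand" with explicit nonbonded identity, for analytic
# potential checks (bypasses file parsing, which needs >= 2 atoms)
fx_point_ligand <- function(elem = "O", xyz = c(0, 0, 0), pcharge = 0) {
  atoms <- data.frame(elem = elem, fcharge = 0L,
                      x = xyz[1], y = xyz[2], z = xyz[3], pcharge = pcharge)
  mol <- growkit:::gk_mol(atoms, data.frame(i = integer(), j = integer(),
                                            order = integer()),
                          name = "point")
  ens <- growkit:::.new_ensemble()
  ens <- growkit:::ensemble_add(ens, matrix(xyz, 1, 3))
  structure(list(mol = mol, core_map = integer(0), rgroup_atoms = 1L,
                 template = NULL, flexible_core = integer(0),
                 ensemble = ens, meta = list()),
            class = "gk_ligand")
}

# brute-force maximum common connected substructure size: exhaustively
# enumerates every connected heavy-atom subset of mol_a and checks by
# backtracking whether it embeds in mol_b as an induced, label-preserving
# subgraph. Independent of mcs_map's clique formulation; for <= 12 heavy
# atoms only.
oracle_mcs_size <- function(mol_a, mol_b) {
  ha <- growkit:::mol_heavy(mol_a)
  hb <- growkit:::mol_heavy(mol_b)
  bond_lookup <- function(mol) {
    cls <- growkit:::mol_bond_class(mol)
    keys <- paste(pmin(mol$bonds$i, mol$bonds$j),
                  pmax(mol$bonds$i, mol$bonds$j))
    stats::setNames(cls, keys)
  }
  ba <- bond_lookup(mol_a); bb <- bond_lookup(mol_b)
  ring_a <- growkit:::mol_rings(mol_a)$atom
  ring_b <- growkit:::mol_rings(mol_b)$atom
  edge <- function(tab, i, j) unname(tab[paste(min(i, j), max(i, j))])
  nb_a <- lapply(seq_len(nrow(mol_a$atoms)), function(v) {
    intersect(growkit:::mol_neighbors(mol_a, v), ha)
  })

  embeds <- function(sub) {
    assign_next <- function(map, used) {
      k <- length(map) + 1
      if (k > length(sub)) return(TRUE)
      a <- sub[k]
      for (b in setdiff(hb, used)) {
        if (mol_a$atoms$elem[a] != mol_b$atoms$elem[b]) next
        if (ring_a[a] != ring_b[b]) next
        ok <- TRUE
        for (p in seq_len(k - 1)) {
          ea <- edge(ba, a, sub[p]); eb <- edge(bb, b, map[p])
          if (!identical(is.na(ea), is.na(eb)) ||
              (!is.na(ea) && !identical(ea, eb))) { ok <- FALSE; break }
        }
        if (ok && assign_next(c(map, b), c(used, b))) return(TRUE)
      }
      FALSE
    }
    assign_next(integer(0), integer(0))
  }

  best <- 0L
  # Uno-style connected-subset enumeration: subsets whose minimum vertex is v
  rec <- function(sub, ext, forb) {
    if (length(sub) > best && embeds(sub)) best <<- length(sub)
    while (length(ext) > 0) {
      u <- ext[1]; ext <- ext[-1]
      grow <- setdiff(nb_a[[u]], c(sub, forb, ext, u))
      rec(c(sub, u), c(ext, grow), forb)
      forb <- c(forb, u)
    }
  }
  for (v in ha) {
    forb <- ha[ha < v]
    rec(v, setdiff(nb_a[[v]], forb), forb)
  }
  best
}
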