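# Internal small-molecule container. Atoms are explicit (hydrogens included),
# indices 1-based. Parsing of SDF/MOL goes through ChemmineR; SMILES and PDB
# ligands go through Open Babel (ChemmineOB). Writing uses the package's own
# V2000 emitter so that output is byte-stable across reruns.

#' Construct a molecule object
#'
#' @param atoms data.frame with columns `elem`, `fcharge`, `x`, `y`, `z` and
#'   optionally `pcharge` (partial charge, e).
#' @param bonds data.frame with columns `i`, `j`, `order`.
#' @param name molecule title.
#' @return an object of class `gk_mol`.
#' @keywords internal
gk_mol <- function(atoms, bonds, name = "") {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (is.null(atoms$pcharge)) atoms$pcharge <- NA_real_
  if (is.null(atoms$fcharge)) atoms$fcharge <- 0L
  atoms <- atoms[, c("elem", "fcharge", "x", "y", "z", "pcharge")]
  if (nrow(bonds) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- bonds[, c("i", "j", "order")]
  }
  co <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && any(!is.finite(co))) {
    stop("all atoms must have finite 3D coordinates")
  }
  structure(list(atoms = atoms, bonds = bonds, name = name), class = "gk_mol")
}

#' @export
print.gk_mol <- function(x, ...) {
  cat(sprintf("<gk_mol> %s: %d atoms (%d heavy), %d bonds\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), sum(x$atoms$elem != "H"), nrow(x$bonds)))
  invisible(x)
}

mol_natoms <- function(mol) nrow(mol$atoms)

mol_coords <- function(mol) unname(as.matrix(mol$atoms[, c("x", "y", "z")]))

`mol_coords<-` <- function(mol, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(mol$atoms), ncol(value) == 3)
  mol$atoms$x <- value[, 1]; mol$atoms$y <- value[, 2]; mol$atoms$z <- value[, 3]
  mol
}

mol_heavy <- function(mol) which(mol$atoms$elem != "H")

#' Molecular graph as an igraph object (vertices carry element labels)
#' @keywords internal
mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = mol_natoms(mol), directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  }
  igraph::set_vertex_attr(g, "elem", value = mol$atoms$elem)
}

mol_neighbors <- function(mol, i) {
  c(mol$bonds$j[mol$bonds$i == i], mol$bonds$i[mol$bonds$j == i])
}

mol_degree <- function(mol) {
  tabulate(c(mol$bonds$i, mol$bonds$j), nbins = mol_natoms(mol))
}

#' Ring membership flags for atoms and bonds (from the cycle space)
#' @return list(atom = logical, bond = logical)
#' @keywords internal
mol_rings <- function(mol) {
  n <- mol_natoms(mol)
  nb <- nrow(mol$bonds)
  if (nb == 0) return(list(atom = logical(n), bond = logical(0)))
  g <- mol_graph(mol)
  # a bond is in a ring iff removing it keeps its endpoints connected
  bond_ring <- vapply(seq_len(nb), function(k) {
    g2 <- igraph::delete_edges(g, k)
    igraph::distances(g2, v = mol$bonds$i[k], to = mol$bonds$j[k]) < Inf
  }, logical(1))
  atom_ring <- logical(n)
  atom_ring[unique(c(mol$bonds$i[bond_ring], mol$bonds$j[bond_ring]))] <- TRUE
  list(atom = atom_ring, bond = bond_ring)
}

#' Simple aromatic perception on the Kekule structure: 5/6-rings in which
#' every member atom carries at least one multiple bond.
#' @return logical per bond
#' @keywords internal
mol_aromatic_bonds <- function(mol) {
  rings <- mol_ring_list(mol)
  n <- mol_natoms(mol)
  has_multi <- logical(n)
  multi <- mol$bonds$order >= 2
  has_multi[unique(c(mol$bonds$i[multi], mol$bonds$j[multi]))] <- TRUE
  arom_bond <- logical(nrow(mol$bonds))
  for (ring in rings) {
    if (length(ring) %in% c(5L, 6L) && all(has_multi[ring])) {
      in_ring <- mol$bonds$i %in% ring & mol$bonds$j %in% ring
      arom_bond <- arom_bond | in_ring
    }
  }
  arom_bond
}

#' Smallest rings: for every ring bond, the shortest cycle through it
#' (computed as the shortest path between its endpoints with the bond removed).
#' @keywords internal
mol_ring_list <- function(mol) {
  if (nrow(mol$bonds) == 0) return(list())
  g <- mol_graph(mol)
  ring_bonds <- which(mol_rings(mol)$bond)
  seen <- character(0)
  rings <- list()
  for (k in ring_bonds) {
    g2 <- igraph::delete_edges(g, k)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = mol$bonds$i[k], to = mol$bonds$j[k]))$vpath[[1]]
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = ",")
    if (length(ring) >= 3 && !(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- ring
    }
  }
  rings
}

#' Bond compatibility class used for matching: aromatic ring bonds collapse to
#' one class so that Kekule alternation does not break symmetry detection.
#' @keywords internal
mol_bond_class <- function(mol) {
  cls <- as.character(mol$bonds$order)
  cls[mol_aromatic_bonds(mol)] <- "ar"
  cls
}

mol_elements <- function(mol) unique(mol$atoms$elem)

mol_formula <- function(mol) {
  tab <- table(mol$atoms$elem)
  ord <- c("C", "H", setdiff(sort(names(tab)), c("C", "H")))
  ord <- ord[ord %in% names(tab)]
  paste0(vapply(ord, function(e) {
    if (tab[[e]] == 1) e else paste0(e, tab[[e]])
  }, character(1)), collapse = "")
}

mol_mw <- function(mol) sum(.gk_elem_prop(mol$atoms$elem, "mass"))

mol_total_charge <- function(mol) sum(mol$atoms$fcharge)

mol_is_connected <- function(mol) {
  if (mol_natoms(mol) <= 1) return(TRUE)
  igraph::is_connected(mol_graph(mol))
}

# ---- parsing ---------------------------------------------------------------

# old-style ctab charge codes
.gk_ctab_charge <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
                     `6` = -2L, `7` = -3L)

#' Convert one ChemmineR SDF record into a gk_mol
#' @keywords internal
mol_from_chemmine <- function(sdf, name = NULL, raw_lines = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  if (!is.matrix(ab) || ncol(ab) < 3) {
    stop("unparseable SDF record (records need at least two atoms, ",
         "with explicit hydrogens)")
  }
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  fch <- integer(length(elem))
  if ("C5" %in% colnames(ab)) {
    code <- as.character(ab[, "C5"])
    hit <- code %in% names(.gk_ctab_charge)
    fch[hit] <- .gk_ctab_charge[code[hit]]
  }
  # M CHG records override the per-atom charge codes
  if (!is.null(raw_lines)) {
    for (ln in grep("^M  CHG", raw_lines, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1]
      pairs <- matrix(f[-1], ncol = 2, byrow = TRUE)[seq_len(k), , drop = FALSE]
      fch[] <- 0L
      fch[pairs[, 1]] <- pairs[, 2]
    }
  }
  atoms <- data.frame(elem = elem, fcharge = fch,
                      x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  hdr <- ChemmineR::header(sdf)
  nm <- if (!is.null(name)) name else unname(hdr[1])
  if (is.na(nm)) nm <- ""
  gk_mol(atoms, bonds, name = nm)
}

#' Read molecules from an SDF/MOL file
#'
#' @param path file path.
#' @return list of `gk_mol` (one per record).
#' @keywords internal
mol_read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  # split raw text per record to recover M CHG lines
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1, head(ends, -1) + 1)
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    raw <- if (k <= length(starts)) lines[starts[k]:ends[min(k, length(ends))]] else NULL
    out[[k]] <- mol_from_chemmine(sdfset[[k]], raw_lines = raw)
    attr(out[[k]], "dim_flag") <- if (length(raw) >= 2 && grepl("2D", raw[2])) "2D" else "3D"
  }
  out
}

#' Read a single molecule from SDF, MOL or PDB
#' @keywords internal
mol_read_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sdf", "mol")) {
    mol_read_sdf(path)[[1]]
  } else if (ext == "pdb") {
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    ChemmineOB::convertFormatFile("PDB", "SDF", path, tmp)
    mol_read_sdf(tmp)[[1]]
  } else {
    stop("unsupported structure format: .", ext, " (expected sdf/mol/pdb)")
  }
}

#' Build a molecule from SMILES via Open Babel 3D generation
#'
#' Coordinates come from Open Babel's stochastic 3D builder and are therefore
#' not reproducible call-to-call; bundled fixtures are shipped as frozen SDF
#' instead.
#' @keywords internal
mol_from_smiles <- function(smiles, name = "mol", gen3d = TRUE) {
  # gen3d adds hydrogens itself; without it they must be added explicitly
  opts <- if (gen3d) data.frame(names = "gen3d", args = "") else
    data.frame(names = "h", args = "")
  txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                   source = paste(smiles, name),
                                   options = opts)
  if (!nzchar(txt)) stop("SMILES could not be interpreted: ", smiles)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  m <- mol_read_sdf(tmp)[[1]]
  m$name <- name
  m
}

# ---- writing ---------------------------------------------------------------

#' Serialise a molecule (optionally with replacement coordinates and SD tags)
#' to V2000 SDF text lines.
#' @keywords internal
mol_to_sdf_lines <- function(mol, coords = NULL, tags = list(), name = NULL) {
  if (is.null(coords)) coords <- mol_coords(mol)
  na <- mol_natoms(mol); nb <- nrow(mol$bonds)
  out <- c(if (!is.null(name)) name else mol$name,
           "  growkit          3D", "")
  out <- c(out, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        coords[, 1], coords[, 2], coords[, 3], mol$atoms$elem))
  if (nb > 0) {
    out <- c(out, sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                          mol$bonds$order))
  }
  chg <- which(mol$atoms$fcharge != 0)
  if (length(chg) > 0) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp,
                                          mol$atoms$fcharge[grp]),
                                  collapse = "")))
    }
  }
  out <- c(out, "M  END")
  for (tag in names(tags)) {
    out <- c(out, sprintf(">  <%s>", tag), as.character(tags[[tag]]), "")
  }
  c(out, "$$$$")
}

#' Write one or more conformers of a molecule to an SDF file
#' @keywords internal
mol_write_sdf <- function(mol, file, coords_list = NULL, tags_list = NULL,
                          name = NULL) {
  if (is.null(coords_list)) coords_list <- list(mol_coords(mol))
  lines <- character(0)
  for (k in seq_along(coords_list)) {
    tg <- if (is.null(tags_list)) list() else tags_list[[k]]
    lines <- c(lines, mol_to_sdf_lines(mol, coords = coords_list[[k]],
                                       tags = tg, name = name))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Molecule as a one-record ChemmineR SDFset (for descriptor/SMARTS backends)
#' @keywords internal
mol_to_sdfset <- function(mol) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  mol_write_sdf(mol, tmp)
  suppressWarnings(ChemmineR::read.SDFset(tmp))
}

#' Assign Gasteiger partial charges (Open Babel backend)
#'
#' Charges are obtained by round-tripping through MOL2, whose writer runs
#' Open Babel's Gasteiger charge model; atom order is preserved.
#' @keywords internal
mol_assign_charges <- function(mol) {
  tin <- tempfile(fileext = ".sdf"); tout <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(tin, tout)))
  mol_write_sdf(mol, tin)
  ChemmineOB::convertFormatFile("SDF", "MOL2", tin, tout)
  lines <- readLines(tout, warn = FALSE)
  a0 <- grep("^@<TRIPOS>ATOM", lines)[1]
  a1 <- grep("^@<TRIPOS>BOND", lines)[1]
  rows <- lines[(a0 + 1):(a1 - 1)]
  rows <- rows[nzchar(trimws(rows))]
  q <- vapply(strsplit(trimws(rows), "\\s+"), function(f) {
    as.numeric(f[length(f)])
  }, numeric(1))
  if (length(q) != mol_natoms(mol)) {
    stop("charge assignment backend returned ", length(q), " atoms, expected ",
         mol_natoms(mol))
  }
  # redistribute any numerical drift so the total matches the formal charge
  q <- q + (mol_total_charge(mol) - sum(q)) / length(q)
  mol$atoms$pcharge <- q
  mol
}
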