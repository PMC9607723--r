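# Drug-likeness and liability reporting: Lipinski rule-of-five descriptors,
# an Ertl-style synthetic accessibility score backed by a bundled circular-
# fragment frequency snapshot, and SMARTS-catalog substructure flags.

#' Lipinski rule-of-five report
#'
#' MW is the average molecular weight; logP comes from the Open Babel
#' atom-contribution model; donors are counted as O-H and N-H bonds and
#' acceptors as N plus O atoms (Lipinski's original N/O counting). A
#' molecule is compliant with at most one violation of
#' {MW <= 500, logP <= 5, HBD <= 5, HBA <= 10}.
#'
#' @param mol a `gk_mol` or `gk_ligand`.
#' @return a one-row data.frame: mw, clogp, hbd, hba, ro5_violations,
#'   ro5_compliant.
#' @export
ro5_report <- function(mol) {
  if (inherits(mol, "gk_ligand")) mol <- mol$mol
  stopifnot(inherits(mol, "gk_mol"))
  if (mol_natoms(mol) == 0) stop("empty molecule")
  mw <- mol_mw(mol)
  props <- ChemmineR::propOB(mol_to_sdfset(mol))
  clogp <- as.numeric(props$logP[1])
  is_h <- mol$atoms$elem == "H"
  no <- mol$atoms$elem %in% c("N", "O")
  hbd <- sum((no[mol$bonds$i] & is_h[mol$bonds$j]) |
               (no[mol$bonds$j] & is_h[mol$bonds$i]))
  hba <- sum(no)
  .ro5_from_descriptors(mw, clogp, hbd, hba)
}

# threshold logic: MW <= 500, clogP <= 5, HBD <= 5, HBA <= 10; compliant
# means at most one violation
.ro5_from_descriptors <- function(mw, clogp, hbd, hba) {
  viol <- sum(c(mw > 500, clogp > 5, hbd > 5, hba > 10))
  data.frame(mw = mw, clogp = clogp, hbd = hbd, hba = hba,
             ro5_violations = viol, ro5_compliant = viol <= 1)
}

# ---- synthetic accessibility ----------------------------------------------

# stable string hash -> 16 hex chars (two independent polynomial hashes over
# a prime modulus; keeps every intermediate inside exact double range)
.fnv1a <- function(s) {
  p <- 2147483647
  vapply(s, function(x) {
    b <- utf8ToInt(x)
    h1 <- 17; h2 <- 1009
    for (v in b) {
      h1 <- (h1 * 31 + v) %% p
      h2 <- (h2 * 131 + v) %% p
    }
    sprintf("%08x%08x", h1, h2)
  }, character(1), USE.NAMES = FALSE)
}

#' Circular-fragment identifiers (radius 0..2) for every heavy atom
#' @return character matrix n_heavy x 3 (radius 0, 1, 2)
#' @keywords internal
sa_fragments <- function(mol) {
  heavy <- mol_heavy(mol)
  is_h <- mol$atoms$elem == "H"
  ring <- mol_rings(mol)$atom
  cls <- mol_bond_class(mol)
  nbrs <- lapply(seq_len(mol_natoms(mol)), function(a) {
    b <- which(mol$bonds$i == a | mol$bonds$j == a)
    other <- ifelse(mol$bonds$i[b] == a, mol$bonds$j[b], mol$bonds$i[b])
    list(atom = other[!is_h[other]], cls = cls[b][!is_h[other]])
  })
  nh <- vapply(seq_len(mol_natoms(mol)), function(a) {
    sum(is_h[mol_neighbors(mol, a)])
  }, integer(1))
  inv0 <- paste(mol$atoms$elem, lengths(lapply(nbrs, `[[`, "atom")), nh,
                mol$atoms$fcharge, as.integer(ring), sep = ":")
  expand <- function(inv) {
    vapply(seq_along(inv), function(a) {
      nb <- nbrs[[a]]
      if (length(nb$atom) == 0) return(inv[a])
      paste(inv[a], paste(sort(paste0(nb$cls, inv[nb$atom])), collapse = "|"),
            sep = ">")
    }, character(1))
  }
  inv1 <- .fnv1a(expand(inv0))
  inv2 <- .fnv1a(expand(inv1))
  cbind(r0 = .fnv1a(inv0), r1 = inv1, r2 = inv2)[heavy, , drop = FALSE]
}

.sa_table_env <- new.env(parent = emptyenv())

.sa_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.sa_table_env$tab)) return(.sa_table_env$tab)
    path <- growkit_example("sa_fragments.tsv")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  counts <- stats::setNames(tab$count, tab$fragment)
  .sa_table_env$tab <- counts
  counts
}

# approximate stereocentre count: sp3 carbons whose four substituent
# environments are all distinct (branch environments at radius 1)
.sa_stereo_count <- function(mol, frag = NULL) {
  if (is.null(frag)) frag <- sa_fragments(mol)
  heavy <- mol_heavy(mol)
  inv1 <- stats::setNames(rep("H", mol_natoms(mol)), seq_len(mol_natoms(mol)))
  inv1[heavy] <- frag[, "r1"]
  n <- 0L
  arom <- mol_aromatic_bonds(mol)
  sp3 <- rep(TRUE, mol_natoms(mol))
  sp3[unique(c(mol$bonds$i[mol$bonds$order >= 2 | arom],
               mol$bonds$j[mol$bonds$order >= 2 | arom]))] <- FALSE
  for (a in which(mol$atoms$elem == "C" & sp3)) {
    nb <- mol_neighbors(mol, a)
    if (length(nb) == 4 && !anyDuplicated(paste(mol$atoms$elem[nb], inv1[nb]))) {
      n <- n + 1L
    }
  }
  n
}

# ring-system complexity: atoms shared between rings (spiro/bridge), plus
# any macrocycle
.sa_ring_stats <- function(mol) {
  rings <- mol_ring_list(mol)
  macro <- any(lengths(rings) > 8)
  shared <- 0L
  if (length(rings) > 1) {
    cnt <- table(unlist(rings))
    shared <- sum(cnt > 1)
  }
  list(macro = macro, shared = as.integer(shared))
}

#' Synthetic accessibility score (1 = easy, 10 = hard)
#'
#' Ertl-style: a fragment-contribution term (log-frequency of each heavy
#' atom's radius-2 circular environment in a bundled frequency snapshot of
#' common drug-like molecules) minus complexity penalties for size, stereo
#' centres, macrocycles and fused/spiro ring atoms, affinely mapped and
#' clamped to [1, 10]. The bundled table is a small snapshot, so scores are
#' approximate; the table file is swappable.
#'
#' @param mol a `gk_mol` or `gk_ligand`.
#' @param table_path optional path to an alternative fragment table (TSV with
#'   columns `fragment`, `count`).
#' @return numeric score in [1, 10] with a `terms` attribute giving the
#'   components.
#' @export
sa_score <- function(mol, table_path = NULL) {
  if (inherits(mol, "gk_ligand")) mol <- mol$mol
  heavy <- mol_heavy(mol)
  if (length(heavy) == 0) stop("molecule has no heavy atoms")
  counts <- .sa_table(table_path)
  cmax <- max(counts)
  frag <- sa_fragments(mol)
  hits <- counts[frag[, "r2"]]
  hits[is.na(hits)] <- 0
  frag_mean <- mean(log10((hits + 1) / (cmax + 1)))

  n <- length(heavy)
  size_pen <- n^1.005 - n
  stereo_pen <- log10(.sa_stereo_count(mol, frag) + 1)
  rs <- .sa_ring_stats(mol)
  macro_pen <- if (rs$macro) log10(2) else 0
  ring_pen <- log10(rs$shared + 1)

  total <- frag_mean - size_pen - stereo_pen - macro_pen - ring_pen
  score <- 1 + 9 * (-total) / 6
  score <- min(10, max(1, score))
  attr(score, "terms") <- c(frag_mean = frag_mean, size_pen = size_pen,
                            stereo_pen = stereo_pen, macro_pen = macro_pen,
                            ring_pen = ring_pen)
  score
}

# ---- substructure catalogs -------------------------------------------------

.read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file missing: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("corrupt catalog file: ", path)
  data.frame(pattern = vapply(parts, `[[`, "", 1),
             label = vapply(parts, `[[`, "", 2), stringsAsFactors = FALSE)
}

#' Flag undesirable substructures (PAINS / NIH / unwanted catalogs)
#'
#' Matches the molecule against the three bundled SMARTS catalogs (pinned
#' snapshot subsets shipped with the package) and reports a boolean per
#' catalog plus the labels of every matched pattern.
#'
#' @param mol a `gk_mol` or `gk_ligand`.
#' @param catalog_dir directory holding `pains.txt`, `nih.txt`,
#'   `unwanted.txt` (defaults to the bundled catalogs).
#' @return list(pains, nih, unwanted, matched_patterns)
#' @export
substructure_flags <- function(mol, catalog_dir = growkit_example("catalogs")) {
  if (inherits(mol, "gk_ligand")) mol <- mol$mol
  sdfset <- mol_to_sdfset(mol)
  out <- list()
  matched <- character(0)
  for (cat_name in c("pains", "nih", "unwanted")) {
    cat_tab <- .read_catalog(file.path(catalog_dir, paste0(cat_name, ".txt")))
    hit <- vapply(cat_tab$pattern, function(p) {
      res <- tryCatch(ChemmineR::smartsSearchOB(sdfset, p),
                      error = function(e) stop("invalid SMARTS in catalog ",
                                               cat_name, ": ", p))
      sum(res) > 0
    }, logical(1), USE.NAMES = FALSE)
    out[[cat_name]] <- any(hit)
    if (any(hit)) {
      matched <- c(matched, paste0(cat_name, ":", cat_tab$label[hit]))
    }
  }
  out$matched_patterns <- matched
  out
}

#' Full property report for a grown ligand
#'
#' @param mol a `gk_mol` or `gk_ligand`.
#' @param catalog_dir see [substructure_flags()].
#' @return one-row data.frame combining [ro5_report()], [sa_score()] and
#'   [substructure_flags()].
#' @export
property_report <- function(mol, catalog_dir = growkit_example("catalogs")) {
  if (inherits(mol, "gk_ligand")) mol <- mol$mol
  r <- ro5_report(mol)
  s <- sa_score(mol)
  f <- substructure_flags(mol, catalog_dir)
  cbind(r, data.frame(sa_score = as.numeric(s), pains = f$pains, nih = f$nih,
                      unwanted = f$unwanted,
                      matched_patterns = paste(f$matched_patterns,
                                               collapse = ";")))
}
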