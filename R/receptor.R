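# Rigid receptor: parsing, sanitisation (strip/keep), hydrogen completion and
# nonbonded parameterisation. Receptor coordinates are never modified after
# load; all downstream refinement treats every receptor atom as fixed.

# standard amino acids plus common protonation variants
.gk_protein_res <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "ASH", "GLH", "CYX", "LYN")

.gk_water_res <- c("HOH", "WAT", "TIP", "TIP3", "SOL")

# Open Babel CLI wrapper for receptor-scale conversions (the library binding
# is used for small molecules; protein-sized structures go through the
# command-line tool)
.obabel <- function(args) {
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) stop("the 'obabel' command-line tool is required ",
                         "for receptor processing but was not found on PATH")
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("obabel failed (status ", status, "): ",
         paste(utils::tail(out, 3), collapse = "; "))
  }
  invisible(out)
}

#' Construct a receptor from an atom table
#' @param atoms data.frame with columns elem, name, resid, resno, chain,
#'   x, y, z (and optionally pcharge, rmin, eps).
#' @keywords internal
gk_receptor <- function(atoms, retained_waters = character(0),
                        parameterised = FALSE, source = "") {
  for (col in c("pcharge", "rmin", "eps")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  if (is.null(atoms$fcharge)) atoms$fcharge <- rep(0L, nrow(atoms))
  structure(list(atoms = atoms, retained_waters = retained_waters,
                 parameterised = parameterised, all_fixed = TRUE,
                 source = source),
            class = "gk_receptor")
}

#' @export
print.gk_receptor <- function(x, ...) {
  cat(sprintf("<gk_receptor> %d atoms, %d residues, %d retained waters%s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$resid, x$atoms$resno,
                                                 x$atoms$chain))),
              length(x$retained_waters),
              if (x$parameterised) ", parameterised" else ""))
  invisible(x)
}

receptor_coords <- function(receptor) {
  unname(as.matrix(receptor$atoms[, c("x", "y", "z")]))
}

# PDB charge column ("1+", "2-", ...) -> integer
.parse_pdb_charge <- function(ch) {
  ch <- trimws(ifelse(is.na(ch), "", ch))
  sgn <- ifelse(grepl("-", ch), -1L, 1L)
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch)))
  out <- ifelse(nzchar(ch) & !is.na(num), sgn * num, 0L)
  as.integer(out)
}

.infer_element <- function(elesy, name) {
  e <- trimws(elesy)
  bad <- is.na(e) | !nzchar(e)
  if (any(bad)) {
    # strip digits/primes then take the leading element symbol
    nm <- gsub("[0-9\\x27\"]", "", trimws(name[bad]))
    two <- toupper(substr(nm, 1, 2)) %in% c("CL", "BR")
    e[bad] <- ifelse(two, paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2))),
                     substr(nm, 1, 1))
  }
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 10)))
}

#' Load a rigid receptor from a PDB file
#'
#' Standard protein residues are retained; water and other hetero residues
#' are stripped unless matched by `keep_residues`. Alternate locations other
#' than the first ("A") are dropped.
#'
#' @param pdb_file path to a PDB file.
#' @param keep_residues optional character vector of residue selectors, each
#'   either `"RESNAME"` or `"RESNAME RESNO"` (e.g. `"HOH 305"`).
#' @return a `gk_receptor`.
#' @export
load_receptor <- function(pdb_file, keep_residues = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(pdb_file, verbose = FALSE),
                  error = function(e) stop("unparseable PDB: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (nrow(a) == 0) stop("PDB contains no atom records")
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  restag <- paste(a$resid, a$resno)
  is_protein <- a$resid %in% .gk_protein_res
  keep <- is_protein
  kept_res <- character(0)
  if (!is.null(keep_residues)) {
    for (sel in keep_residues) {
      parts <- strsplit(trimws(sel), "\\s+")[[1]]
      hit <- if (length(parts) == 1) a$resid == parts[1]
             else a$resid == parts[1] & a$resno == as.integer(parts[2])
      if (!any(hit)) stop("unknown residue selector: ", sel)
      keep <- keep | hit
      kept_res <- c(kept_res, unique(restag[hit]))
    }
  }
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms retained: empty protein after stripping")
  atoms <- data.frame(
    elem = .infer_element(a$elesy, a$elety),
    name = a$elety, resid = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    fcharge = .parse_pdb_charge(a$charge), stringsAsFactors = FALSE)
  gk_receptor(atoms, retained_waters = unique(kept_res), source = pdb_file)
}

#' Write a receptor to a PDB file
#' @param receptor a `gk_receptor`.
#' @param file output path.
#' @export
receptor_write_pdb <- function(receptor, file) {
  a <- receptor$atoms
  writeLines(c(.pdb_atom_lines(a, het = !(a$resid %in% .gk_protein_res)),
               "END"), file)
  invisible(file)
}

# fixed-width PDB ATOM/HETATM records
.pdb_atom_lines <- function(a, het = FALSE, serial_start = 1L) {
  rec <- if (length(het) == 1) rep(ifelse(het, "HETATM", "ATOM  "), nrow(a))
         else ifelse(het, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(a$name) <= 3, sprintf(" %-3s", a$name),
               sprintf("%-4s", a$name))
  fc <- if (is.null(a$fcharge)) integer(nrow(a)) else a$fcharge
  chg <- ifelse(fc == 0 | is.na(fc), "  ",
                paste0(abs(fc), ifelse(fc > 0, "+", "-")))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%s",
          rec, serial_start + seq_len(nrow(a)) - 1L, nm, a$resid,
          substr(a$chain, 1, 1), a$resno, a$x, a$y, a$z, 1, 0,
          toupper(a$elem), chg)
}

#' Complete a receptor: rebuild missing backbone oxygens, add hydrogens
#'
#' Missing backbone carbonyl O atoms are reconstructed from the local
#' N/CA/C geometry; hydrogens are then added at pH 7 through the Open Babel
#' protonation model. Original heavy-atom coordinates are untouched and the
#' atom count never decreases.
#'
#' @param receptor a `gk_receptor`.
#' @return the completed `gk_receptor`.
#' @export
fix_receptor <- function(receptor) {
  a <- receptor$atoms
  # rebuild missing backbone O from CA-C and the next residue's N
  prot <- which(a$resid %in% .gk_protein_res)
  res_split <- split(prot, paste(a$chain[prot], a$resno[prot]))
  for (rr in res_split) {
    nms <- a$name[rr]
    if (all(c("N", "CA", "C") %in% nms) && !("O" %in% nms)) {
      cpos <- unlist(a[rr[nms == "C"][1], c("x", "y", "z")])
      capos <- unlist(a[rr[nms == "CA"][1], c("x", "y", "z")])
      resno <- a$resno[rr[1]]; chain <- a$chain[rr[1]]
      nxt <- which(a$resno == resno + 1 & a$chain == chain & a$name == "N")
      if (length(nxt) >= 1) {
        npos <- unlist(a[nxt[1], c("x", "y", "z")])
        bis <- -((capos - cpos) / sqrt(sum((capos - cpos)^2)) +
                 (npos - cpos) / sqrt(sum((npos - cpos)^2)))
      } else {
        bis <- -(capos - cpos)
      }
      bis <- bis / sqrt(sum(bis^2))
      opos <- cpos + 1.23 * bis
      a <- rbind(a, data.frame(elem = "O", name = "O", resid = a$resid[rr[1]],
                               resno = resno, chain = chain,
                               x = opos[1], y = opos[2], z = opos[3],
                               pcharge = NA_real_, rmin = NA_real_,
                               eps = NA_real_, fcharge = 0L))
    }
  }
  ord <- order(a$chain, a$resno, match(a$name, c("N", "CA", "C", "O")),
               na.last = TRUE)
  a <- a[ord, , drop = FALSE]

  # already-complete structures pass through unchanged (idempotence): a
  # residue counts as protonated when it carries at least one hydrogen
  prot_res <- unique(paste(a$chain, a$resno)[a$resid %in% .gk_protein_res])
  has_h <- unique(paste(a$chain, a$resno)[a$elem == "H"])
  if (length(prot_res) > 0 && all(prot_res %in% has_h)) {
    return(gk_receptor(a, retained_waters = receptor$retained_waters,
                       parameterised = receptor$parameterised,
                       source = receptor$source))
  }

  tin <- tempfile(fileext = ".pdb"); tout <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(tin, tout)))
  tmp <- gk_receptor(a, receptor$retained_waters, source = receptor$source)
  receptor_write_pdb(tmp, tin)
  .obabel(c(tin, "-O", tout, "-p", "7"))
  prot_out <- load_receptor_raw(tout)
  if (nrow(prot_out$atoms) < nrow(a)) {
    stop("structure completion removed atoms unexpectedly; residues involved: ",
         paste(utils::head(setdiff(paste(a$resid, a$resno),
                                   paste(prot_out$atoms$resid,
                                         prot_out$atoms$resno))),
               collapse = ", "))
  }
  # keep the original heavy-atom records verbatim (Open Babel relabels
  # topologically equivalent branches and renumbers residues); take only the
  # added hydrogens and attach each to the residue of its nearest heavy atom
  hnew <- prot_out$atoms[prot_out$atoms$elem == "H", , drop = FALSE]
  hold <- sum(a$elem == "H")
  if (nrow(hnew) > hold) {
    heavy <- a[a$elem != "H", , drop = FALSE]
    # adopt the perceived protonation-state formal charges (coordinates are
    # unchanged, so heavy atoms match exactly)
    hout <- prot_out$atoms[prot_out$atoms$elem != "H", , drop = FALSE]
    if (nrow(hout) == nrow(heavy)) {
      ax <- as.matrix(heavy[, c("x", "y", "z")])
      bx <- as.matrix(hout[, c("x", "y", "z")])
      d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
      hit <- apply(d2, 1, which.min)
      ok <- sqrt(pmax(0, d2[cbind(seq_len(nrow(ax)), hit)])) < 1e-2
      heavy$fcharge[ok] <- hout$fcharge[hit[ok]]
    }
    hx <- as.matrix(hnew[, c("x", "y", "z")])
    hv <- as.matrix(heavy[, c("x", "y", "z")])
    d2 <- outer(rowSums(hx^2), rowSums(hv^2), "+") - 2 * hx %*% t(hv)
    parent <- apply(d2, 1, which.min)
    hnew$resid <- heavy$resid[parent]
    hnew$resno <- heavy$resno[parent]
    hnew$chain <- heavy$chain[parent]
    merged <- rbind(heavy, hnew)
  } else {
    merged <- a
  }
  merged <- merged[order(merged$chain, merged$resno,
                         merged$elem == "H"), , drop = FALSE]
  rownames(merged) <- NULL
  gk_receptor(merged, retained_waters = receptor$retained_waters,
              source = receptor$source)
}

# read a PDB keeping every atom (used for round-tripping fixed structures)
#' @keywords internal
load_receptor_raw <- function(pdb_file) {
  pdb <- bio3d::read.pdb(pdb_file, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    elem = .infer_element(a$elesy, a$elety),
    name = a$elety, resid = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    fcharge = .parse_pdb_charge(a$charge), stringsAsFactors = FALSE)
  gk_receptor(atoms, source = pdb_file)
}

#' Assign nonbonded parameters to a receptor
#'
#' Partial charges come from Gasteiger electronegativity equalisation (Open
#' Babel backend), which conserves the total formal charge of the structure;
#' Lennard-Jones parameters are element-keyed (UFF set). The receptor must be
#' complete (hydrogens present) for meaningful charges.
#'
#' @param receptor a `gk_receptor`.
#' @param ff_name identifier of the parameter scheme; `"gasteiger-uff"` is
#'   the built-in backend.
#' @return the receptor with `pcharge`, `rmin`, `eps` filled in.
#' @export
parameterise_receptor <- function(receptor, ff_name = "gasteiger-uff") {
  if (!identical(ff_name, "gasteiger-uff")) {
    stop("unknown force field backend: ", ff_name)
  }
  a <- receptor$atoms
  bad <- !(a$elem %in% .gk_elements$elem)
  if (any(bad)) {
    stop("no parameters for element(s): ",
         paste(unique(a$elem[bad]), collapse = ", "),
         " (residues ", paste(unique(a$resid[bad]), collapse = ", "), ")")
  }
  tin <- tempfile(fileext = ".pdb"); tout <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(tin, tout)))
  receptor_write_pdb(receptor, tin)
  .obabel(c(tin, "-O", tout))
  lines <- readLines(tout, warn = FALSE)
  a0 <- grep("^@<TRIPOS>ATOM", lines)[1]
  a1 <- grep("^@<TRIPOS>", lines)
  a1 <- min(a1[a1 > a0])
  rows <- lines[(a0 + 1):(a1 - 1)]
  rows <- rows[nzchar(trimws(rows))]
  q <- vapply(strsplit(trimws(rows), "\\s+"),
              function(f) as.numeric(f[9]), numeric(1))
  if (length(q) != nrow(a)) {
    stop("charge backend returned ", length(q), " atoms, expected ", nrow(a))
  }
  # normalise residual drift so charges sum to the nearest integer total
  q <- q + (round(sum(q)) - sum(q)) / length(q)
  receptor$atoms$pcharge <- q
  receptor$atoms$rmin <- .gk_elem_prop(a$elem, "vdw_x")
  receptor$atoms$eps <- .gk_elem_prop(a$elem, "vdw_d")
  receptor$parameterised <- TRUE
  receptor
}

#' Construct a pre-parameterised receptor from bare coordinates
#'
#' Convenience constructor used by the synthetic fixtures and tests: every
#' atom gets an explicit charge and Lennard-Jones parameter set.
#'
#' @param coords n x 3 matrix (Angstrom).
#' @param elem element symbols (recycled).
#' @param pcharge partial charges, e (recycled).
#' @param rmin like-pair minimum-energy distances, Angstrom (default: UFF by
#'   element).
#' @param eps well depths, kcal/mol (default: UFF by element).
#' @return a parameterised `gk_receptor`.
#' @export
make_point_receptor <- function(coords, elem = "C", pcharge = 0,
                                rmin = NULL, eps = NULL) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  elem <- rep_len(elem, n)
  atoms <- data.frame(
    elem = elem, name = elem, resid = rep("TOY", n), resno = seq_len(n),
    chain = rep("A", n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    pcharge = rep_len(pcharge, n),
    rmin = if (is.null(rmin)) .gk_elem_prop(elem, "vdw_x") else rep_len(rmin, n),
    eps = if (is.null(eps)) .gk_elem_prop(elem, "vdw_d") else rep_len(eps, n),
    stringsAsFactors = FALSE)
  gk_receptor(atoms, parameterised = TRUE, source = "point-receptor")
}
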