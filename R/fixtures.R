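# Download-free synthetic fixtures: geometric toy pockets and a small bundled
# R-group library, plus the brute-force distance oracle used to validate the
# clash filter. Toy pockets are test scaffolds, not realistic binding sites.

#' Path to a bundled example/fixture file
#' @param file file name under the package's extdata directory; empty lists
#'   the directory.
#' @export
growkit_example <- function(file = "") {
  if (!nzchar(file)) return(system.file("extdata", package = "growkit"))
  p <- system.file("extdata", file, package = "growkit")
  if (!nzchar(p)) stop("no bundled file called ", file)
  p
}

#' Generate a deterministic toy receptor pocket
#'
#' Places a pseudo-random shell of parameterised C/N/O atoms around an empty
#' cavity centred at the origin; no atom lies within `cavity_radius` of the
#' centre, and the assigned point charges sum to zero. The result is a
#' fully-parameterised rigid receptor suitable for pocket refinement tests.
#'
#' @param seed RNG seed (the pocket is a pure function of it).
#' @param cavity_radius cavity radius in Angstrom (> 0).
#' @param n_atoms number of shell atoms (>= 10).
#' @param pdb_file optional path; when given the pocket is also written as PDB.
#' @return list with elements `receptor` (a `gk_receptor`), `cavity_radius`,
#'   `centre`, and `seed`.
#' @export
make_toy_pocket <- function(seed = 1L, cavity_radius = 6.0, n_atoms = 60L,
                            pdb_file = NULL) {
  if (cavity_radius <= 0) stop("cavity_radius must be > 0")
  if (n_atoms < 10) stop("n_atoms must be >= 10")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  # sequential rejection sampling: shell atoms keep >= 2.8 A separation
  coords <- matrix(NA_real_, n_atoms, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n_atoms && tries < n_atoms * 2000L) {
    tries <- tries + 1L
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    cand <- d * stats::runif(1, cavity_radius + 0.5, cavity_radius + 3.5)
    if (placed == 0L ||
        min(sqrt(rowSums(sweep(coords[seq_len(placed), , drop = FALSE],
                               2, cand)^2))) >= 2.8) {
      placed <- placed + 1L
      coords[placed, ] <- cand
    }
  }
  if (placed < n_atoms) stop("could not place ", n_atoms,
                             " atoms on the shell; increase cavity_radius")
  elem <- sample(c("C", "N", "O"), n_atoms, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  q <- rep_len(c(0.1, -0.1), n_atoms)
  if (n_atoms %% 2 == 1) q[n_atoms] <- 0
  rec <- make_point_receptor(coords, elem = elem, pcharge = q)
  if (!is.null(pdb_file)) receptor_write_pdb(rec, pdb_file)
  list(receptor = rec, cavity_radius = cavity_radius,
       centre = c(0, 0, 0), seed = as.integer(seed))
}

#' The bundled toy R-group library
#'
#' A stand-in for the large curated medicinal-chemistry libraries: ~25 common
#' substituents (alkyl, aryl, polar, halogen, and one bromo fragment that
#' exercises the ML-element fallback) shipped as frozen 3D SDF files with a
#' TSV index.
#'
#' @param dir library directory: SDF files plus an `index.tsv` with columns
#'   `label`, `filename`, `attachment_atom` (defaults to the bundled library).
#' @return named list of `gk_rgroup` objects.
#' @export
toy_rgroup_library <- function(dir = growkit_example("rgroups")) {
  idx_file <- file.path(dir, "index.tsv")
  if (!file.exists(idx_file)) stop("no index.tsv in ", dir)
  idx <- utils::read.delim(idx_file, stringsAsFactors = FALSE)
  if (anyDuplicated(idx$label)) stop("R-group labels must be unique")
  out <- lapply(seq_len(nrow(idx)), function(k) {
    rgroup_from_sdf(file.path(dir, idx$filename[k]),
                    attachment_atom = idx$attachment_atom[k],
                    label = idx$label[k])
  })
  names(out) <- idx$label
  out
}

#' Exact minimum pairwise distance by double loop
#'
#' Reference oracle for the clash filter: O(N*M) over all atom pairs, no
#' shortcuts.
#'
#' @param coords_a,coords_b coordinate matrices (n x 3, m x 3), non-empty.
#' @return the minimum distance in Angstrom.
#' @export
oracle_pairwise_min_distance <- function(coords_a, coords_b) {
  coords_a <- matrix(coords_a, ncol = 3)
  coords_b <- matrix(coords_b, ncol = 3)
  if (nrow(coords_a) == 0 || nrow(coords_b) == 0) {
    stop("both coordinate sets must be non-empty")
  }
  best <- Inf
  for (i in seq_len(nrow(coords_a))) {
    for (j in seq_len(nrow(coords_b))) {
      d <- sqrt(sum((coords_a[i, ] - coords_b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}
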