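# Element-keyed lookup tables used across the package.
# Masses: IUPAC 2021 standard atomic weights (abridged).
# Covalent radii: Cordero et al. consensus values (Angstrom).
# vdW parameters: UFF nonbonded set; `x` is the like-pair minimum-energy
# distance (Angstrom), `d` the well depth (kcal/mol).

.gk_elements <- data.frame(
  elem = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998,
           30.974, 32.06, 35.45, 79.904, 126.904),
  rcov = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02, 1.20, 1.39),
  vdw_x = c(2.886, 4.083, 3.851, 3.660, 3.500, 3.364,
            4.147, 4.035, 3.947, 4.189, 4.500),
  vdw_d = c(0.044, 0.180, 0.105, 0.069, 0.060, 0.050,
            0.305, 0.274, 0.227, 0.251, 0.339),
  # nominal maximum valence (neutral atom) for post-merge sanity checks
  valence = c(1, 3, 4, 3, 2, 1, 5, 6, 1, 1, 1),
  stringsAsFactors = FALSE
)
rownames(.gk_elements) <- .gk_elements$elem

#' Coulomb constant in kcal * Angstrom / (mol * e^2)
#' @noRd
.gk_kcoul <- 332.0637

#' Gas constant in kcal/(mol K)
#' @noRd
.gk_rgas <- 1.98720425e-3

.gk_elem_prop <- function(elem, prop) {
  idx <- match(elem, .gk_elements$elem)
  if (anyNA(idx)) {
    stop("unsupported element(s): ",
         paste(unique(elem[is.na(idx)]), collapse = ", "))
  }
  .gk_elements[[prop]][idx]
}

#' Elements covered by the ANI-style ML ligand backend
#' @noRd
.gk_ml_elements <- c("H", "C", "N", "O", "F", "S", "Cl")
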