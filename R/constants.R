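# Physical constants and element tables used package-wide.
# Units are fixed internally: Angstrom, elementary charge, kJ/mol.

#' Coulomb constant in kJ mol^-1 Angstrom e^-2
#'
#' The electrostatic prefactor used by every Coulomb sum in the package,
#' 1389.35458 kJ mol^-1 A e^-2 (CODATA-derived).
#'
#' @export
k_coulomb <- 1389.35458

# Covalent radii (A) for distance-based bond inference.
.covalent_radius <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, "NA" = 1.66, K = 2.03, MG = 1.41,
  CA = 1.76, ZN = 1.22, FE = 1.32
)

# van der Waals radii (A) for SASA (Bondi-style values).
.vdw_radius <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, "NA" = 2.27, K = 2.75, MG = 1.73,
  CA = 2.31, ZN = 1.39, FE = 2.00
)

# Standard bond lengths (A) used for the default scaled link-atom rule.
.standard_bond <- c(
  "C-H" = 1.090, "C-C" = 1.526, "C-N" = 1.471, "C-O" = 1.410,
  "C-S" = 1.810, "N-H" = 1.010, "O-H" = 0.960, "S-H" = 1.336
)

.element_lookup <- function(table, elements, default = NA_real_) {
  out <- unname(table[toupper(elements)])
  out[is.na(out)] <- default
  out
}

.standard_bond_length <- function(el1, el2) {
  key1 <- paste(toupper(el1), toupper(el2), sep = "-")
  key2 <- paste(toupper(el2), toupper(el1), sep = "-")
  out <- ifelse(!is.na(.standard_bond[key1]), .standard_bond[key1],
                .standard_bond[key2])
  unname(out)
}
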