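## Physical constants (kcal/mol/e/Angstrom unit system, T = 298 K)

## Coulomb constant: e^2 * N_A / (4 pi eps0), kcal * Angstrom / (mol e^2)
.COULOMB <- 332.0636

## kT at 298 K in kcal/mol
.KT298 <- 0.0019872041 * 298

## 2.303 * R * T at 298 K: one pKa unit in kcal/mol
.PK_KCAL <- 1.364

## region label codes for DielectricMap arrays
.REGION <- c(
  protein_layer_3 = 1L, protein_layer_5 = 2L,
  protein_layer_10 = 3L, protein_layer_20 = 4L,
  membrane_core = 5L, membrane_head = 6L, solvent = 7L
)

#' Inverse square Debye length
#'
#' Returns kappa^2 in 1/Angstrom^2 for a 1:1 electrolyte of the given ionic
#' strength in a medium of permittivity \code{eps}.
#'
#' @param ionicStrength ionic strength, mol/L
#' @param eps relative permittivity of the salt-bearing medium
#' @param temperature temperature in K
#' @return kappa^2 in Angstrom^-2
#' @export
debyeKappaSq <- function(ionicStrength, eps, temperature = 298) {
  if (ionicStrength <= 0) return(0)
  kT <- 0.0019872041 * temperature
  ## number density of a 1:1 salt: sum c_i z_i^2 = 2 I, in atoms/A^3
  n <- 2 * ionicStrength * 6.02214076e-4
  4 * pi * .COULOMB * n / (eps * kT)
}
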