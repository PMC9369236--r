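#' Physical constants used throughout the package
#'
#' Returns the fixed set of physical constants in the package's internal unit
#' convention: energies in meV, time in ps, lengths in Angstrom, temperature
#' in K, molar energies in kJ/mol.
#'
#' @return A named list with components
#'   \describe{
#'     \item{hbar}{Reduced Planck constant, 0.6582119 meV ps.}
#'     \item{kB}{Boltzmann constant, 0.0861733 meV/K.}
#'     \item{Rgas}{Molar gas constant, 0.0083145 kJ/(mol K).}
#'     \item{kJ_per_kcal}{4.184 kJ per kcal (thermochemical calorie).}
#'     \item{kB_J}{Boltzmann constant in J/K, used for resilience
#'       pseudo-force constants.}
#'   }
#' @examples
#' ns_constants()$hbar
#' @export
ns_constants <- function() {
  list(
    hbar = 0.6582119,      # meV ps
    kB = 0.0861733,        # meV / K
    Rgas = 0.0083145,      # kJ / (mol K)
    kJ_per_kcal = 4.184,
    kB_J = 1.380649e-23    # J / K
  )
}

# internal shortcut, avoids repeated list construction in hot loops
.const <- ns_constants()
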