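## Internal unit system: nm, kJ/mol, elementary charge e, degrees, Kelvin.
## Energies in kcal/mol appear only at the energy-histogram bin boundary
## (converted with 1 cal = 4.184 J at construction time).

#' Physical constants used throughout the package
#'
#' All internal quantities are expressed in nm, kJ/mol, elementary charges,
#' degrees and Kelvin. These constants perform the conversions between that
#' system and reported units (Debye, bar, g/cm^3).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ mol^-1 K^-1.}
#'   \item{coulomb}{Coulomb prefactor \eqn{1/(4\pi\epsilon_0)}, kJ mol^-1 nm e^-2.}
#'   \item{debyePerENm}{Debye per e nm.}
#'   \item{avogadro}{Avogadro constant, mol^-1.}
#'   \item{kcalToKj}{kJ per kcal (1 cal = 4.184 J).}
#'   \item{barPerKjMolNm3}{bar per kJ mol^-1 nm^-3.}
#'   \item{massO,massH,massWater}{Atomic/molecular masses, g/mol.}
#' }
#' @export
dffitConstants <- list(
  kB             = 0.0083144621,
  coulomb        = 138.935458,
  debyePerENm    = 48.032,
  avogadro       = 6.02214076e23,
  kcalToKj       = 4.184,
  barPerKjMolNm3 = 16.6054,
  massO          = 15.9994,
  massH          = 1.00794,
  massWater      = 18.01528
)

## Deterministic 32-bit seed derivation: one master seed per run, one stream
## per (generation, individual). Keeps every value strictly below 2^31.
deriveSeed <- function(master, generation = 0L, individual = 0L) {
  m <- 2147483647
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + 12345 + 69621 * as.numeric(generation)) %% m
  x <- (x * 48271 + 12345 + 16807 * as.numeric(individual)) %% m
  as.integer(x %% (m - 1L)) + 1L
}
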