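#' Physical constants and unit conventions
#'
#' The package uses a single fixed unit system throughout: coordinates in
#' angstrom, energies in electronvolt, partial charges in units of the
#' elementary charge, temperatures in kelvin. There is no unit
#' autodetection.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{k_B}{Boltzmann constant, 8.617333262e-5 eV/K (CODATA).}
#'   \item{k_e}{Coulomb constant, 14.399645 eV.A/e^2.}
#'   \item{dG_SHE}{Absolute oxidation free energy of the standard
#'     hydrogen electrode, 4.44 eV per electron.}
#'   \item{T_default}{Default simulation temperature, 310 K.}
#' }
#' @export
redox_constants <- list(
  k_B = 8.617333262e-5,
  k_e = 14.399645,
  dG_SHE = 4.44,
  T_default = 310
)

## standard atomic masses (amu) for center-of-mass computations
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, CL = 35.45, K = 39.098
)
.atomic_masses["NA"] <- 22.990

#' Look up standard atomic masses
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @keywords internal
atomic_mass <- function(elements) {
  el <- toupper(elements)
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(el[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

## internal: stop with a class so callers/CLI can map to exit codes
.validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("redoxlra_validation_error", "error")))
}

.io_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("redoxlra_io_error", "error")))
}

#' Round to printed precision
#'
#' Half-away-from-zero rounding with a tiny guard against binary
#' representation error, matching how tabulated values at a fixed number
#' of decimals are conventionally printed (e.g. 7.135 eV prints as 7.14).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
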