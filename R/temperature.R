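#' @name physical-constants
#' @title Physical constants used by the temperature machinery
#' @description CODATA values: the molar gas constant `GAS_CONSTANT_R`
#'   (J mol^-1 K^-1) and the Boltzmann constant `BOLTZMANN_KB` (J K^-1).
#' @export
GAS_CONSTANT_R <- 8.31446261815324

#' @rdname physical-constants
#' @export
BOLTZMANN_KB <- 1.380649e-23

#' Convert degrees Celsius to Kelvin
#'
#' @param celsius temperature in degrees C
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(celsius) {
  kelvin <- as.numeric(celsius) + 273.15
  if (any(kelvin <= 0)) stop("temperature below absolute zero", call. = FALSE)
  kelvin
}

#' Arrhenius rate constant
#'
#' k = A exp(-dG / (R T)): the rate constant of an elementary reaction with
#' collision prefactor `A` and activation free energy `dG` at absolute
#' temperature `T`. For the composite reactions of gene expression the
#' activation parameters are not tabulated, so this is an expository utility;
#' the simulation scenarios are driven by [shift_factors] instead.
#'
#' @param prefactor_A collision-rate prefactor (same units as the returned
#'   rate constant); must be positive
#' @param delta_G activation free energy (J/mol); must be non-negative
#' @param temperature_K absolute temperature (K); must be positive
#' @return The rate constant (units of `prefactor_A`). Vectorized over
#'   `temperature_K`.
#' @examples
#' arrhenius_rate(1, 0, 298.15)  # zero barrier: k = A
#' @export
arrhenius_rate <- function(prefactor_A, delta_G, temperature_K) {
  if (!is.finite(prefactor_A) || prefactor_A <= 0) {
    stop("prefactor_A must be positive", call. = FALSE)
  }
  if (!is.finite(delta_G) || delta_G < 0) {
    stop("delta_G must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0)) {
    stop("temperature_K must be positive", call. = FALSE)
  }
  prefactor_A * exp(-delta_G / (GAS_CONSTANT_R * temperature_K))
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = kb T / (6 pi eta R0): translational diffusion coefficient of a
#' spherical particle of hydrodynamic radius `R0` in a solvent of dynamic
#' viscosity `eta` at absolute temperature `T`. At fixed viscosity D is
#' linear in T, so a 10 K drop near room temperature reduces diffusion (and
#' hence molecular encounter rates) by only a few percent; the strong
#' temperature sensitivity of composite reactions must come from the number
#' of encounters required and the reactive fraction per encounter.
#'
#' @param temperature_K absolute temperature (K)
#' @param viscosity_eta dynamic viscosity (Pa s)
#' @param hydro_radius_R0 hydrodynamic radius (m)
#' @return Diffusion coefficient (m^2/s). Vectorized over `temperature_K`.
#' @examples
#' stokes_einstein_D(287.15, 1e-3, 2e-9) / stokes_einstein_D(297.15, 1e-3, 2e-9)
#' @export
stokes_einstein_D <- function(temperature_K, viscosity_eta, hydro_radius_R0) {
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0)) {
    stop("temperature_K must be positive", call. = FALSE)
  }
  if (!is.finite(viscosity_eta) || viscosity_eta <= 0) {
    stop("viscosity_eta must be positive", call. = FALSE)
  }
  if (!is.finite(hydro_radius_R0) || hydro_radius_R0 <= 0) {
    stop("hydro_radius_R0 must be positive", call. = FALSE)
  }
  BOLTZMANN_KB * temperature_K / (6 * pi * viscosity_eta * hydro_radius_R0)
}

#' Van't Hoff (Q10) temperature factor
#'
#' The multiplicative change of a rate over a temperature change `delta_T`,
#' given its Q10 (fold change per 10 K): factor = q10^(delta_T / 10).
#' Cooling (negative `delta_T`) gives a factor below 1. Biochemical
#' reactions typically have Q10 between 2 and 3; chloroplast translation is
#' about 2.5-fold per 10 K.
#'
#' @param q10 fold change per 10 K warming (> 1)
#' @param delta_T temperature change in K (negative for cooling)
#' @return Dimensionless factor. Vectorized over `delta_T`.
#' @examples
#' q10_factor(2.5, -10)  # 0.4
#' @export
q10_factor <- function(q10, delta_T) {
  if (!is.finite(q10) || q10 <= 1) stop("q10 must exceed 1", call. = FALSE)
  q10^(as.numeric(delta_T) / 10)
}

#' Encounter counts needed to synthesize an mRNA or a protein
#'
#' Order-of-magnitude bookkeeping for why production reactions are more
#' temperature sensitive than degradation: making the mRNA for a protein of
#' `protein_length_aa` amino acids takes at least three successful
#' nucleotide encounters per codon (3 x length), and translating it takes
#' roughly one loaded-tRNA encounter per amino acid, whereas a protease or
#' ribonuclease needs a single encounter with its target. Both counts are
#' reported together with their nearest power of ten.
#'
#' @param protein_length_aa protein length in amino acids (>= 1)
#' @return A list with `mrna_encounters`, `translation_encounters`, and the
#'   corresponding `mrna_order`, `translation_order` (nearest powers of ten).
#' @examples
#' encounter_estimate(350)  # ~1000 encounters to make the mRNA
#' @export
encounter_estimate <- function(protein_length_aa) {
  n <- as.numeric(protein_length_aa)[1]
  if (!is.finite(n) || n < 1) {
    stop("protein_length_aa must be at least 1", call. = FALSE)
  }
  mrna <- 3 * n
  transl <- n
  list(
    mrna_encounters = mrna,
    translation_encounters = transl,
    mrna_order = 10^round(log10(mrna)),
    translation_order = 10^round(log10(transl))
  )
}
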