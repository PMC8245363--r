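#' Rate constants of the four-reaction expression model
#'
#' Bundles the four rate parameters of the transcription-translation model:
#' `k1`, the zeroth-order transcription rate (concentration per time, a.u.);
#' `k2`, the first-order mRNA degradation rate constant (1/time); `k3`, the
#' first-order translation rate constant (1/time, per unit mRNA); and `k4`,
#' the first-order protein degradation rate constant (1/time). All units are
#' arbitrary; the model works in relative rates.
#'
#' @param k1 transcription rate (a.u. concentration / a.u. time)
#' @param k2 mRNA degradation rate constant (1 / a.u. time)
#' @param k3 translation rate constant (1 / a.u. time)
#' @param k4 protein degradation rate constant (1 / a.u. time)
#'
#' @return An object of class `rate_constants`: a named numeric vector
#'   `c(k1, k2, k3, k4)`.
#' @examples
#' rate_constants(2.5, 1, 2.5, 1)
#' @export
rate_constants <- function(k1, k2, k3, k4) {
  k <- c(k1 = as.numeric(k1)[1], k2 = as.numeric(k2)[1],
         k3 = as.numeric(k3)[1], k4 = as.numeric(k4)[1])
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("all four rate constants must be strictly positive and finite",
         call. = FALSE)
  }
  structure(k, class = "rate_constants")
}

#' Coerce to rate constants
#'
#' Accepts a `rate_constants` object, a named list/vector with entries
#' `k1..k4`, or an unnamed numeric vector of length 4 (in k1..k4 order).
#'
#' @param x object to coerce
#' @return A `rate_constants` object.
#' @export
as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  x <- unlist(x)
  if (!is.null(names(x)) && all(c("k1", "k2", "k3", "k4") %in% names(x))) {
    return(rate_constants(x[["k1"]], x[["k2"]], x[["k3"]], x[["k4"]]))
  }
  if (length(x) == 4L) {
    return(rate_constants(x[1], x[2], x[3], x[4]))
  }
  stop("cannot interpret 'x' as four rate constants k1..k4", call. = FALSE)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (a.u.):\n")
  cat(sprintf("  k1 (transcription)        = %g\n", x[["k1"]]))
  cat(sprintf("  k2 (mRNA degradation)     = %g\n", x[["k2"]]))
  cat(sprintf("  k3 (translation)          = %g\n", x[["k3"]]))
  cat(sprintf("  k4 (protein degradation)  = %g\n", x[["k4"]]))
  invisible(x)
}

#' Reference rate sets for the warm and cold conditions
#'
#' The package's reference parameterization of the model at 24 degrees C
#' (warm, pre-shift) and 14 degrees C (cold, post-shift). Across the 10
#' degree drop the production rates (transcription k1, translation k3) fall
#' 10-fold while the two degradation rates (k2, k4) fall only 2-fold,
#' reflecting the much larger number of molecular encounters needed to
#' synthesize a macromolecule than to degrade one.
#'
#' @param temperature 24 or 14 (degrees C)
#' @return A [rate_constants] object.
#' @examples
#' reference_rates(24)  # (2.5, 1, 2.5, 1)
#' reference_rates(14)  # (0.25, 0.5, 0.25, 0.5)
#' @export
reference_rates <- function(temperature = 24) {
  temperature <- as.numeric(temperature)[1]
  if (isTRUE(temperature == 24)) {
    rate_constants(2.5, 1, 2.5, 1)
  } else if (isTRUE(temperature == 14)) {
    rate_constants(0.25, 0.5, 0.25, 0.5)
  } else {
    stop("reference rates are defined at 24 and 14 degrees C only",
         call. = FALSE)
  }
}

#' Multiplicative shift factors for the four reactions
#'
#' Dimensionless factors f1..f4 applied to the rate constants k1..k4 at a
#' temperature shift. Cooling is expressed by factors below 1.
#'
#' @param f1,f2,f3,f4 strictly positive multiplicative factors for k1..k4
#' @return An object of class `shift_factors` (named numeric vector).
#' @export
shift_factors <- function(f1, f2, f3, f4) {
  f <- c(f1 = as.numeric(f1)[1], f2 = as.numeric(f2)[1],
         f3 = as.numeric(f3)[1], f4 = as.numeric(f4)[1])
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("all shift factors must be strictly positive and finite",
         call. = FALSE)
  }
  structure(f, class = "shift_factors")
}

#' @export
print.shift_factors <- function(x, ...) {
  cat(sprintf("Shift factors: f1 = %g, f2 = %g, f3 = %g, f4 = %g\n",
              x[["f1"]], x[["f2"]], x[["f3"]], x[["f4"]]))
  invisible(x)
}

#' Apply temperature-shift factors to a rate set
#'
#' Element-wise product: the post-shift rates are (k1 f1, k2 f2, k3 f3,
#' k4 f4). Composing two factor sets is equivalent to applying their
#' element-wise product once.
#'
#' @param rates a [rate_constants] object (pre-shift rates)
#' @param factors a [shift_factors] object
#' @return The post-shift [rate_constants].
#' @examples
#' apply_shift(reference_rates(24), shift_factors(0.1, 0.5, 0.1, 0.5))
#' @export
apply_shift <- function(rates, factors) {
  rates <- as_rate_constants(rates)
  if (!inherits(factors, "shift_factors")) {
    factors <- do.call(shift_factors, as.list(unlist(factors)))
  }
  rate_constants(rates[["k1"]] * factors[["f1"]],
                 rates[["k2"]] * factors[["f2"]],
                 rates[["k3"]] * factors[["f3"]],
                 rates[["k4"]] * factors[["f4"]])
}

#' Named cold-shift scenarios
#'
#' The four canonical cold-shift scenarios compare how strongly production
#' (k1, k3) and degradation (k2, k4) are slowed by the temperature drop:
#'
#' * `uniform`: all four reactions slowed by the same factor (0.1). mRNA and
#'   protein steady states are unchanged, so concentrations stay constant.
#' * `degradation_spared`: production slowed 10-fold, both degradations only
#'   2-fold (factors 0.1, 0.5, 0.1, 0.5) -- the reference cold condition;
#'   mRNA and protein both fall.
#' * `protein_degradation_spared`: only protein degradation is spared
#'   (factors 0.1, 0.1, 0.1, 0.5).
#' * `mrna_degradation_spared`: only mRNA degradation is spared
#'   (factors 0.1, 0.5, 0.1, 0.1).
#'
#' @param name one of the scenario names above
#' @return A [shift_factors] object.
#' @examples
#' apply_shift(reference_rates(24), scenario_factors("degradation_spared"))
#' @export
scenario_factors <- function(name) {
  presets <- list(
    uniform                     = shift_factors(0.1, 0.1, 0.1, 0.1),
    degradation_spared          = shift_factors(0.1, 0.5, 0.1, 0.5),
    protein_degradation_spared  = shift_factors(0.1, 0.1, 0.1, 0.5),
    mrna_degradation_spared     = shift_factors(0.1, 0.5, 0.1, 0.1)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown scenario; valid names: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' @rdname scenario_factors
#' @export
scenario_names <- function() {
  c("uniform", "degradation_spared", "protein_degradation_spared",
    "mrna_degradation_spared")
}
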