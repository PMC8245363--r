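#' Design of a synthetic immunoblot time course
#'
#' Sampling layout of the emulated western-blot experiment: a control plant
#' kept warm and a plant shifted to the cold at time zero, each sampled at
#' the same time points with replicate blots per point. The default grid is
#' dense early and sparse late -- 0, 0.5 min, 5 min, 20 min, 1 h, 5 h,
#' 1 day and 2 days after the shift -- for three thylakoid-complex core
#' subunits (PetA, PsbA, AtpA) with three replicates.
#'
#' @param time_points_h sampling times in hours, starting at 0, increasing
#' @param n_replicates replicates per time point (>= 1)
#' @param proteins character vector of protein labels
#' @param conditions character vector, by default `control` and `shifted`
#' @return An object of class `blot_design`.
#' @export
blot_design <- function(time_points_h = c(0, 0.5 / 60, 5 / 60, 20 / 60,
                                          1, 5, 24, 48),
                        n_replicates = 3,
                        proteins = c("PetA", "PsbA", "AtpA"),
                        conditions = c("control", "shifted")) {
  time_points_h <- as.numeric(time_points_h)
  if (time_points_h[1] != 0 || any(diff(time_points_h) <= 0)) {
    stop("time_points_h must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)[1]
  if (n_replicates < 1L) stop("need at least one replicate", call. = FALSE)
  structure(list(time_points_h = time_points_h,
                 n_replicates = n_replicates,
                 proteins = as.character(proteins),
                 conditions = as.character(conditions)),
            class = "blot_design")
}

#' Noise model for synthetic blot intensities
#'
#' Two noise components act on the latent kinetic signal: a slow shared
#' sinusoidal fluctuation (amplitude as a fraction of the signal, default
#' period 24 h with one phase per protein, affecting control and shifted
#' series identically -- mimicking circadian/developmental drift) and
#' multiplicative lognormal measurement noise per blot with the given
#' coefficient of variation (densitometry readings are positive and roughly
#' CV-stable).
#'
#' @param multiplicative_cv coefficient of variation of the lognormal
#'   measurement noise (fraction, >= 0; default 0.1)
#' @param fluctuation_amplitude fractional amplitude of the shared slow
#'   oscillation (0 <= amplitude < 1; default 0.15)
#' @param fluctuation_period period of the oscillation in hours (default 24)
#' @param seed integer random seed
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_cv = 0.1,
                        fluctuation_amplitude = 0.15,
                        fluctuation_period = 24,
                        seed = 1L) {
  cv <- as.numeric(multiplicative_cv)[1]
  amp <- as.numeric(fluctuation_amplitude)[1]
  period <- as.numeric(fluctuation_period)[1]
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (!is.finite(amp) || amp < 0 || amp >= 1) {
    stop("fluctuation_amplitude must be in [0, 1)", call. = FALSE)
  }
  if (!is.finite(period) || period <= 0) {
    stop("fluctuation_period must be positive", call. = FALSE)
  }
  structure(list(multiplicative_cv = cv, fluctuation_amplitude = amp,
                 fluctuation_period = period, seed = as.integer(seed)[1]),
            class = "noise_model")
}

#' Relative quantification of replicate intensities
#'
#' Reproduces the blot quantification: each replicate series is divided by
#' its own intensity at time 0, then the relative values are averaged
#' across replicates per time point. The result is invariant to rescaling
#' any single replicate (e.g. loading or exposure differences).
#'
#' @param raw numeric matrix of raw intensities, one row per replicate, one
#'   column per time point; the first column is the 0-min sample
#' @return List with `relative` (matrix of per-replicate relative values)
#'   and `averaged` (numeric vector of replicate means per time point).
#' @examples
#' quantify_relative(rbind(c(2, 4), c(4, 8)))  # averaged: 1, 2
#' @export
quantify_relative <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw) || ncol(raw) < 1) {
    stop("raw must be a numeric matrix (replicates x time points)",
         call. = FALSE)
  }
  if (any(!is.finite(raw[, 1])) || any(raw[, 1] <= 0)) {
    stop("each replicate needs a positive intensity at time 0",
         call. = FALSE)
  }
  rel <- sweep(raw, 1, raw[, 1], "/")
  list(relative = rel, averaged = colMeans(rel))
}

#' Generate a synthetic immunoblot dataset
#'
#' Emulates the quantified western-blot time courses. The latent protein
#' signal comes from the kinetic model: the control series sits at the
#' warm (pre-shift) steady state, while the shifted series starts there and
#' evolves under the post-shift rates from time zero (the blot clock starts
#' at the shift; model time is mapped to wall-clock hours via
#' `hours_per_unit`). The latent signal is modulated by the shared slow
#' fluctuation and per-blot lognormal noise from the [noise_model], then
#' each replicate is normalized to its own 0-min sample and replicates are
#' averaged (see [quantify_relative()]). Fully reproducible given the seed.
#'
#' @param design a [blot_design]
#' @param protocol a [shift_protocol]; only its rate sets are used -- the
#'   shifted condition applies `rates_post` from time 0
#' @param noise a [noise_model]
#' @param hours_per_unit wall-clock hours per model time unit (default 1)
#' @return A data frame of class `blot_dataset` with columns `protein`,
#'   `condition`, `time_h`, `replicate`, `relative_abundance`, and an
#'   `averaged` attribute (data frame of replicate means per time point).
#' @examples
#' prot <- shift_protocol(reference_rates(24), reference_rates(14))
#' blots <- generate_blots(blot_design(), prot, noise_model(seed = 7))
#' head(attr(blots, "averaged"))
#' @export
generate_blots <- function(design, protocol, noise = noise_model(),
                           hours_per_unit = 1) {
  if (!inherits(design, "blot_design")) stop("not a blot_design",
                                             call. = FALSE)
  if (!inherits(protocol, "shift_protocol")) stop("not a shift_protocol",
                                                  call. = FALSE)
  if (!inherits(noise, "noise_model")) stop("not a noise_model",
                                            call. = FALSE)
  hours_per_unit <- as.numeric(hours_per_unit)[1]
  if (!is.finite(hours_per_unit) || hours_per_unit <= 0) {
    stop("hours_per_unit must be positive", call. = FALSE)
  }
  t_h <- design$time_points_h
  t_model <- t_h / hours_per_unit
  warm_ss <- steady_state(protocol$rates_pre)
  latent <- list(
    control = rep(warm_ss$protein, length(t_model)),
    shifted = closed_form(protocol$rates_post,
                          system_state(warm_ss$mrna, warm_ss$protein, 0),
                          t = t_model)$protein
  )
  set.seed(noise$seed)
  phases <- stats::runif(length(design$proteins), 0, 2 * pi)
  names(phases) <- design$proteins
  sdlog <- sqrt(log(1 + noise$multiplicative_cv^2))
  tidy <- list()
  avg <- list()
  for (prot in design$proteins) {
    wobble <- 1 + noise$fluctuation_amplitude *
      sin(2 * pi * t_h / noise$fluctuation_period + phases[[prot]])
    for (cond in design$conditions) {
      base <- latent[[cond]] * wobble
      raw <- matrix(NA_real_, design$n_replicates, length(t_h))
      for (r in seq_len(design$n_replicates)) {
        eps <- stats::rlnorm(length(t_h), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
        raw[r, ] <- base * eps
      }
      q <- quantify_relative(raw)
      tidy[[paste(prot, cond)]] <- data.frame(
        protein = prot, condition = cond,
        time_h = rep(t_h, each = design$n_replicates),
        replicate = rep(seq_len(design$n_replicates), times = length(t_h)),
        relative_abundance = as.vector(q$relative)
      )
      avg[[paste(prot, cond)]] <- data.frame(
        protein = prot, condition = cond, time_h = t_h,
        mean_relative = q$averaged
      )
    }
  }
  out <- do.call(rbind, tidy)
  rownames(out) <- NULL
  averaged <- do.call(rbind, avg)
  rownames(averaged) <- NULL
  structure(out,
            averaged = averaged,
            design = design, noise = noise,
            hours_per_unit = hours_per_unit,
            class = c("blot_dataset", "data.frame"))
}

#' Write a blot dataset as tidy TSV files
#'
#' Writes the per-replicate tidy table (`protein`, `condition`, `time_h`,
#' `replicate`, `relative_abundance`) and, optionally, the
#' replicate-averaged series.
#'
#' @param dataset a `blot_dataset`
#' @param path tidy TSV path
#' @param path_averaged optional TSV path for the averaged series
#' @return `path`, invisibly.
#' @export
write_blots <- function(dataset, path, path_averaged = NULL) {
  if (!inherits(dataset, "blot_dataset")) {
    stop("not a blot_dataset", call. = FALSE)
  }
  utils::write.table(as.data.frame(dataset), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(path_averaged)) {
    utils::write.table(attr(dataset, "averaged"), path_averaged, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
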