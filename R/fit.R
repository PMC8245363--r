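#' Recover rate constants from a time course
#'
#' Least-squares fit of the four-reaction model to a measured time course,
#' using the exact closed-form solution for predictions and the
#' Levenberg-Marquardt minimizer with a deterministic multi-start (the
#' first start at the log-midpoint of the bounds, the rest drawn
#' log-uniformly under the seed). Parameters are fitted on the log scale,
#' which enforces positivity.
#'
#' Two data layouts are supported:
#' * absolute trajectory: columns `time`, `mrna`, `protein` -- all four
#'   rates are identifiable (given the initial state, default both species
#'   absent);
#' * normalized series: columns `time` (or `time_h`) and `relative`, a
#'   protein signal divided by its own value at time 0, as produced by blot
#'   quantification. Normalization destroys the absolute concentration
#'   scale, so the transcription rate k1 is not identifiable: it is fixed
#'   at 1 (unless supplied in `known`), the initial relative mRNA level is
#'   fitted as an extra parameter `m0`, and the result is flagged with
#'   `scale_identifiable = FALSE` together with the identifiable ratio
#'   structure (mRNA and protein steady states relative to the k1 = 1
#'   gauge).
#'
#' Non-convergence is reported in the `converged` flag, never as an error.
#'
#' @param data data frame in one of the two layouts above
#' @param known named numeric vector of rates fixed at known values,
#'   e.g. `c(k2 = 1, k4 = 1)`
#' @param bounds length-2 numeric (shared lower/upper bound for all free
#'   parameters, default `c(1e-3, 1e3)`)
#' @param seed integer seed for the multi-start draws
#' @param n_starts number of starts (>= 1, default 5)
#' @param init initial [system_state] for the absolute layout (default:
#'   both species absent)
#' @return An object of class `rate_fit`: list with `estimates`
#'   ([rate_constants]), `free`, `fixed`, `rss`, `converged`, `info`,
#'   `message`, `scale_identifiable`, `ratios` (normalized layout only,
#'   else NULL), `n_data`.
#' @examples
#' truth <- reference_rates(24)
#' traj <- closed_form(truth, system_state(0, 0), t = seq(0.25, 20, 0.5))
#' fit <- fit_rates(traj)
#' fit$estimates
#' @export
fit_rates <- function(data, known = NULL, bounds = c(1e-3, 1e3),
                      seed = 1L, n_starts = 5L,
                      init = system_state(0, 0)) {
  data <- as.data.frame(data)
  if ("time_h" %in% names(data) && !"time" %in% names(data)) {
    data$time <- data$time_h
  }
  normalized <- "relative" %in% names(data) &&
    !all(c("mrna", "protein") %in% names(data))
  if (!"time" %in% names(data)) stop("data needs a time column",
                                     call. = FALSE)
  if (!normalized && !all(c("mrna", "protein") %in% names(data))) {
    stop("data must have columns (time, mrna, protein) or (time, relative)",
         call. = FALSE)
  }
  known <- unlist(known)
  if (length(known) && (!all(names(known) %in% c("k1", "k2", "k3", "k4")) ||
                        any(known <= 0))) {
    stop("known must be a named positive vector over k1..k4", call. = FALSE)
  }
  bounds <- as.numeric(bounds)
  if (length(bounds) != 2 || any(bounds <= 0) || bounds[1] >= bounds[2]) {
    stop("bounds must be positive and increasing", call. = FALSE)
  }

  fixed <- as.list(known)
  scale_identifiable <- TRUE
  if (normalized && !"k1" %in% names(fixed)) {
    fixed$k1 <- 1
    scale_identifiable <- FALSE
  }
  free <- setdiff(c("k1", "k2", "k3", "k4"), names(fixed))
  if (normalized) free <- c(free, "m0")

  obs <- if (normalized) data$relative else c(data$mrna, data$protein)
  n_obs <- sum(is.finite(obs))
  if (n_obs < length(free)) {
    stop("need at least as many data points as free parameters",
         call. = FALSE)
  }

  predict_resid <- function(logpar) {
    par <- exp(logpar)
    k <- c(fixed, as.list(par[setdiff(free, "m0")]))
    rates <- rate_constants(k$k1, k$k2, k$k3, k$k4)
    if (normalized) {
      st <- system_state(par[["m0"]], 1, 0)
      pred <- closed_form(rates, st, t = data$time)$protein
      pred - data$relative
    } else {
      tr <- closed_form(rates, init, t = data$time)
      c(tr$mrna - data$mrna, tr$protein - data$protein)
    }
  }

  lo <- log(bounds[1]); hi <- log(bounds[2])
  n_starts <- max(1L, as.integer(n_starts)[1])
  set.seed(as.integer(seed))
  starts <- vector("list", n_starts)
  starts[[1]] <- stats::setNames(rep((lo + hi) / 2, length(free)), free)
  if (n_starts > 1) {
    for (i in 2:n_starts) {
      starts[[i]] <- stats::setNames(stats::runif(length(free), lo, hi), free)
    }
  }

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = st, lower = rep(lo, length(free)),
                           upper = rep(hi, length(free)),
                           fn = predict_resid,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, maxfev = 5000))),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    conv <- res$info %in% 1:4
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && rss < best$rss)) {
      best <- list(fit = res, rss = rss, conv = conv)
    }
  }

  if (is.null(best)) {
    return(structure(list(
      estimates = NULL, free = free, fixed = fixed, rss = NA_real_,
      converged = FALSE, info = NA_integer_,
      message = "all starts failed", scale_identifiable = scale_identifiable,
      ratios = NULL, n_data = n_obs), class = "rate_fit"))
  }

  par <- exp(best$fit$par)
  k <- c(fixed, as.list(par[setdiff(free, "m0")]))
  estimates <- rate_constants(k$k1, k$k2, k$k3, k$k4)
  ratios <- NULL
  if (normalized) {
    ss <- steady_state(estimates)
    ratios <- list(m0 = unname(par[["m0"]]),
                   mrna_ss_over_k1 = ss$mrna / estimates[["k1"]],
                   protein_ss_over_k1 = ss$protein / estimates[["k1"]])
  }
  structure(list(
    estimates = estimates, free = free, fixed = fixed,
    rss = best$rss, converged = best$conv, info = best$fit$info,
    message = best$fit$message,
    scale_identifiable = scale_identifiable,
    ratios = ratios, n_data = n_obs), class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("Rate-constant fit",
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$estimates)) print(x$estimates)
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  }
  cat(sprintf("  RSS = %g over %d observations\n", x$rss, x$n_data))
  if (!isTRUE(x$scale_identifiable)) {
    cat("  note: data are normalized; absolute scale (k1) not",
        "identifiable, k1 gauge-fixed\n")
  }
  invisible(x)
}
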