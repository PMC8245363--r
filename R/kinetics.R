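#' System state of the expression model
#'
#' Concentrations of the two species at a time point. Concentrations are in
#' arbitrary units and must be non-negative; `time` marks when the state
#' applies (used as the start time by [closed_form()]).
#'
#' @param mrna mRNA concentration (a.u., >= 0)
#' @param protein protein concentration (a.u., >= 0)
#' @param time time stamp (a.u., default 0)
#' @return An object of class `system_state`.
#' @export
system_state <- function(mrna = 0, protein = 0, time = 0) {
  s <- list(mrna = as.numeric(mrna)[1], protein = as.numeric(protein)[1],
            time = as.numeric(time)[1])
  if (any(!is.finite(unlist(s)))) {
    stop("state must be finite", call. = FALSE)
  }
  if (s$mrna < 0 || s$protein < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(s, class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("State at t = %g: mRNA = %g, protein = %g (a.u.)\n",
              x$time, x$mrna, x$protein))
  invisible(x)
}

#' Time derivatives of mRNA and protein
#'
#' The model has four lumped reactions: transcription at constant rate k1,
#' mRNA degradation at rate k2 * mRNA, translation at rate k3 * mRNA, and
#' protein degradation at rate k4 * protein. Hence
#' d(mRNA)/dt = k1 - k2 * mRNA and d(protein)/dt = k3 * mRNA - k4 * protein.
#'
#' @param state a [system_state]
#' @param rates a [rate_constants] object
#' @return Named numeric vector `c(mrna = d_mrna, protein = d_protein)`.
#' @examples
#' derivatives(system_state(0, 0), rate_constants(2.5, 1, 2.5, 1))
#' @export
derivatives <- function(state, rates) {
  rates <- as_rate_constants(rates)
  if (!inherits(state, "system_state")) {
    state <- system_state(state[[1]], state[[2]])
  }
  c(mrna = rates[["k1"]] - rates[["k2"]] * state$mrna,
    protein = rates[["k3"]] * state$mrna - rates[["k4"]] * state$protein)
}

#' Exact steady state of the expression model
#'
#' Setting both derivatives to zero gives mRNA_ss = k1 / k2 and
#' protein_ss = (k1 k3) / (k2 k4). Both are strictly positive for positive
#' rates, and invariant under a common scaling of all four rate constants --
#' the reason a uniform temperature effect on all reactions leaves
#' concentrations unchanged.
#'
#' @param rates a [rate_constants] object
#' @return An object of class `steady_state`: list with `mrna` and `protein`.
#' @examples
#' steady_state(reference_rates(24))  # mRNA 2.5, protein 6.25
#' @export
steady_state <- function(rates) {
  rates <- as_rate_constants(rates)
  structure(list(mrna = rates[["k1"]] / rates[["k2"]],
                 protein = rates[["k1"]] * rates[["k3"]] /
                   (rates[["k2"]] * rates[["k4"]])),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state: mRNA = %g, protein = %g (a.u.)\n",
              x$mrna, x$protein))
  invisible(x)
}

#' Trajectory container
#'
#' A data frame of class `trajectory` with columns `time`, `mrna`,
#' `protein`, strictly increasing in `time`.
#'
#' @param time,mrna,protein equal-length numeric vectors
#' @return A `trajectory` data frame.
#' @export
trajectory <- function(time, mrna, protein) {
  if (length(time) != length(mrna) || length(time) != length(protein)) {
    stop("time, mrna and protein must have equal length", call. = FALSE)
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = time, mrna = mrna, protein = protein),
            class = c("trajectory", "data.frame"))
}

#' Closed-form solution of the linear cascade
#'
#' The model is a linear first-order cascade, so its solution is exact:
#' mRNA(t) relaxes mono-exponentially to k1/k2 with rate k2, and protein(t)
#' is the standard two-exponential solution with rates k2 and k4. The
#' degenerate case k2 = k4 is resolved by its t exp(-k t) limit (triggered
#' when |k2 - k4| < 1e-12 max(k2, k4)). Serves as the analytic oracle for
#' the numerical integrator.
#'
#' @param rates a [rate_constants] object
#' @param init initial [system_state] (its `time` field is the start time)
#' @param t time(s) at which to evaluate, all >= `init$time`
#' @return A [trajectory] data frame with one row per element of `t`.
#' @examples
#' closed_form(reference_rates(24), system_state(0, 0), t = c(1, 5, 20))
#' @export
closed_form <- function(rates, init = system_state(0, 0), t) {
  rates <- as_rate_constants(rates)
  if (!inherits(init, "system_state")) stop("init must be a system_state",
                                            call. = FALSE)
  dt <- as.numeric(t) - init$time
  if (any(dt < 0)) stop("t must not precede init$time", call. = FALSE)
  k1 <- rates[["k1"]]; k2 <- rates[["k2"]]
  k3 <- rates[["k3"]]; k4 <- rates[["k4"]]
  ss <- steady_state(rates)
  dm <- init$mrna - ss$mrna
  em2 <- exp(-k2 * dt)
  mrna <- ss$mrna + dm * em2
  if (abs(k2 - k4) < 1e-12 * max(k2, k4)) {
    k <- k4
    protein <- ss$protein + (init$protein - ss$protein) * exp(-k * dt) +
      k3 * dm * dt * exp(-k * dt)
  } else {
    B <- k3 * dm / (k4 - k2)
    A <- init$protein - ss$protein - B
    protein <- ss$protein + A * exp(-k4 * dt) + B * em2
  }
  trajectory(as.numeric(t), mrna, protein)
}

#' Temperature-shift protocol
#'
#' One simulation experiment: the system runs with `rates_pre` from time 0,
#' all rates change instantaneously to `rates_post` at `shift_time`
#' (piecewise-constant rates, no ramp), and the run ends at `duration`.
#' Defaults place the shift at t = 400 with a total window of 1200 a.u.,
#' long enough for the reference rate sets to settle on both sides.
#'
#' @param rates_pre pre-shift [rate_constants]
#' @param rates_post post-shift [rate_constants]
#' @param shift_time time of the shift (0 < shift_time < duration)
#' @param duration total simulated time
#' @return An object of class `shift_protocol`.
#' @examples
#' shift_protocol(reference_rates(24), reference_rates(14))
#' @export
shift_protocol <- function(rates_pre, rates_post,
                           shift_time = 400, duration = 1200) {
  rates_pre <- as_rate_constants(rates_pre)
  rates_post <- as_rate_constants(rates_post)
  shift_time <- as.numeric(shift_time)[1]
  duration <- as.numeric(duration)[1]
  if (!is.finite(shift_time) || !is.finite(duration) ||
      shift_time <= 0 || shift_time >= duration) {
    stop("need 0 < shift_time < duration", call. = FALSE)
  }
  structure(list(rates_pre = rates_pre, rates_post = rates_post,
                 shift_time = shift_time, duration = duration),
            class = "shift_protocol")
}

#' @export
print.shift_protocol <- function(x, ...) {
  cat(sprintf("Shift protocol: shift at t = %g, duration %g\n",
              x$shift_time, x$duration))
  cat("Pre-shift "); print(x$rates_pre)
  cat("Post-shift "); print(x$rates_post)
  invisible(x)
}

ode_rhs <- function(t, y, parms) {
  list(c(parms[["k1"]] - parms[["k2"]] * y[1],
         parms[["k3"]] * y[1] - parms[["k4"]] * y[2]))
}

#' Integrate the model under piecewise-constant rates
#'
#' Integrates the ODE system with lsoda (rtol 1e-8, atol 1e-10) segment by
#' segment: `rates_list[[i]]` applies from `c(0, change_times)[i]` up to the
#' next change time, with the final segment ending at `duration`.
#' Concentrations are continuous across segment boundaries. Covers both the
#' single temperature shift and multi-phase interventions such as a
#' temporary complete stop of degradation followed by its restoration.
#'
#' @param rates_list list of [rate_constants], one per segment
#' @param change_times strictly increasing times of the rate changes
#'   (length = number of segments - 1), all in (0, duration)
#' @param duration total simulated time
#' @param init initial [system_state] at time 0
#' @param n_points number of output grid points over `[0, duration]` (>= 2);
#'   the change times are inserted into the grid
#' @return A [trajectory] data frame.
#' @export
simulate_piecewise <- function(rates_list, change_times, duration,
                               init = system_state(0, 0), n_points = 601) {
  rates_list <- lapply(rates_list, as_rate_constants)
  change_times <- as.numeric(change_times)
  duration <- as.numeric(duration)[1]
  n_points <- as.integer(n_points)[1]
  if (n_points < 2L) stop("n_points must be at least 2", call. = FALSE)
  if (length(rates_list) != length(change_times) + 1L) {
    stop("need one more rate set than change times", call. = FALSE)
  }
  if (length(change_times) &&
      (any(diff(c(0, change_times, duration)) <= 0))) {
    stop("change_times must be strictly increasing within (0, duration)",
         call. = FALSE)
  }
  grid <- sort(unique(c(seq(0, duration, length.out = n_points),
                        change_times)))
  bounds <- c(0, change_times, duration)
  y <- c(init$mrna, init$protein)
  out_t <- numeric(0); out_m <- numeric(0); out_p <- numeric(0)
  for (i in seq_along(rates_list)) {
    seg_t <- grid[grid >= bounds[i] & grid <= bounds[i + 1]]
    if (length(seg_t) == 0 || seg_t[1] > bounds[i]) seg_t <- c(bounds[i], seg_t)
    if (seg_t[length(seg_t)] < bounds[i + 1]) seg_t <- c(seg_t, bounds[i + 1])
    sol <- deSolve::ode(y = y, times = seg_t, func = ode_rhs,
                        parms = unclass(rates_list[[i]]),
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed in segment ", i, call. = FALSE)
    }
    keep <- if (i == 1L) seq_len(nrow(sol)) else seq(2, nrow(sol))
    out_t <- c(out_t, sol[keep, 1])
    out_m <- c(out_m, sol[keep, 2])
    out_p <- c(out_p, sol[keep, 3])
    y <- c(sol[nrow(sol), 2], sol[nrow(sol), 3])
  }
  dup <- duplicated(out_t)
  # tiny negative values from integrator round-off are clipped to zero
  trajectory(out_t[!dup], pmax(out_m[!dup], 0), pmax(out_p[!dup], 0))
}

#' Simulate a temperature-shift experiment
#'
#' Numerically integrates a [shift_protocol]: `rates_pre` up to
#' `shift_time`, `rates_post` afterwards, with concentrations continuous at
#' the shift. By default the simulation starts with none of the species
#' present.
#'
#' @param protocol a [shift_protocol]
#' @param init initial [system_state] (default: both species absent)
#' @param n_points number of output grid points (>= 2)
#' @return A [trajectory] data frame.
#' @examples
#' prot <- shift_protocol(reference_rates(24), reference_rates(14))
#' traj <- simulate_shift(prot)
#' tail(traj, 1)  # approaches the cold steady state (0.5, 0.25)
#' @export
simulate_shift <- function(protocol, init = system_state(0, 0),
                           n_points = 601) {
  if (!inherits(protocol, "shift_protocol")) {
    stop("protocol must be a shift_protocol", call. = FALSE)
  }
  simulate_piecewise(list(protocol$rates_pre, protocol$rates_post),
                     protocol$shift_time, protocol$duration,
                     init = init, n_points = n_points)
}

#' Has a trajectory reached steady state?
#'
#' Checks whether the relative variation of both species over the final 10%
#' of the time window is below `rel_tol`: max - min over that window,
#' relative to the mean level of the species (guarded for levels near zero).
#'
#' @param traj a [trajectory]
#' @param rel_tol relative tolerance (fraction, default 1e-4)
#' @return TRUE if both species are steady, FALSE otherwise.
#' @export
is_steady <- function(traj, rel_tol = 1e-4) {
  if (!inherits(traj, "trajectory") || nrow(traj) == 0) {
    stop("traj must be a non-empty trajectory", call. = FALSE)
  }
  t0 <- traj$time[1]; t1 <- traj$time[nrow(traj)]
  win <- traj$time >= t1 - 0.1 * (t1 - t0)
  steady_one <- function(x) {
    x <- x[win]
    scale <- max(mean(abs(x)), .Machine$double.eps)
    (max(x) - min(x)) / scale < rel_tol
  }
  steady_one(traj$mrna) && steady_one(traj$protein)
}

#' Write / read a trajectory as TSV
#'
#' Plain tab-separated text with header `time`, `mrna`, `protein`, one row
#' per grid point.
#'
#' @param traj a [trajectory]
#' @param path file path
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a [trajectory].
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "trajectory")) stop("not a trajectory", call. = FALSE)
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  trajectory(df$time, df$mrna, df$protein)
}
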