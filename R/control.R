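#' Control points of the expression model
#'
#' The four rates the chloroplast could adjust to compensate a
#' temperature-induced change: `transcription` (k1), `mrna_degradation`
#' (k2), `translation` (k3) and `protein_degradation` (k4).
#'
#' @return Character vector of the four control-point names.
#' @export
control_points <- function() {
  c("transcription", "mrna_degradation", "translation", "protein_degradation")
}

point_rate <- c(transcription = "k1", mrna_degradation = "k2",
                translation = "k3", protein_degradation = "k4")

check_point <- function(point) {
  if (!is.character(point) || length(point) != 1L ||
      !point %in% control_points()) {
    stop("control point must be one of: ",
         paste(control_points(), collapse = ", "), call. = FALSE)
  }
  point
}

as_target_ss <- function(target) {
  if (inherits(target, "steady_state")) return(target)
  if (is.list(target) && all(c("mrna", "protein") %in% names(target))) {
    return(structure(list(mrna = as.numeric(target$mrna),
                          protein = as.numeric(target$protein)),
                     class = "steady_state"))
  }
  stop("target must be a steady_state (or list with mrna and protein)",
       call. = FALSE)
}

new_control_solution <- function(points, fold_changes, post_rates,
                                 target_ss, target_species) {
  adj <- unclass(post_rates)
  for (p in points) adj[[point_rate[[p]]]] <- adj[[point_rate[[p]]]] *
      fold_changes[[p]]
  adjusted <- as_rate_constants(adj)
  structure(list(
    points = points,
    fold_changes = fold_changes,
    post_rates = post_rates,
    adjusted_rates = adjusted,
    achieved_ss = steady_state(adjusted),
    target_ss = target_ss,
    target_species = target_species,
    transition_time = transition_time(adjusted, "protein")
  ), class = "control_solution")
}

#' @export
print.control_solution <- function(x, ...) {
  cat("Control solution via:", paste(x$points, collapse = " + "), "\n")
  for (p in x$points) {
    fc <- x$fold_changes[[p]]
    dir <- if (fc >= 1) sprintf("%.4g-fold up", fc)
           else sprintf("%.4g-fold down", 1 / fc)
    cat(sprintf("  %s (%s): %s\n", p, point_rate[[p]], dir))
  }
  cat(sprintf("  achieved steady state: mRNA = %g, protein = %g\n",
              x$achieved_ss$mrna, x$achieved_ss$protein))
  cat(sprintf("  transition time (rate-sum formula): %g\n",
              x$transition_time))
  invisible(x)
}

#' Fold-change required at a single control point
#'
#' Inverts the steady-state formulas to find the unique multiplicative
#' change of one rate constant that restores a target steady state. With
#' the reference cold rates and the warm protein steady state as target,
#' transcription or translation must be upregulated 25-fold, or either
#' degradation rate downregulated 25-fold; stabilizing only the mRNA level
#' needs just a fivefold reduction of its degradation.
#'
#' @param point one of [control_points()]
#' @param post_rates the (uncompensated) post-shift [rate_constants]
#' @param target the [steady_state] to restore (typically the pre-shift one)
#' @param target_species `"protein"` or `"mrna"`: which species the target
#'   constrains. Defaults to `"protein"` for transcription, translation and
#'   protein degradation; must be stated explicitly for mRNA degradation,
#'   which affects both species.
#' @return A `control_solution`: the fold-change (on the rate constant;
#'   > 1 is upregulation, < 1 downregulation), the adjusted rates, the
#'   achieved steady state and the transition time.
#' @examples
#' warm <- steady_state(reference_rates(24))
#' required_fold_change("transcription", reference_rates(14), warm)
#' @export
required_fold_change <- function(point, post_rates, target,
                                 target_species = NULL) {
  point <- check_point(point)
  post_rates <- as_rate_constants(post_rates)
  target <- as_target_ss(target)
  if (is.null(target_species)) {
    if (point == "mrna_degradation") {
      stop("for mrna_degradation, state target_species (\"mrna\" or ",
           "\"protein\"): this rate sets both steady states", call. = FALSE)
    }
    target_species <- "protein"
  }
  target_species <- match.arg(target_species, c("protein", "mrna"))
  if (target_species == "mrna" &&
      point %in% c("translation", "protein_degradation")) {
    stop(point, " does not affect the mRNA steady state; target it via ",
         "transcription or mrna_degradation", call. = FALSE)
  }
  ss <- steady_state(post_rates)
  goal <- target[[target_species]]
  have <- ss[[target_species]]
  if (!is.finite(goal) || goal <= 0) {
    stop("unattainable target: the target steady state must be positive ",
         "and finite", call. = FALSE)
  }
  fc <- switch(point,
    transcription = goal / have,
    translation = goal / have,
    mrna_degradation = have / goal,
    protein_degradation = have / goal
  )
  fold_changes <- stats::setNames(list(fc), point)
  new_control_solution(point, fold_changes, post_rates, target,
                       target_species)
}

#' mRNA side effect of a control solution
#'
#' Restoring the protein level through the mRNA side of the cascade
#' (transcription or mRNA degradation) forces the mRNA pool itself to a
#' new level. This returns the achieved mRNA steady state divided by the
#' pre-shift mRNA steady state -- a fivefold rise for the reference
#' transcription-only compensation, well above four times the original pool.
#'
#' @param solution a `control_solution`
#' @param pre_shift_ss the pre-shift [steady_state]; defaults to the
#'   solution's own target when that carries an mRNA level
#' @return The mRNA fold-change (dimensionless).
#' @export
mrna_side_effect <- function(solution, pre_shift_ss = NULL) {
  if (!inherits(solution, "control_solution")) {
    stop("solution must be a control_solution", call. = FALSE)
  }
  if (is.null(pre_shift_ss)) pre_shift_ss <- solution$target_ss
  pre_shift_ss <- as_target_ss(pre_shift_ss)
  solution$achieved_ss$mrna / pre_shift_ss$mrna
}

#' Compensation shared across several control points
#'
#' When several rates are adjusted together, only the product of their
#' fold-changes is constrained: the protein steady state is restored
#' whenever (f1 f3) / (f2 f4) equals the required total. Under the equal
#' split of the reference 25-fold requirement, transcription and
#' translation each rise fivefold, or both degradations each fall fivefold.
#'
#' @param points character vector of [control_points()] (non-empty, unique)
#' @param post_rates the post-shift [rate_constants]
#' @param target the [steady_state] to restore (protein level is targeted)
#' @param split `"equal"`, or a named numeric vector giving the fold-change
#'   on each point's rate constant; a custom split must multiply out to the
#'   required total (production folds count directly, degradation folds
#'   reciprocally) or an error is raised
#' @return A `control_solution` covering all the points.
#' @examples
#' warm <- steady_state(reference_rates(24))
#' combined_control(c("transcription", "translation"),
#'                  reference_rates(14), warm)
#' @export
combined_control <- function(points, post_rates, target, split = "equal") {
  points <- unique(vapply(points, check_point, character(1)))
  if (length(points) == 0) stop("points must be non-empty", call. = FALSE)
  post_rates <- as_rate_constants(post_rates)
  target <- as_target_ss(target)
  ss <- steady_state(post_rates)
  total <- target$protein / ss$protein
  if (!is.finite(total) || total <= 0) {
    stop("unattainable target", call. = FALSE)
  }
  production <- c("transcription", "translation")
  if (identical(split, "equal")) {
    share <- total^(1 / length(points))
    fold_changes <- lapply(points, function(p) {
      if (p %in% production) share else 1 / share
    })
    names(fold_changes) <- points
  } else {
    if (is.null(names(split)) || !setequal(names(split), points)) {
      stop("a custom split must be a named numeric vector over exactly ",
           "the given points", call. = FALSE)
    }
    contrib <- vapply(points, function(p) {
      if (p %in% production) split[[p]] else 1 / split[[p]]
    }, numeric(1))
    if (abs(prod(contrib) - total) > 1e-8 * total) {
      stop(sprintf(
        "inconsistent split: fold-changes multiply to %.6g, need %.6g",
        prod(contrib), total), call. = FALSE)
    }
    fold_changes <- as.list(split)[points]
  }
  new_control_solution(points, fold_changes, post_rates, target, "protein")
}

#' Transition time between steady states
#'
#' The model's transition-time measure for a regulation acting at the mRNA
#' or the protein level, computed from the (adjusted) rate constants:
#' tau_mRNA = 1 / (k1 + k2) and tau_protein = 1 / (k1 + k2 + k3 + k4)
#' (`method = "rate_sum"`, the default). These sums mix the zeroth-order
#' transcription rate with first-order constants; they are used verbatim as
#' the model's speed measure. For comparison, `method = "relaxation"`
#' returns the textbook relaxation times of the linear cascade: 1 / k2 for
#' the mRNA and 1 / min(k2, k4) (the slowest eigenvalue) for the protein.
#'
#' @param rates the (adjusted) [rate_constants]
#' @param level `"mrna"` or `"protein"`
#' @param method `"rate_sum"` (default) or `"relaxation"`
#' @return Transition time (a.u.).
#' @examples
#' transition_time(reference_rates(24), "mrna")     # 1 / 3.5
#' transition_time(reference_rates(24), "protein")  # 1 / 7
#' @export
transition_time <- function(rates, level = c("mrna", "protein"),
                            method = c("rate_sum", "relaxation")) {
  rates <- as_rate_constants(rates)
  level <- match.arg(level)
  method <- match.arg(method)
  if (method == "rate_sum") {
    if (level == "mrna") 1 / (rates[["k1"]] + rates[["k2"]])
    else 1 / sum(rates)
  } else {
    if (level == "mrna") 1 / rates[["k2"]]
    else 1 / min(rates[["k2"]], rates[["k4"]])
  }
}

#' Simulate the response to a compensatory intervention
#'
#' Runs the model under a solution's adjusted rates from one of two
#' starting points: `"immediate"` starts at the pre-shift steady state (the
#' cell reacts the moment the temperature drops), `"settled"` starts at the
#' uncompensated post-shift steady state (the cell first relaxes into the
#' cold state, then compensates). Both converge to the restored steady
#' state; in immediate mode, protein-side interventions (translation up,
#' protein degradation down) transiently overshoot the final protein level
#' while mRNA-side interventions (transcription up, mRNA degradation down)
#' transiently dip below it. The trajectory is evaluated with the exact
#' closed-form solution.
#'
#' @param solution a `control_solution` whose target carries both species
#' @param mode `"immediate"` or `"settled"`
#' @param duration simulated time; default long enough to converge
#'   (18 / min(k2, k4) of the adjusted rates)
#' @param n_points output grid size
#' @return A [trajectory].
#' @export
response_simulation <- function(solution, mode = c("immediate", "settled"),
                                duration = NULL, n_points = 601) {
  if (!inherits(solution, "control_solution")) {
    stop("solution must be a control_solution", call. = FALSE)
  }
  mode <- match.arg(mode)
  adj <- solution$adjusted_rates
  init_ss <- if (mode == "immediate") solution$target_ss
             else steady_state(solution$post_rates)
  if (is.null(duration)) {
    duration <- 18 / min(adj[["k2"]], adj[["k4"]])
  }
  init <- system_state(init_ss$mrna, init_ss$protein, time = 0)
  closed_form(adj, init, t = seq(0, duration, length.out = n_points))
}

#' Cost-versus-speed Pareto front of compensation
#'
#' When an upregulated production rate and a downregulated degradation rate
#' share the compensation, their factors are constrained: restoring the
#' protein steady state requires up_factor x down_factor = F, the total
#' fold-compensation (25 for the reference shift). Sweeping the production
#' up-factor `u` over a log-spaced grid from 1 to F (with the degradation
#' down-factor d = F/u) trades cost against speed: the up-factor is a proxy
#' for the extra ATP demand of production, while the transition time tau
#' (rate-sum formula on the adjusted rates) falls monotonically as more of
#' the burden moves to production. `level = "mrna"` adjusts transcription
#' (k1 up) and mRNA degradation (k2 down), reporting tau_mRNA; `"protein"`
#' adjusts translation (k3 up) and protein degradation (k4 down), reporting
#' tau_protein. No point on the front dominates another.
#'
#' @param post_rates the post-shift [rate_constants]
#' @param target the [steady_state] to restore (protein level)
#' @param level `"mrna"` or `"protein"`: which production/degradation pair
#'   carries the compensation
#' @param n_grid number of grid points (>= 2, default 50)
#' @return A data frame of class `pareto_front` with columns `up_factor`,
#'   `down_factor`, `tau`, sorted by increasing `up_factor`.
#' @examples
#' warm <- steady_state(reference_rates(24))
#' pf <- pareto_front(reference_rates(14), warm, "mrna", n_grid = 5)
#' @export
pareto_front <- function(post_rates, target, level = c("mrna", "protein"),
                         n_grid = 50) {
  post_rates <- as_rate_constants(post_rates)
  target <- as_target_ss(target)
  level <- match.arg(level)
  n_grid <- as.integer(n_grid)[1]
  if (n_grid < 2L) stop("n_grid must be at least 2", call. = FALSE)
  total <- target$protein / steady_state(post_rates)$protein
  if (!is.finite(total) || total <= 1) {
    stop("target must require a net upregulation (total factor > 1)",
         call. = FALSE)
  }
  u <- exp(seq(0, log(total), length.out = n_grid))
  d <- total / u
  tau <- vapply(seq_along(u), function(i) {
    adj <- unclass(post_rates)
    if (level == "mrna") {
      adj[["k1"]] <- adj[["k1"]] * u[i]
      adj[["k2"]] <- adj[["k2"]] / d[i]
    } else {
      adj[["k3"]] <- adj[["k3"]] * u[i]
      adj[["k4"]] <- adj[["k4"]] / d[i]
    }
    transition_time(as_rate_constants(adj), level)
  }, numeric(1))
  structure(data.frame(up_factor = u, down_factor = d, tau = tau),
            class = c("pareto_front", "data.frame"))
}

#' Write a Pareto front as TSV
#'
#' Columns `up_factor`, `down_factor`, `tau`, tab-separated.
#'
#' @param front a `pareto_front`
#' @param path file path
#' @return `path`, invisibly.
#' @export
write_pareto <- function(front, path) {
  if (!inherits(front, "pareto_front")) {
    stop("not a pareto_front", call. = FALSE)
  }
  utils::write.table(as.data.frame(front), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
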