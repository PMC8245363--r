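# Shared fixtures: the reference warm/cold rate sets and small helpers.

warm_rates <- function() reference_rates(24)
cold_rates <- function() reference_rates(14)

random_rates <- function() {
  as_rate_constants(stats::runif(4, 0.05, 5))
}

# max relative deviation between two trajectories on a shared grid
max_rel_err <- function(a, b) {
  stopifnot(all(a$time == b$time))
  max(abs(a$mrna - b$mrna) / (abs(b$mrna) + 1e-8),
      abs(a$protein - b$protein) / (abs(b$protein) + 1e-8))
}

# single-segment numerical integration at constant rates
integrate_constant <- function(rates, duration, init = system_state(0, 0),
                               n_points = 201) {
  simulate_piecewise(list(rates), numeric(0), duration,
                     init = init, n_points = n_points)
}
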