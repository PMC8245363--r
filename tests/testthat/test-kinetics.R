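test_that("derivatives implement the four rate laws", {
  r <- rate_constants(2.5, 1, 2.5, 1)
  d0 <- derivatives(system_state(0, 0), r)
  expect_equal(unname(d0), c(2.5, 0))
  # at the steady state both derivatives vanish exactly
  expect_equal(unname(derivatives(system_state(2.5, 6.25), r)), c(0, 0))
  set.seed(11)
  for (i in 1:25) {
    rr <- random_rates()
    ss <- steady_state(rr)
    expect_equal(unname(derivatives(system_state(ss$mrna, ss$protein), rr)),
                 c(0, 0))
  }
  expect_error(derivatives(list(NaN, 1), r), "finite")
})

test_that("steady states are k1/k2 and k1 k3/(k2 k4)", {
  expect_equal(unclass(steady_state(rate_constants(2.5, 1, 2.5, 1))),
               list(mrna = 2.5, protein = 6.25))
  expect_equal(unclass(steady_state(rate_constants(0.25, 0.5, 0.25, 0.5))),
               list(mrna = 0.5, protein = 0.25))
  expect_equal(unclass(steady_state(rate_constants(1, 1, 1, 1))),
               list(mrna = 1, protein = 1))
  expect_error(rate_constants(0, 1, 1, 1), "positive")
  expect_error(steady_state(c(-1, 1, 1, 1)), "positive")
})

test_that("steady state is invariant under uniform scaling of all rates", {
  set.seed(21)
  for (i in 1:20) {
    r <- random_rates()
    c_fac <- stats::runif(1, 0.01, 100)
    scaled <- as_rate_constants(unclass(r) * c_fac)
    expect_equal(unclass(steady_state(scaled)), unclass(steady_state(r)))
  }
})

test_that("closed form fixes the steady state and reaches it as t grows", {
  set.seed(31)
  for (i in 1:20) {
    r <- random_rates()
    ss <- steady_state(r)
    at_ss <- closed_form(r, system_state(ss$mrna, ss$protein), t = c(0, 1, 7))
    expect_equal(at_ss$mrna, rep(ss$mrna, 3))
    expect_equal(at_ss$protein, rep(ss$protein, 3))
    far <- closed_form(r, system_state(0, 0),
                       t = 60 / min(r[["k2"]], r[["k4"]]))
    expect_equal(far$mrna, ss$mrna, tolerance = 1e-9)
    expect_equal(far$protein, ss$protein, tolerance = 1e-9)
  }
})

test_that("degenerate equal-degradation closed form matches the nearby
           non-degenerate solution", {
  r_eq <- rate_constants(2.5, 1, 2.5, 1)
  r_near <- rate_constants(2.5, 1, 2.5, 1 + 1e-9)
  t <- seq(0, 10, 0.5)
  a <- closed_form(r_eq, system_state(0, 0), t)
  b <- closed_form(r_near, system_state(0, 0), t)
  expect_equal(a$protein, b$protein, tolerance = 1e-6)
})

test_that("numerical integrator agrees with the closed form", {
  r <- rate_constants(2.5, 1, 2.5, 1)
  num <- integrate_constant(r, 20)
  exact <- closed_form(r, system_state(0, 0), t = num$time)
  expect_lt(max_rel_err(num, exact), 1e-6)
})

test_that("shift simulation is continuous and lands on the post-shift
           steady state", {
  prot <- shift_protocol(warm_rates(), cold_rates())
  traj <- simulate_shift(prot)
  expect_true(all(diff(traj$time) > 0))
  expect_true(all(traj$mrna >= 0) && all(traj$protein >= 0))
  # continuity at the shift: the state at shift_time is the settled warm
  # steady state, and the next grid point follows the cold dynamics started
  # from exactly that state
  i <- which(traj$time == prot$shift_time)
  expect_length(i, 1)
  expect_equal(traj$mrna[i], 2.5, tolerance = 1e-6)
  expect_equal(traj$protein[i], 6.25, tolerance = 1e-6)
  cont <- closed_form(cold_rates(),
                      system_state(traj$mrna[i], traj$protein[i],
                                   prot$shift_time),
                      t = traj$time[i + 1])
  expect_equal(traj$mrna[i + 1], cont$mrna, tolerance = 1e-6)
  expect_equal(traj$protein[i + 1], cont$protein, tolerance = 1e-6)
  # endpoints at the cold steady state
  n <- nrow(traj)
  expect_equal(traj$mrna[n], 0.5, tolerance = 1e-6)
  expect_equal(traj$protein[n], 0.25, tolerance = 1e-6)
})

test_that("a no-shift protocol converges to the single steady state with no
           kink", {
  prot <- shift_protocol(warm_rates(), warm_rates(),
                         shift_time = 10, duration = 30)
  traj <- simulate_shift(prot)
  n <- nrow(traj)
  expect_equal(traj$mrna[n], 2.5, tolerance = 1e-7)
  expect_equal(traj$protein[n], 6.25, tolerance = 1e-7)
  exact <- closed_form(warm_rates(), system_state(0, 0), t = traj$time)
  expect_lt(max_rel_err(traj, exact), 1e-6)
})

test_that("uniform slowdown of all rates leaves concentrations at the
           pre-shift steady state", {
  post <- apply_shift(warm_rates(), scenario_factors("uniform"))
  prot <- shift_protocol(warm_rates(), post)
  traj <- simulate_shift(prot)
  after <- traj[traj$time >= prot$shift_time, ]
  expect_equal(after$mrna, rep(2.5, nrow(after)), tolerance = 1e-6)
  expect_equal(after$protein, rep(6.25, nrow(after)), tolerance = 1e-6)
})

test_that("is_steady detects settled and growing trajectories", {
  flat <- trajectory(0:100, rep(1, 101), rep(2, 101))
  expect_true(is_steady(flat))
  growing <- trajectory(0:100, 1 + 0:100, 2 * (1 + 0:100))
  expect_false(is_steady(growing))
  long_run <- integrate_constant(warm_rates(), 40)
  expect_true(is_steady(long_run))
  short_run <- integrate_constant(warm_rates(), 2)
  expect_false(is_steady(short_run))
})

test_that("piecewise integration supports a temporary stop of degradation", {
  # protein degradation halted for a while, then restored: protein rises
  # during the pause and relaxes back afterwards
  r <- cold_rates()
  paused <- as_rate_constants(c(unclass(r)[1:3], k4 = 1e-9))
  traj <- simulate_piecewise(list(r, paused, r), c(50, 60), 200,
                             init = system_state(0.5, 0.25))
  during <- traj$protein[traj$time > 50 & traj$time <= 60]
  expect_true(all(diff(during) > 0))
  expect_equal(traj$protein[nrow(traj)], 0.25, tolerance = 1e-3)
})

test_that("trajectories round-trip through TSV", {
  traj <- integrate_constant(warm_rates(), 10, n_points = 21)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "time\tmrna\tprotein")
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(traj), tolerance = 1e-12)
  unlink(path)
})

test_that("trajectories from non-negative initial states stay non-negative", {
  set.seed(41)
  for (i in 1:20) {
    r <- random_rates()
    traj <- integrate_constant(r, 30 / min(r[["k2"]], r[["k4"]]))
    expect_true(all(traj$mrna >= 0))
    expect_true(all(traj$protein >= 0))
  }
})
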