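warm_ss <- function() steady_state(warm_rates())

test_that("single-point fold-changes invert the steady-state formulas", {
  f1 <- required_fold_change("transcription", cold_rates(), warm_ss())
  expect_equal(f1$fold_changes$transcription, 25)
  expect_equal(f1$achieved_ss$protein, 6.25)

  f3 <- required_fold_change("translation", cold_rates(), warm_ss())
  expect_equal(f3$fold_changes$translation, 25)

  f4 <- required_fold_change("protein_degradation", cold_rates(), warm_ss())
  expect_equal(f4$fold_changes$protein_degradation, 1 / 25)
  expect_equal(f4$adjusted_rates[["k4"]], 0.02)

  # targeting the protein through mRNA degradation: 25-fold decrease
  f2p <- required_fold_change("mrna_degradation", cold_rates(), warm_ss(),
                              target_species = "protein")
  expect_equal(f2p$fold_changes$mrna_degradation, 1 / 25)

  # stabilizing only the mRNA pool needs a fivefold decrease
  f2m <- required_fold_change("mrna_degradation", cold_rates(), warm_ss(),
                              target_species = "mrna")
  expect_equal(f2m$fold_changes$mrna_degradation, 1 / 5)
  expect_equal(f2m$achieved_ss$mrna, 2.5)

  # every protein-targeting solution restores the protein level exactly
  for (sol in list(f1, f3, f4, f2p)) {
    expect_identical(sol$achieved_ss$protein,
                     steady_state(sol$adjusted_rates)$protein)
    expect_equal(sol$achieved_ss$protein, 6.25)
  }
})

test_that("invalid control targets raise errors", {
  expect_error(required_fold_change("mrna_degradation", cold_rates(),
                                    warm_ss()), "target_species")
  expect_error(required_fold_change("translation", cold_rates(), warm_ss(),
                                    target_species = "mrna"),
               "does not affect")
  expect_error(required_fold_change("transcription", cold_rates(),
                                    list(mrna = 2.5, protein = -1)),
               "unattainable")
  expect_error(required_fold_change("ribosome", cold_rates(), warm_ss()),
               "control point")
})

test_that("mRNA side effects of protein-targeting solutions", {
  f1 <- required_fold_change("transcription", cold_rates(), warm_ss())
  expect_equal(mrna_side_effect(f1), 5)
  expect_gt(mrna_side_effect(f1), 4)
  f2 <- required_fold_change("mrna_degradation", cold_rates(), warm_ss(),
                             target_species = "protein")
  expect_equal(mrna_side_effect(f2), 5)
  # translation does not enter the mRNA steady state
  f3 <- required_fold_change("translation", cold_rates(), warm_ss())
  expect_equal(f3$achieved_ss$mrna, steady_state(cold_rates())$mrna)
})

test_that("combined control splits the total fold-change", {
  both_up <- combined_control(c("transcription", "translation"),
                              cold_rates(), warm_ss())
  expect_equal(both_up$fold_changes$transcription, 5)
  expect_equal(both_up$fold_changes$translation, 5)
  expect_equal(both_up$achieved_ss$protein, 6.25)

  both_down <- combined_control(c("mrna_degradation", "protein_degradation"),
                                cold_rates(), warm_ss())
  expect_equal(both_down$fold_changes$mrna_degradation, 1 / 5)
  expect_equal(both_down$fold_changes$protein_degradation, 1 / 5)
  expect_equal(both_down$achieved_ss$protein, 6.25)

  # degenerate single-point combination equals the direct solution
  single <- combined_control("transcription", cold_rates(), warm_ss())
  direct <- required_fold_change("transcription", cold_rates(), warm_ss())
  expect_equal(single$fold_changes$transcription,
               direct$fold_changes$transcription)

  # a custom split must multiply out to the required total
  ok <- combined_control(c("transcription", "translation"), cold_rates(),
                         warm_ss(), split = c(transcription = 12.5,
                                              translation = 2))
  expect_equal(ok$achieved_ss$protein, 6.25)
  expect_error(
    combined_control(c("transcription", "translation"), cold_rates(),
                     warm_ss(), split = c(transcription = 2,
                                          translation = 2)),
    "inconsistent split")
})

test_that("exact compensation holds across random post-shift conditions", {
  set.seed(13)
  for (i in 1:20) {
    post <- random_rates()
    target <- steady_state(random_rates())
    for (p in control_points()) {
      sol <- required_fold_change(p, post, target,
                                  target_species = "protein")
      expect_identical(sol$achieved_ss$protein,
                       steady_state(sol$adjusted_rates)$protein)
      expect_equal(sol$achieved_ss$protein, target$protein,
                   tolerance = 1e-12)
    }
  }
})

test_that("transition times follow the rate-sum formulas", {
  r <- warm_rates()
  expect_equal(transition_time(r, "mrna"), 1 / 3.5)
  expect_equal(transition_time(r, "protein"), 1 / 7)
  # homogeneity: scaling all rates by c scales tau by 1/c
  set.seed(17)
  for (i in 1:10) {
    rr <- random_rates()
    c_fac <- stats::runif(1, 0.1, 10)
    scaled <- as_rate_constants(unclass(rr) * c_fac)
    expect_equal(transition_time(scaled, "mrna"),
                 transition_time(rr, "mrna") / c_fac)
    expect_equal(transition_time(scaled, "protein"),
                 transition_time(rr, "protein") / c_fac)
  }
  # labelled relaxation-time alternative
  expect_equal(transition_time(r, "mrna", "relaxation"), 1)
  expect_equal(transition_time(rate_constants(1, 2, 1, 0.5), "protein",
                               "relaxation"), 2)
})

test_that("immediate responses overshoot for protein-side control and dip
           for mRNA-side control", {
  tol <- 1e-6
  for (p in c("translation", "protein_degradation")) {
    sol <- required_fold_change(p, cold_rates(), warm_ss())
    tr <- response_simulation(sol, "immediate")
    expect_gt(max(tr$protein), 6.25 + tol)     # transient maximum above
    expect_equal(tr$protein[nrow(tr)], 6.25, tolerance = 1e-4)
  }
  for (p in c("transcription", "mrna_degradation")) {
    sol <- required_fold_change(p, cold_rates(), warm_ss(),
                                target_species = "protein")
    tr <- response_simulation(sol, "immediate")
    expect_lt(min(tr$protein), 6.25 - tol)     # transient minimum below
    expect_equal(tr$protein[nrow(tr)], 6.25, tolerance = 1e-4)
  }
})

test_that("settled responses converge to the restored steady state", {
  solutions <- c(
    lapply(control_points(), function(p)
      required_fold_change(p, cold_rates(), warm_ss(),
                           target_species = "protein")),
    list(combined_control(c("transcription", "translation"),
                          cold_rates(), warm_ss()),
         combined_control(c("mrna_degradation", "protein_degradation"),
                          cold_rates(), warm_ss())))
  for (sol in solutions) {
    tr <- response_simulation(sol, "settled")
    expect_equal(tr$protein[1],
                 steady_state(cold_rates())$protein, tolerance = 1e-12)
    expect_equal(tr$protein[nrow(tr)], sol$achieved_ss$protein,
                 tolerance = 1e-4)
    expect_equal(tr$mrna[nrow(tr)], sol$achieved_ss$mrna,
                 tolerance = 1e-4)
  }
})

test_that("production-side compensation is faster than degradation-side", {
  up <- required_fold_change("transcription", cold_rates(), warm_ss())
  down <- required_fold_change("mrna_degradation", cold_rates(), warm_ss(),
                               target_species = "protein")
  expect_lt(transition_time(up$adjusted_rates, "mrna"),
            transition_time(down$adjusted_rates, "mrna"))
})

test_that("the Pareto front trades cost against speed without dominated
           points", {
  pf <- pareto_front(cold_rates(), warm_ss(), "mrna", n_grid = 50)
  expect_equal(nrow(pf), 50)
  expect_equal(pf$up_factor[1], 1)
  expect_equal(pf$up_factor[50], 25)
  expect_equal(pf$up_factor * pf$down_factor, rep(25, 50))
  expect_true(all(diff(pf$up_factor) > 0))
  expect_true(all(diff(pf$tau) < 0))
  # boundary and midpoint values from the rate-sum formula
  expect_equal(pf$tau[50], 1 / (25 * 0.25 + 0.5))          # pure production
  expect_equal(pf$tau[1], 1 / (0.25 + 0.5 / 25))           # pure degradation
  pf3 <- pareto_front(cold_rates(), warm_ss(), "mrna", n_grid = 3)
  expect_equal(pf3$up_factor[2], 5)
  expect_equal(pf3$tau[2], 1 / 1.35)

  pfp <- pareto_front(cold_rates(), warm_ss(), "protein", n_grid = 50)
  expect_true(all(diff(pfp$tau) < 0))
  expect_equal(pfp$tau[50], 1 / (0.25 + 0.5 + 25 * 0.25 + 0.5))
})

test_that("pareto fronts round-trip through TSV", {
  pf <- pareto_front(cold_rates(), warm_ss(), "protein", n_grid = 10)
  path <- tempfile(fileext = ".tsv")
  write_pareto(pf, path)
  expect_identical(readLines(path, n = 1), "up_factor\tdown_factor\ttau")
  back <- utils::read.delim(path)
  expect_equal(back$tau, pf$tau, tolerance = 1e-12)
  unlink(path)
})
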