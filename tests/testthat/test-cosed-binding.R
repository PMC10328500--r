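test_that("solve_equilibrium: limits and bisection oracle", {
  expect_equal(solve_equilibrium(0, 2, 5), 0)
  # weak-binding limit: bound -> L S / K
  expect_equal(solve_equilibrium(12, 2, 1e9), 12 * 2 / 1e9, tolerance = 1e-6)
  # stoichiometric limit
  expect_equal(solve_equilibrium(2, 2, 1e-9), 2, tolerance = 1e-4)
  # the quoted example: L=12, S=2, K=5 vs bisection
  expect_equal(solve_equilibrium(12, 2, 5), oracle_bound_bisect(12, 2, 5),
               tolerance = 1e-10)
  expect_error(solve_equilibrium(-1, 2, 5), ">= 0")
  expect_error(solve_equilibrium(1, 2, 0), "> 0")
})

test_that("solve_competition: reduction, symmetry, conservation, monotonicity", {
  # no competitor reduces to solve_equilibrium
  r0 <- solve_competition(12, 5, 0, 1, 2)
  expect_equal(r0$boundA_uM, solve_equilibrium(12, 2, 5), tolerance = 1e-10)
  expect_equal(r0$boundB_uM, 0)
  # symmetric ligands bind equally
  rs <- solve_competition(6, 2, 6, 2, 2)
  expect_equal(rs$boundA_uM, rs$boundB_uM, tolerance = 1e-12)
  # conservation + fixed-point oracle across a parameter sweep
  set.seed(51)
  for (i in 1:20) {
    LA <- runif(1, 0, 15); LB <- runif(1, 0, 5)
    KA <- 10^runif(1, -2, 2); KB <- 10^runif(1, -2, 2)
    S <- runif(1, 0.5, 5)
    r <- solve_competition(LA, KA, LB, KB, S)
    expect_lt(abs(r$free_sites_uM + r$boundA_uM + r$boundB_uM - S), 1e-9)
    fp <- oracle_competition_nested(LA, KA, LB, KB, S)
    expect_equal(r$boundA_uM, fp$boundA, tolerance = 1e-6)
    expect_equal(r$boundB_uM, fp$boundB, tolerance = 1e-6)
  }
  # boundA nonincreasing in the competitor concentration
  bA <- vapply(seq(0, 2.59, length.out = 12), function(lb)
    solve_competition(12, 5, lb, 0.5, 2)$boundA_uM, 0)
  expect_true(all(diff(bA) <= 1e-12))
})

test_that("quantify_lane: trivial and analytic-Gaussian cases", {
  pos <- 1:200
  gauss <- function(mu, sd, area) area * dnorm(pos, mu, sd)
  wins <- list(supernatant = c(1, 100), pellet = c(101, 200))
  # all signal in supernatant
  p_sup <- gel_lane_profile(pos, gauss(50, 5, 2), band_windows = wins)
  expect_equal(as.numeric(quantify_lane(p_sup)), 0, tolerance = 1e-6)
  # areas 1 (sup) and 3 (pellet) -> 0.75
  p_mix <- gel_lane_profile(pos, gauss(50, 5, 1) + gauss(150, 5, 3),
                            band_windows = wins)
  expect_equal(as.numeric(quantify_lane(p_mix)), 0.75, tolerance = 1e-3)
  # peak auto-detection agrees with explicit windows
  p_auto <- gel_lane_profile(pos, gauss(50, 5, 1) + gauss(150, 5, 3))
  expect_equal(as.numeric(quantify_lane(p_auto)), 0.75, tolerance = 1e-3)
  # error contracts
  overlap <- list(supernatant = c(1, 120), pellet = c(100, 200))
  expect_error(quantify_lane(gel_lane_profile(pos, gauss(50, 5, 1),
                                              band_windows = overlap)),
               "overlap")
  expect_error(quantify_lane(gel_lane_profile(pos, rep(0, 200),
                                              band_windows = wins)),
               "S \\+ P")
})

test_that("gel round-trip: noiseless lanes reproduce the truth series", {
  g <- generate_gel(synth_gel_params(kd_uM = 5, site_conc_uM = 2,
                                     noise_sd_frac = 0))
  got <- vapply(g$lanes, function(l) as.numeric(quantify_lane(l)), 0)
  expect_equal(got, g$truth$fraction_bound, tolerance = 1e-3)
})

test_that("fit_binding: noiseless recovery, boundary flag, error contracts", {
  g <- generate_gel(synth_gel_params(kd_uM = 5, site_conc_uM = 2,
                                     noise_sd_frac = 0))
  fit <- fit_binding(g$truth, sites_total_uM = 2)
  expect_lt(abs(fit$kd_uM - 5) / 5, 0.01)
  expect_false(fit$at_boundary)
  # stoichiometric truth is not identifiable: flag the grid edge
  tight <- generate_gel(synth_gel_params(kd_uM = 1e-9, noise_sd_frac = 0))
  fit_t <- fit_binding(tight$truth, sites_total_uM = 2)
  expect_true(fit_t$at_boundary)
  # free-sites fit also recovers on clean data
  fit_s <- fit_binding(g$truth, sites_total_uM = 1, fix_sites = FALSE)
  expect_lt(abs(fit_s$kd_uM - 5) / 5, 0.05)
  expect_lt(abs(fit_s$sites_uM - 2) / 2, 0.05)
  expect_error(fit_binding(binding_series(c(1, 2, 3), c(.1, .2, .3)), 2),
               ">= 4")
  expect_error(fit_binding(binding_series(1:5, rep(0.5, 5)), 2),
               "degenerate")
})

test_that("fit_binding consistency: kd error shrinks as noise shrinks", {
  err_at <- function(noise) {
    errs <- vapply(1:8, function(s) {
      g <- generate_gel(synth_gel_params(kd_uM = 5, noise_sd_frac = noise,
                                         seed = 700 + s))
      got <- vapply(g$lanes, function(l) as.numeric(quantify_lane(l)), 0)
      fit <- fit_binding(binding_series(g$truth$titrant_uM, got), 2)
      abs(fit$kd_uM - 5) / 5
    }, 0)
    median(errs)
  }
  expect_lt(err_at(0.01), err_at(0.2) + 0.02)
  expect_lt(err_at(0.01), 0.05)
})

test_that("displacement_percent and the competition sweep", {
  expect_equal(displacement_percent(0.4, 0.4), 0)
  expect_equal(displacement_percent(0.4, 0.2), 50)
  expect_error(displacement_percent(0, 0.2), "> 0")
  # sweep mirrors a competition assay: ligand held at 12 uM, competitor
  # 0 -> 2.59 uM over shared 2 uM sites; displacement is monotone
  comp <- seq(0, 2.59, length.out = 8)
  base <- solve_competition(12, 5, 0, 0.5, 2)$boundA_uM / 12
  disp <- vapply(comp, function(cb)
    displacement_percent(base,
                         solve_competition(12, 5, cb, 0.5, 2)$boundA_uM / 12),
    0)
  expect_equal(disp[1], 0)
  expect_true(all(diff(disp) >= -1e-9))
})
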