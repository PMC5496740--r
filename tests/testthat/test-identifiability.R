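test_that("rates_from_pools reproduces the observed pools for any assumed flux", {
  r <- rates_from_pools(pool_state(3, 6), 12)
  expect_equal(r$beta, 4)
  expect_equal(r$gamma, 2)
  expect_equal(rates_from_pools(pool_state(3, 6), 24)$beta, 8)
  expect_equal(rates_from_pools(pool_state(3, 6), 6)$gamma, 1)
  expect_error(rates_from_pools(pool_state(0, 6), 12),
               class = "autoflux_undefined_ratio")
  expect_error(rates_from_pools(pool_state(3, 6), 0),
               class = "autoflux_invalid_parameter")
  # property: the reconstructed parameters hit the pools exactly, so the
  # pools never constrain the flux
  pools <- withr::with_seed(31, replicate(100, pool_state(runif(1, 0.1, 30),
                                                          runif(1, 0.1, 30)),
                                          simplify = FALSE))
  fluxes <- withr::with_seed(32, runif(100, 0.1, 50))
  for (i in seq_along(pools)) {
    r <- rates_from_pools(pools[[i]], fluxes[[i]])
    ss <- steady_state_pools(kinetic_params(r$assumed_flux, r$beta, r$gamma))
    expect_equal(ss$ap, pools[[i]]$ap, tolerance = 1e-14)
    expect_equal(ss$al, pools[[i]]$al, tolerance = 1e-14)
  }
})

test_that("scenario_table yields one valid row per flux, identical pools", {
  tab <- scenario_table(pool_state(3, 6), c(12, 24, 6))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$beta, c(4, 8, 2))
  expect_equal(tab$gamma, c(2, 4, 1))
  expect_true(all(tab$ap == 3 & tab$al == 6))
  expect_equal(nrow(scenario_table(pool_state(1, 2), 5)), 1)
  empty <- scenario_table(pool_state(1, 2), numeric())
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("assumed_flux", "beta", "gamma", "ap", "al"))
})

test_that("noise-free time-course data are recovered to optimizer tolerance", {
  truth <- kinetic_params(12, 4, 2)
  times <- c(0.25, 0.5, 1, 2, 4, 8)
  # 400 animals per time point approximates the zero-noise limit
  rec <- simulate_relaxation_counts(truth, n_animals = 400, times = times,
                                    seed = 77)
  fit <- fit_timecourse(rec, kinetic_params(5, 1, 1), n_starts = 3, seed = 1)
  est <- tidy(fit)$estimate
  expect_true(fit$converged)
  expect_equal(est, c(12, 4, 2), tolerance = 0.05)
  expect_true(all(tidy(fit)$std.error > 0))
})

test_that("least-squares cross-check agrees with the Poisson fit on rich data", {
  truth <- kinetic_params(12, 4, 2)
  rec <- simulate_relaxation_counts(truth, n_animals = 200,
                                    times = c(0.25, 0.5, 1, 2, 4, 8), seed = 5)
  f1 <- fit_timecourse(rec, kinetic_params(5, 1, 1), n_starts = 2, seed = 1)
  f2 <- fit_timecourse(rec, kinetic_params(5, 1, 1), n_starts = 2, seed = 1,
                       method = "ls")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 0.1)
})

test_that("estimates tighten as the number of animals grows", {
  truth <- kinetic_params(12, 4, 2)
  times <- c(0.25, 0.5, 1, 2, 4, 8)
  err_at <- function(n) {
    errs <- sapply(1:12, function(i) {
      rec <- simulate_relaxation_counts(truth, n, times, seed = 300 + i)
      est <- tidy(fit_timecourse(rec, kinetic_params(5, 1, 1),
                                 n_starts = 1, seed = i))$estimate
      mean(abs(est - c(12, 4, 2)) / c(12, 4, 2))
    })
    median(errs)
  }
  e <- c(err_at(10), err_at(100))
  expect_lt(e[2], e[1])
})

test_that("fit input contracts are enforced", {
  truth <- kinetic_params(12, 4, 2)
  rec <- simulate_relaxation_counts(truth, 5, c(0.5, 1), seed = 1)
  expect_error(fit_timecourse(rec, truth), ">= 3 distinct time points")
  rec2 <- simulate_relaxation_counts(truth, 5, c(0.5, 1, 2), seed = 1)
  expect_error(fit_timecourse(dplyr::filter(rec2, vesicle == "AP"), truth),
               "both AP and AL")
})

test_that("profile likelihood over flux is flat on steady-state-only data", {
  truth <- kinetic_params(12, 4, 2)
  counts <- simulate_steady_state_counts(truth, n_animals = 30, seed = 41)
  prof <- profile_flux_loglik(counts, flux_grid = c(6, 12, 24, 48))
  expect_lt(diff(range(prof$loglik)), 1e-4)
  # but curved on relaxation data, where the flux is identified
  rec <- simulate_relaxation_counts(truth, 30, c(0.25, 0.5, 1, 2, 4, 8),
                                    seed = 42)
  prof2 <- profile_flux_loglik(rec, flux_grid = c(6, 12, 24),
                               known_init = pool_state(0, 0))
  expect_gt(diff(range(prof2$loglik)), 10)
  expect_equal(prof2$flux[which.max(prof2$loglik)], 12)
})

test_that("tidy and glance expose the fit in broom form", {
  rec <- simulate_relaxation_counts(kinetic_params(12, 4, 2), 30,
                                    c(0.25, 0.5, 1, 2, 4, 8), seed = 9)
  fit <- fit_timecourse(rec, kinetic_params(5, 1, 1), n_starts = 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_identical(td$term, c("influx", "beta", "gamma"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_identical(gl$n_obs, nrow(rec))
})
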