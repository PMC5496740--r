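test_that("fold-change inference is inverse to the pool change", {
  pert <- infer_rate_fold_changes(pool_state(1, 1), pool_state(3, 2))
  expect_equal(pert$f_beta, 1 / 3)
  expect_equal(pert$f_gamma, 1 / 2)
  same <- infer_rate_fold_changes(pool_state(2, 5), pool_state(2, 5))
  expect_equal(same$f_beta, 1)
  expect_equal(same$f_gamma, 1)
  expect_error(infer_rate_fold_changes(pool_state(0, 1), pool_state(1, 1)),
               class = "autoflux_undefined_ratio")
})

test_that("apply_perturbation scales the rate constants and keeps the influx", {
  p <- kinetic_params(12, 4, 2)
  expect_equal(apply_perturbation(p, perturbation(1, 1)), p)
  p2 <- apply_perturbation(p, perturbation(1 / 3, 1 / 2))
  expect_equal(p2$influx, 12)
  expect_equal(p2$beta, 4 / 3)
  expect_equal(p2$gamma, 1)
  ss <- steady_state_pools(p2)
  expect_equal(ss$ap, 9)
  expect_equal(ss$al, 12)
})

test_that("perturb-then-infer round-trip is the identity over sampled cases", {
  params <- rand_params(200, seed = 21)
  perts <- rand_perturbations(200, seed = 22)
  for (i in seq_along(params)) {
    ctrl <- steady_state_pools(params[[i]])
    trt <- steady_state_pools(apply_perturbation(params[[i]], perts[[i]]))
    rec <- infer_rate_fold_changes(ctrl, trt)
    expect_equal(rec$f_beta, perts[[i]]$f_beta, tolerance = 1e-12)
    expect_equal(rec$f_gamma, perts[[i]]$f_gamma, tolerance = 1e-12)
  }
  # a known BafA-like washout case recovers exactly
  ctrl <- steady_state_pools(kinetic_params(12, 4, 2))
  trt <- steady_state_pools(
    apply_perturbation(kinetic_params(12, 4, 2), perturbation(1 / 1.5, 1 / 4)))
  rec <- infer_rate_fold_changes(ctrl, trt)
  expect_equal(rec$f_beta, 1 / 1.5)
  expect_equal(rec$f_gamma, 1 / 4)
})

test_that("reducing beta can only raise the AP pool", {
  fs <- withr::with_seed(23, runif(200, 0.05, 0.999))
  ps <- rand_params(200, seed = 23)
  for (i in seq_along(fs)) {
    p <- ps[[i]]
    f <- fs[[i]]
    ap0 <- steady_state_pools(p)$ap
    ap1 <- steady_state_pools(apply_perturbation(p, perturbation(f, 1)))$ap
    expect_gt(ap1, ap0)
  }
})

test_that("change_call thresholds at alpha and follows the ratio sign", {
  expect_identical(change_call(3, p_value = 0.5)$direction, "none")
  expect_identical(change_call(3, p_value = 0.001)$direction, "increase")
  expect_identical(change_call(0.4, p_value = 0.001)$direction, "decrease")
  # direction is "none" iff p >= alpha
  expect_identical(change_call(2, p_value = 0.01, alpha = 0.01)$direction, "none")
  expect_identical(change_call(2, p_value = 0.0099, alpha = 0.01)$direction,
                   "increase")
})

test_that("the full 3x3 classifier truth table matches the decision logic", {
  dirs <- c("increase", "decrease", "none")
  expected_status <- function(ap, al) {
    if (ap == "none" && al == "none") "blocked" else "active"
  }
  expected_pattern <- function(ap, al) {
    if (ap == "none" && al == "none") return("not_applicable")
    if (ap == "increase" && al == "decrease") return("complete")
    if (ap == "increase" && al == "increase") return("partial")
    "other"
  }
  for (ap in dirs) {
    for (al in dirs) {
      got <- classify_flux(ap, al)
      expect_identical(got$status, expected_status(ap, al))
      expect_identical(got$inhibition_pattern, expected_pattern(ap, al))
    }
  }
  # blocked implies the pattern is not applicable, by construction
  blocked <- classify_flux("none", "none")
  expect_identical(blocked$inhibition_pattern, "not_applicable")
})

test_that("equilibration diagnostic flags slow regimes and passes fast ones", {
  fast <- equilibration_fraction(kinetic_params(12, 8, 6),
                                 perturbation(1 / 3, 1 / 2), t = 2)
  expect_true(all(fast$equilibrated))
  slow <- equilibration_fraction(kinetic_params(12, 0.4, 0.2),
                                 perturbation(1 / 3, 1 / 2), t = 2)
  expect_false(all(slow$equilibrated))
  expect_true(all(fast$fraction >= 0 & fast$fraction <= 1))
})

test_that("flux_assay classifies an active cell and a blocked genotype correctly", {
  cfg <- generator_config(n_animals_per_cell = 40)
  active <- generate_flux_assay(cfg, "WT", "intestine", 1, seed = 101)
  res_a <- flux_assay(active)
  expect_s3_class(res_a, "flux_assay_result")
  expect_identical(res_a$status, "active")
  expect_identical(res_a$inhibition_pattern, "partial")

  blocked <- generate_flux_assay(cfg, "cst-1", "seam_cells", 1, seed = 102)
  res_b <- flux_assay(blocked)
  expect_identical(res_b$status, "blocked")
  expect_identical(res_b$inhibition_pattern, "not_applicable")
})

test_that("flux_assay validates its input schema", {
  cfg <- generator_config(n_animals_per_cell = 5)
  rec <- generate_flux_assay(cfg, "WT", "muscle", 3, seed = 1)
  expect_error(flux_assay(dplyr::select(rec, -count)), "missing columns")
  expect_error(flux_assay(dplyr::filter(rec, treatment == "control")),
               "No 'bafa' arm")
})
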