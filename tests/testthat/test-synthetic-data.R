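test_that("the generator is deterministic given a seed", {
  cfg <- generator_config(n_animals_per_cell = 10)
  a <- generate_count_dataset(cfg, seed = 61)
  b <- generate_count_dataset(cfg, seed = 61)
  expect_identical(a, b)
  c <- generate_count_dataset(cfg, seed = 62)
  expect_false(identical(a, c))
})

test_that("counts follow the configured means with Poisson marginals", {
  # zero means give all-zero counts
  zero <- generator_config(
    mean_trajectories = tibble::tibble(
      genotype = "WT", tissue = "intestine", vesicle = c("AP", "AL"),
      day = 1, mean = 0),
    n_animals_per_cell = 50)
  expect_true(all(generate_count_dataset(zero, seed = 1)$count == 0))

  # CLT bound on the sample mean at mean 5, n = 10000
  cfg <- generator_config(
    mean_trajectories = tibble::tibble(
      genotype = "WT", tissue = "intestine", vesicle = c("AP", "AL"),
      day = 1, mean = 5),
    n_animals_per_cell = 10000)
  d <- generate_count_dataset(cfg, seed = 63)
  m <- mean(d$count[d$vesicle == "AP"])
  expect_lt(abs(m - 5), 3 * sqrt(5 / 10000))
  # variance/mean ratio near 1 (Poisson marginals)
  vm <- var(d$count[d$vesicle == "AP"]) / m
  expect_equal(vm, 1, tolerance = 0.1)
})

test_that("the negative-binomial dispersion knob produces overdispersion", {
  cfg <- generator_config(
    mean_trajectories = tibble::tibble(
      genotype = "WT", tissue = "intestine", vesicle = c("AP", "AL"),
      day = 1, mean = 5),
    n_animals_per_cell = 5000, dispersion = 2)
  d <- generate_count_dataset(cfg, seed = 64)
  x <- d$count[d$vesicle == "AP"]
  expect_gt(var(x) / mean(x), 2)
})

test_that("a missing design cell is reported by name", {
  cfg <- generator_config(n_animals_per_cell = 5)
  expect_error(
    generate_count_dataset(cfg, genotypes = "WT", tissues = "intestine",
                           days = 4, seed = 1),
    class = "autoflux_config_error")
  err <- tryCatch(
    generate_flux_assay(cfg, "WT", "intestine", 1, treatment = "nope"),
    error = function(e) conditionMessage(e))
  expect_match(err, "nope")
})

test_that("the default design covers the study layout", {
  cfg <- generator_config(n_animals_per_cell = 2)
  d <- generate_count_dataset(cfg, seed = 65)
  core <- dplyr::filter(d, genotype %in% c("WT", "daf-2", "glp-1"),
                        tissue != "seam_cells")
  expect_setequal(unique(core$genotype), c("WT", "daf-2", "glp-1"))
  expect_setequal(unique(core$tissue),
                  c("intestine", "muscle", "pharynx", "neurons"))
  expect_setequal(unique(core$day), c(1, 3, 5, 7, 10))
  expect_setequal(unique(core$vesicle), c("AP", "AL"))
  # Day 7 is omitted for neurons
  expect_false(any(core$tissue == "neurons" & core$day == 7))
  # (animal_id, vesicle) unique within the dataset
  expect_false(any(duplicated(d[c("animal_id", "vesicle")])))
})

test_that("flux-assay arms sit at the kinetic-model pools with truth attached", {
  cfg <- generator_config(n_animals_per_cell = 4000)
  rec <- generate_flux_assay(cfg, "WT", "intestine", 1, seed = 66)
  truth <- attr(rec, "truth")
  expect_equal(truth$f_beta, 1 / 3)
  expect_equal(truth$f_gamma, 1 / 2)
  arm_means <- rec |>
    dplyr::group_by(treatment, vesicle) |>
    dplyr::summarise(m = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = c(treatment, vesicle), values_from = m)
  # configured WT intestine Day 1 means: AP 2, AL 6; BafA arm at 3x AP, 2x AL
  expect_equal(arm_means$control_AP, 2, tolerance = 0.05)
  expect_equal(arm_means$bafa_AP, 6, tolerance = 0.05)
  expect_equal(arm_means$bafa_AL, 12, tolerance = 0.05)
  # recovery of the embedded perturbation from arm means
  rec_pert <- infer_rate_fold_changes(
    pool_state(arm_means$control_AP, arm_means$control_AL),
    pool_state(arm_means$bafa_AP, arm_means$bafa_AL))
  expect_equal(rec_pert$f_beta, 1 / 3, tolerance = 0.05)
  expect_equal(rec_pert$f_gamma, 1 / 2, tolerance = 0.05)
})

test_that("a fusion block observed mid-transient shows AP up, AL down", {
  cfg <- generator_config(n_animals_per_cell = 2000, observe_at = 2)
  rec <- generate_flux_assay(cfg, "WT", "intestine", 1,
                             treatment = "rab7_rnai", seed = 67)
  m <- rec |>
    dplyr::group_by(treatment, vesicle) |>
    dplyr::summarise(m = mean(count), .groups = "drop")
  ap_ctrl <- m$m[m$treatment == "control" & m$vesicle == "AP"]
  ap_trt <- m$m[m$treatment == "rab7_rnai" & m$vesicle == "AP"]
  al_ctrl <- m$m[m$treatment == "control" & m$vesicle == "AL"]
  al_trt <- m$m[m$treatment == "rab7_rnai" & m$vesicle == "AL"]
  expect_gt(ap_trt, ap_ctrl * 1.2)
  expect_lt(al_trt, al_ctrl * 0.95)
})

test_that("colocalization draws respect the simplex and converge", {
  cfg <- generator_config()
  z <- generate_colocalization(0, cfg, seed = 1)
  expect_identical(unlist(z), c(gfp = 0L, lysotracker = 0L, neither = 0L))
  all_gfp <- generate_colocalization(
    500, generator_config(coloc_fractions = c(1, 0, 0)), seed = 2)
  expect_identical(all_gfp$gfp, 500L)
  big <- generate_colocalization(1e6, cfg, seed = 3)
  props <- unlist(big) / 1e6
  expect_lt(max(abs(props - c(0.10, 0.75, 0.15))), 0.005)
  expect_error(generate_colocalization(-1, cfg), "non-negative")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(coloc_fractions = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(generator_config(n_animals_per_cell = 0), ">= 1")
  expect_error(generator_config(dispersion = -1), "positive")
  tr <- default_mean_trajectories()
  tr$mean[1] <- -1
  expect_error(generator_config(mean_trajectories = tr), ">= 0")
})
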