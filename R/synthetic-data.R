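#' Default per-day mean count trajectories
#'
#' Expected AP and AL counts per observation unit, by genotype, tissue,
#' vesicle type and adult day. The shapes loosely follow the described trends
#' of the study design the generator emulates — AP pools rising with age in
#' all wild-type tissues (most steeply in muscle), ALs more abundant than APs
#' and plateauing after early adulthood, neuronal ALs declining, long-lived
#' mutants starting from elevated AP pools — but they are configuration data,
#' not assertions about any real measurement.
#'
#' @return A tibble with columns `genotype`, `tissue`, `vesicle`, `day`,
#'   `mean`.
#' @examples
#' default_mean_trajectories()
#' @export
default_mean_trajectories <- function() {
  days <- c(1, 3, 5, 7, 10)
  traj <- function(genotype, tissue, vesicle, means) {
    tibble::tibble(genotype = genotype, tissue = tissue, vesicle = vesicle,
                   day = days, mean = means)
  }
  dplyr::bind_rows(
    # wild type: AP up with age everywhere; muscle steepest (~15-fold);
    # ALs > APs, rising early then flat; neuronal ALs decline
    traj("WT", "intestine", "AP", c(2, 4, 6, 8, 10)),
    traj("WT", "intestine", "AL", c(6, 9, 10, 10, 10)),
    traj("WT", "muscle",    "AP", c(1, 3, 6, 10, 15)),
    traj("WT", "muscle",    "AL", c(4, 7, 8, 8, 8)),
    traj("WT", "pharynx",   "AP", c(2, 3, 5, 7, 9)),
    traj("WT", "pharynx",   "AL", c(5, 8, 9, 9, 9)),
    traj("WT", "neurons",   "AP", c(2, 3, 4, 5, 6)),
    traj("WT", "neurons",   "AL", c(6, 5, 4, 3, 2)),
    # daf-2: elevated AP/AL in intestine and muscle, late AL excess over WT
    traj("daf-2", "intestine", "AP", c(4, 6, 7, 8, 8)),
    traj("daf-2", "intestine", "AL", c(8, 10, 12, 13, 14)),
    traj("daf-2", "muscle",    "AP", c(3, 5, 7, 9, 11)),
    traj("daf-2", "muscle",    "AL", c(6, 9, 10, 10, 10)),
    traj("daf-2", "pharynx",   "AP", c(2, 3, 5, 7, 8)),
    traj("daf-2", "pharynx",   "AL", c(7, 8, 9, 9, 8)),
    traj("daf-2", "neurons",   "AP", c(4, 4, 3, 3, 2)),
    traj("daf-2", "neurons",   "AL", c(4, 5, 6, 7, 8)),
    # glp-1: elevated intestinal APs, generally lower ALs
    traj("glp-1", "intestine", "AP", c(4, 6, 7, 8, 9)),
    traj("glp-1", "intestine", "AL", c(4, 6, 7, 7, 8)),
    traj("glp-1", "muscle",    "AP", c(3, 4, 6, 9, 13)),
    traj("glp-1", "muscle",    "AL", c(3, 4, 4, 4, 4)),
    traj("glp-1", "pharynx",   "AP", c(2, 3, 5, 6, 8)),
    traj("glp-1", "pharynx",   "AL", c(3, 4, 5, 6, 6)),
    traj("glp-1", "neurons",   "AP", c(4, 4, 4, 5, 5)),
    traj("glp-1", "neurons",   "AL", c(4, 4, 4, 4, 4)),
    # seam cells fuse shortly after Day 1, so they exist only at Day 1;
    # cst-1 mutants carry a genetic block with elevated baseline APs
    tibble::tibble(genotype = c("WT", "WT", "cst-1", "cst-1"),
                   tissue = "seam_cells",
                   vesicle = c("AP", "AL", "AP", "AL"),
                   day = 1, mean = c(3, 5, 6, 5))
  )
}

#' Configuration of the synthetic puncta-count generator
#'
#' Bundles everything the generator needs: per-day mean trajectories for each
#' (genotype, tissue, vesicle), treatment effects expressed as rate-constant
#' perturbations, the per-cell sample size, colocalization fractions for the
#' tandem-reporter validation (mCherry with GFP, with LysoTracker, or with
#' neither), and an optional negative-binomial dispersion.
#'
#' Defaults emulate the design the package models: adult days 1, 3, 5, 7 and
#' 10; 30 animals per design cell; colocalization fractions (0.10, 0.75,
#' 0.15); BafA as a (1/3, 1/2) perturbation of (beta, gamma); rab-7 RNAi as a
#' fusion block (beta scaled by 0.2, gamma unchanged); Day 7 dropped for
#' neurons; cst-1 treated as a genotype with fully blocked flux (treatments
#' leave its pools unchanged).
#'
#' @param mean_trajectories Tibble of per-day means (see
#'   [default_mean_trajectories()]).
#' @param perturbation_effects Named list mapping treatment names to
#'   [perturbation()] objects; `"control"` must map to `perturbation(1, 1)`.
#' @param n_animals_per_cell Animals per (genotype, tissue, day, treatment)
#'   cell (>= 1; default 30).
#' @param coloc_fractions Length-3 non-negative vector summing to 1: fractions
#'   of mCherry-positive punctae co-localized with GFP, with LysoTracker, or
#'   with neither.
#' @param dispersion `NULL` (default) for pure Poisson counts, or a positive
#'   negative-binomial size parameter adding animal-to-animal overdispersion
#'   (variance `mu + mu^2 / dispersion`).
#' @param blocked_genotypes Genotypes with a genetic block in autophagy:
#'   rate-constant perturbations have no effect on their pools.
#' @param drop_neuron_day7 Drop the Day 7 neurons cell from the design
#'   (default TRUE).
#' @param observe_at Time (in hours) after treatment at which treated pools
#'   are observed: `Inf` (default) places treated arms at their new steady
#'   state; a finite value samples the closed-form transient instead, which
#'   is how a fusion block can show the AP-up/AL-down pattern.
#' @param assumed_flux Flux used to back out per-cell rate constants from the
#'   control means when evaluating treated pools at a finite `observe_at`
#'   (irrelevant at `observe_at = Inf`).
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_animals_per_cell = 20)
#' @export
generator_config <- function(mean_trajectories = default_mean_trajectories(),
                             perturbation_effects = list(
                               control = perturbation(1, 1),
                               bafa = perturbation(1 / 3, 1 / 2),
                               rab7_rnai = perturbation(0.2, 1)
                             ),
                             n_animals_per_cell = 30,
                             coloc_fractions = c(gfp = 0.10,
                                                 lysotracker = 0.75,
                                                 neither = 0.15),
                             dispersion = NULL,
                             blocked_genotypes = c("cst-1", "atg-mutant"),
                             drop_neuron_day7 = TRUE,
                             observe_at = Inf,
                             assumed_flux = 12) {
  mean_trajectories <- tibble::as_tibble(mean_trajectories)
  needed <- c("genotype", "tissue", "vesicle", "day", "mean")
  if (!all(needed %in% names(mean_trajectories))) {
    abort(sprintf("`mean_trajectories` needs columns: %s",
                  paste(needed, collapse = ", ")))
  }
  if (any(mean_trajectories$mean < 0)) {
    abort("All trajectory means must be >= 0.")
  }
  stopifnot(length(coloc_fractions) == 3L, all(coloc_fractions >= 0))
  if (abs(sum(coloc_fractions) - 1) > 1e-8) {
    abort("`coloc_fractions` must sum to 1.")
  }
  if (n_animals_per_cell < 1) abort("`n_animals_per_cell` must be >= 1.")
  if (!is.null(dispersion) && (!is.numeric(dispersion) || dispersion <= 0)) {
    abort("`dispersion` must be NULL or a positive number.")
  }
  perturbation_effects <- purrr::map(perturbation_effects, as_perturbation)
  if (is.null(perturbation_effects$control)) {
    perturbation_effects$control <- perturbation(1, 1)
  }
  structure(
    list(mean_trajectories = mean_trajectories,
         perturbation_effects = perturbation_effects,
         n_animals_per_cell = as.integer(n_animals_per_cell),
         coloc_fractions = coloc_fractions,
         dispersion = dispersion,
         blocked_genotypes = blocked_genotypes,
         drop_neuron_day7 = isTRUE(drop_neuron_day7),
         observe_at = observe_at,
         assumed_flux = assumed_flux),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  design cells: %d trajectory rows, %d animals per cell\n",
              nrow(x$mean_trajectories), x$n_animals_per_cell))
  cat(sprintf("  treatments: %s\n",
              paste(names(x$perturbation_effects), collapse = ", ")))
  cat(sprintf("  counts: %s\n",
              if (is.null(x$dispersion)) "Poisson"
              else sprintf("negative binomial (size %g)", x$dispersion)))
  invisible(x)
}

# Expected (AP, AL) means for one design cell under a treatment.
# Control means come straight from the trajectory table; treated means follow
# the kinetic model: back out per-cell parameters from the control pools
# under the configured assumed flux, apply the perturbation, and read the
# pools at the new steady state (observe_at = Inf) or along the transient.
cell_means <- function(config, genotype, tissue, day, treatment) {
  tr <- config$mean_trajectories
  pick <- function(ves) {
    m <- tr$mean[tr$genotype == genotype & tr$tissue == tissue &
                   tr$vesicle == ves & tr$day == day]
    if (length(m) != 1L) {
      abort(sprintf(
        "No mean trajectory configured for cell (%s, %s, %s, day %s).",
        genotype, tissue, ves, day), class = "autoflux_config_error")
    }
    m
  }
  ap0 <- pick("AP"); al0 <- pick("AL")
  pert <- config$perturbation_effects[[treatment]]
  if (is.null(pert)) {
    abort(sprintf("No perturbation configured for treatment '%s'.", treatment),
          class = "autoflux_config_error")
  }
  blocked <- genotype %in% config$blocked_genotypes
  if (blocked || (pert$f_beta == 1 && pert$f_gamma == 1)) {
    return(c(AP = ap0, AL = al0))
  }
  if (ap0 <= 0 || al0 <= 0) {
    # no vesicles to perturb; treated means equal control means
    return(c(AP = ap0, AL = al0))
  }
  base <- rates_from_pools(pool_state(ap0, al0), config$assumed_flux)
  params <- kinetic_params(base$assumed_flux, base$beta, base$gamma)
  perturbed <- apply_perturbation(params, pert)
  if (is.infinite(config$observe_at)) {
    ss <- steady_state_pools(perturbed)
    c(AP = ss$ap, AL = ss$al)
  } else {
    tr2 <- closed_form_timecourse(perturbed, pool_state(ap0, al0),
                                  times = config$observe_at)
    c(AP = tr2$ap, AL = tr2$al)
  }
}

draw_counts <- function(n, mean, dispersion) {
  if (mean <= 0) return(rep(0L, n))
  if (is.null(dispersion)) {
    rpois(n, mean)
  } else {
    rnbinom(n, size = dispersion, mu = mean)
  }
}

design_cells <- function(config, genotypes = NULL, tissues = NULL,
                         days = NULL) {
  cells <- dplyr::distinct(config$mean_trajectories,
                           .data$genotype, .data$tissue, .data$day)
  if (!is.null(genotypes)) cells <- dplyr::filter(cells, .data$genotype %in% genotypes)
  if (!is.null(tissues)) cells <- dplyr::filter(cells, .data$tissue %in% tissues)
  if (!is.null(days)) cells <- dplyr::filter(cells, .data$day %in% days)
  if (config$drop_neuron_day7) {
    cells <- dplyr::filter(cells, !(.data$tissue == "neurons" & .data$day == 7))
  }
  cells
}

#' Generate a synthetic puncta-count dataset
#'
#' Draws independent Poisson (or negative-binomial, if a dispersion is
#' configured) counts for every (genotype, tissue, day, treatment, vesicle)
#' cell of the configured design, `n_animals_per_cell` animals per cell.
#' Control means follow the configured trajectories; treated means follow the
#' kinetic model via [apply_perturbation()] on the per-cell implied
#' parameters. Fully reproducible given a seed.
#'
#' @param config A [generator_config()].
#' @param treatments Character vector of arms to generate (default
#'   `"control"`).
#' @param genotypes,tissues,days Optional design filters (default: every cell
#'   present in the trajectory table).
#' @param seed Integer seed; the same config and seed yield the identical
#'   table.
#' @return A tibble of count records: `animal_id`, `genotype`, `tissue`,
#'   `day`, `treatment`, `vesicle`, `count`.
#' @examples
#' cfg <- generator_config(n_animals_per_cell = 5)
#' generate_count_dataset(cfg, seed = 1)
#' @export
generate_count_dataset <- function(config, treatments = "control",
                                   genotypes = NULL, tissues = NULL,
                                   days = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cells <- design_cells(config, genotypes, tissues, days)
  if (nrow(cells) == 0L) {
    abort("No design cells match the requested genotypes/tissues/days.",
          class = "autoflux_config_error")
  }
  gen <- function() {
    purrr::pmap_dfr(cells, function(genotype, tissue, day) {
      purrr::map_dfr(treatments, function(trt) {
        mus <- cell_means(config, genotype, tissue, day, trt)
        n <- config$n_animals_per_cell
        ids <- sprintf("%s_%s_d%02d_%s_%03d", genotype, tissue, day, trt,
                       seq_len(n))
        purrr::map_dfr(c("AP", "AL"), function(ves) {
          tibble::tibble(
            animal_id = ids, genotype = genotype, tissue = tissue,
            day = day, treatment = trt, vesicle = ves,
            count = as.integer(draw_counts(n, mus[[ves]], config$dispersion))
          )
        })
      })
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a paired control/BafA flux-assay dataset
#'
#' One design cell, two arms: the control arm at the configured baseline
#' means and the treated arm at the kinetic-model pools under the configured
#' perturbation (new steady state by default). The ground-truth perturbation
#' actually applied (identity for genetically blocked genotypes) is attached
#' as the `"truth"` attribute for recovery tests.
#'
#' @param config A [generator_config()].
#' @param genotype,tissue,day The design cell.
#' @param treatment Treated arm name (default `"bafa"`).
#' @param seed Integer seed.
#' @return A tibble of paired count records with attribute `"truth"` (a
#'   [perturbation()]).
#' @examples
#' cfg <- generator_config(n_animals_per_cell = 10)
#' rec <- generate_flux_assay(cfg, "WT", "intestine", 1, seed = 1)
#' attr(rec, "truth")
#' @export
generate_flux_assay <- function(config, genotype, tissue, day,
                                treatment = "bafa", seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$perturbation_effects[[treatment]])) {
    abort(sprintf("No perturbation configured for treatment '%s'.", treatment),
          class = "autoflux_config_error")
  }
  out <- generate_count_dataset(config, treatments = c("control", treatment),
                                genotypes = genotype, tissues = tissue,
                                days = day, seed = seed)
  truth <- if (genotype %in% config$blocked_genotypes) {
    perturbation(1, 1)
  } else {
    config$perturbation_effects[[treatment]]
  }
  attr(out, "truth") <- truth
  out
}

#' Generate colocalization counts for mCherry-positive punctae
#'
#' Multinomial draw over the configured fractions of mCherry-positive punctae
#' co-localized with GFP (APs), with LysoTracker (acidic ALs), or with
#' neither.
#'
#' @param n_punctae Total number of mCherry-positive punctae (>= 0).
#' @param config A [generator_config()] (only `coloc_fractions` is used).
#' @param seed Integer seed.
#' @return A one-row tibble with integer columns `gfp`, `lysotracker`,
#'   `neither` summing to `n_punctae`.
#' @examples
#' generate_colocalization(1000, generator_config(), seed = 1)
#' @export
generate_colocalization <- function(n_punctae, config = generator_config(),
                                    seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(n_punctae) || length(n_punctae) != 1L || n_punctae < 0 ||
      n_punctae != round(n_punctae)) {
    abort("`n_punctae` must be a single non-negative integer.")
  }
  draw <- function() {
    if (n_punctae == 0) {
      counts <- c(0L, 0L, 0L)
    } else {
      counts <- as.integer(rmultinom(1, size = n_punctae,
                                     prob = config$coloc_fractions))
    }
    tibble::tibble(gfp = counts[1], lysotracker = counts[2],
                   neither = counts[3])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate Poisson counts along a relaxation time course
#'
#' Convenience generator for fitting experiments: the deterministic
#' closed-form trajectory from `init` is sampled at `times`, and
#' `n_animals` independent Poisson counts per vesicle type are drawn around
#' each time point.
#'
#' @param params True [kinetic_params()].
#' @param n_animals Animals per time point.
#' @param times Observation times (strictly increasing, > 0 recommended).
#' @param init Initial [pool_state()] (default vesicle-free).
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `animal`, `vesicle`, `count`.
#' @examples
#' simulate_relaxation_counts(kinetic_params(12, 4, 2), n_animals = 5,
#'                            times = c(0.5, 1, 2), seed = 1)
#' @export
simulate_relaxation_counts <- function(params, n_animals, times,
                                       init = pool_state(0, 0), seed = NULL) {
  params <- as_kinetic_params(params)
  init <- as_pool_state(init)
  times <- check_times(times)
  traj <- closed_form_timecourse(params, init, times)
  gen <- function() {
    purrr::pmap_dfr(traj, function(time, ap, al) {
      tibble::tibble(
        time = time,
        animal = rep(seq_len(n_animals), 2L),
        vesicle = rep(c("AP", "AL"), each = n_animals),
        count = c(rpois(n_animals, ap), rpois(n_animals, al))
      )
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate Poisson counts at steady state
#'
#' Counts drawn around the steady-state pools of `params`; useful for
#' demonstrating that steady-state-only data leave the flux unidentified.
#'
#' @param params True [kinetic_params()].
#' @param n_animals Animals observed.
#' @param seed Integer seed.
#' @return A tibble with columns `time` (0), `animal`, `vesicle`, `count`.
#' @export
simulate_steady_state_counts <- function(params, n_animals, seed = NULL) {
  params <- as_kinetic_params(params)
  ss <- steady_state_pools(params)
  gen <- function() {
    tibble::tibble(
      time = 0,
      animal = rep(seq_len(n_animals), 2L),
      vesicle = rep(c("AP", "AL"), each = n_animals),
      count = c(rpois(n_animals, ss$ap), rpois(n_animals, ss$al))
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
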