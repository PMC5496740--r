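#' Rate constants consistent with fixed pools under an assumed flux
#'
#' Steady-state pools alone do not determine flux: for any assumed flux
#' \eqn{J > 0} and observed pools \eqn{([AP], [AL])}, the rate constants
#' \eqn{\beta = J/[AP]} and \eqn{\gamma = J/[AL]} reproduce those pools
#' exactly. This is the algebra behind the demonstration that the same
#' steady-state measurements are consistent with unchanged, doubled or halved
#' flux.
#'
#' @param pools Observed steady-state [pool_state()] (both pools > 0).
#' @param assumed_flux Assumed flux (> 0), vesicles per unit time.
#' @return A one-row tibble with columns `assumed_flux`, `beta`, `gamma`,
#'   `ap`, `al`.
#' @examples
#' rates_from_pools(pool_state(3, 6), assumed_flux = 12) # beta 4, gamma 2
#' @export
rates_from_pools <- function(pools, assumed_flux) {
  pools <- as_pool_state(pools)
  stopifnot(is.numeric(assumed_flux), length(assumed_flux) == 1L)
  if (pools$ap <= 0 || pools$al <= 0) {
    abort("Both pools must be > 0 (rate constants undefined otherwise).",
          class = "autoflux_undefined_ratio")
  }
  if (!is.finite(assumed_flux) || assumed_flux <= 0) {
    abort("`assumed_flux` must be finite and > 0.",
          class = "autoflux_invalid_parameter")
  }
  tibble::tibble(assumed_flux = assumed_flux,
                 beta = assumed_flux / pools$ap,
                 gamma = assumed_flux / pools$al,
                 ap = pools$ap, al = pools$al)
}

#' Scenario table: one rate-constant pair per assumed flux
#'
#' Applies [rates_from_pools()] to a vector of assumed fluxes, producing the
#' non-identifiability ledger: every row is a distinct parameter triple whose
#' steady state reproduces the identical observed pools, so the pools place
#' no constraint on the flux.
#'
#' @param pools Observed steady-state [pool_state()].
#' @param fluxes Numeric vector of assumed fluxes (all > 0); the canonical
#'   demonstration uses unchanged, doubled and halved flux, e.g.
#'   `c(12, 24, 6)`.
#' @return A tibble with columns `assumed_flux`, `beta`, `gamma`, `ap`, `al`
#'   (zero rows for an empty `fluxes`).
#' @examples
#' scenario_table(pool_state(3, 6), c(12, 24, 6))
#' @export
scenario_table <- function(pools, fluxes = c(12, 24, 6)) {
  pools <- as_pool_state(pools)
  stopifnot(is.numeric(fluxes))
  if (length(fluxes) == 0L) {
    return(tibble::tibble(assumed_flux = numeric(), beta = numeric(),
                          gamma = numeric(), ap = numeric(), al = numeric()))
  }
  purrr::map_dfr(fluxes, function(f) rates_from_pools(pools, f))
}

# Poisson log-likelihood of count records around a deterministic trajectory.
# records: tibble with columns time, vesicle ("AP"/"AL"), count.
timecourse_loglik <- function(theta, records, init) {
  # theta on log scale: (log J, log beta, log gamma)
  p <- exp(theta)
  if (any(!is.finite(p))) return(-Inf)
  params <- list(influx = p[1], beta = p[2], gamma = p[3], time_unit = "hour")
  tt <- sort(unique(records$time))
  traj <- closed_form_timecourse(
    kinetic_params(p[1], p[2], p[3]), init, times = tt)
  lam_ap <- traj$ap[match(records$time, traj$time)]
  lam_al <- traj$al[match(records$time, traj$time)]
  lam <- ifelse(records$vesicle == "AP", lam_ap, lam_al)
  lam <- pmax(lam, 1e-12)
  sum(dpois(records$count, lam, log = TRUE))
}

#' Fit the kinetic model to relaxation time-course counts
#'
#' Maximum-likelihood estimation of (J, beta, gamma) from out-of-steady-state
#' count data under a Poisson observation model around the deterministic
#' closed-form trajectory. Optimization runs on the log-parameter scale with
#' multiple starting points (the supplied guess plus jittered restarts, best
#' objective wins, ties broken by smallest parameter norm); standard errors
#' come from the observed-information inverse at the optimum, delta-mapped to
#' the natural scale.
#'
#' Steady-state-only data leave the flux direction identified only through
#' the absolute scale of the pools; such fits are reported with an
#' ill-conditioning warning rather than an error.
#'
#' @param records A data frame with columns `time`, `vesicle` (`"AP"`/`"AL"`)
#'   and `count`: one row per animal, vesicle and time point, with at least 3
#'   distinct time points covering both vesicle types.
#' @param init_guess Starting [kinetic_params()] for the optimizer.
#' @param known_init The known initial [pool_state()] of the relaxation
#'   (default: vesicle-free, `pool_state(0, 0)`).
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Integer seed controlling the jittered restarts (default 1).
#' @param method `"poisson"` (maximum likelihood, default) or `"ls"`
#'   (least squares on the per-time-point means, retained as a cross-check).
#' @return An object of class `flux_fit`: list with `estimate`
#'   (a `kinetic_params`), `stderr` (named numeric), `converged`, `objective`
#'   (negative log-likelihood or residual sum of squares), `n_obs`, and the
#'   per-start table `starts`. Use [tidy()] / [glance()] to extract results.
#' @examples
#' truth <- kinetic_params(12, 4, 2)
#' rec <- simulate_relaxation_counts(truth, n_animals = 30,
#'                                   times = c(0.25, 0.5, 1, 2, 4, 8),
#'                                   seed = 1)
#' fit <- fit_timecourse(rec, init_guess = kinetic_params(5, 1, 1))
#' tidy(fit)
#' @export
fit_timecourse <- function(records, init_guess,
                           known_init = pool_state(0, 0),
                           n_starts = 5, seed = 1,
                           method = c("poisson", "ls")) {
  method <- match.arg(method)
  if (!is.data.frame(records) ||
      !all(c("time", "vesicle", "count") %in% names(records))) {
    abort("`records` needs columns time, vesicle, count.")
  }
  records <- tibble::as_tibble(records)
  if (length(unique(records$time)) < 3L) {
    abort("Need counts at >= 3 distinct time points to fit (J, beta, gamma).")
  }
  if (!all(c("AP", "AL") %in% records$vesicle)) {
    abort("`records` must contain both AP and AL counts.")
  }
  init_guess <- as_kinetic_params(init_guess)
  known_init <- as_pool_state(known_init)

  objective <- if (method == "poisson") {
    function(theta) -timecourse_loglik(theta, records, known_init)
  } else {
    means <- records |>
      dplyr::group_by(.data$time, .data$vesicle) |>
      dplyr::summarise(m = mean(.data$count), .groups = "drop")
    function(theta) {
      p <- exp(theta)
      if (any(!is.finite(p))) return(Inf)
      traj <- closed_form_timecourse(kinetic_params(p[1], p[2], p[3]),
                                     known_init, sort(unique(means$time)))
      mu <- ifelse(means$vesicle == "AP",
                   traj$ap[match(means$time, traj$time)],
                   traj$al[match(means$time, traj$time)])
      sum((means$m - mu)^2)
    }
  }

  theta0 <- log(pmax(c(init_guess$influx, init_guess$beta, init_guess$gamma),
                     1e-6))
  starts <- withr::with_seed(seed, {
    s <- replicate(max(n_starts - 1L, 0L),
                   theta0 + stats::rnorm(3, sd = 0.75), simplify = FALSE)
    c(list(theta0), s)
  })

  runs <- purrr::map(starts, function(th) {
    tryCatch(
      optim(th, objective, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0L) {
    return(new_flux_fit(NULL, records, method, converged = FALSE))
  }
  vals <- purrr::map_dbl(runs, "value")
  best_val <- min(vals)
  # ties broken by smallest parameter norm
  tied <- which(vals - best_val < 1e-8)
  norms <- purrr::map_dbl(runs[tied], function(r) sqrt(sum(exp(r$par)^2)))
  best <- runs[tied][[which.min(norms)]]
  converged <- best$convergence == 0

  est <- exp(best$par)
  stderr <- c(influx = NA_real_, beta = NA_real_, gamma = NA_real_)
  ill_conditioned <- FALSE
  if (method == "poisson") {
    hess <- tryCatch(optimHess(best$par, objective), error = function(e) NULL)
    if (!is.null(hess)) {
      rc <- tryCatch(rcond(hess), error = function(e) 0)
      if (is.na(rc) || rc < 1e-10) {
        ill_conditioned <- TRUE
        warn(paste("Observed information is ill-conditioned; the data may be",
                   "at steady state, where flux is identified only through",
                   "the absolute pool scale."),
             class = "autoflux_ill_conditioned")
      } else {
        v <- tryCatch(solve(hess), error = function(e) NULL)
        if (!is.null(v) && all(diag(v) > 0)) {
          # delta method: se(exp(theta)) = exp(theta) * se(theta)
          stderr <- setNames(est * sqrt(diag(v)), c("influx", "beta", "gamma"))
        }
      }
    }
  }

  structure(
    list(
      estimate = kinetic_params(est[1], est[2], est[3]),
      stderr = stderr,
      converged = converged,
      objective = best$value,
      method = method,
      ill_conditioned = ill_conditioned,
      known_init = known_init,
      n_obs = nrow(records),
      starts = tibble::tibble(
        start = seq_along(runs),
        objective = vals,
        convergence = purrr::map_int(runs, "convergence")
      )
    ),
    class = "flux_fit"
  )
}

new_flux_fit <- function(est, records, method, converged) {
  structure(
    list(estimate = NULL, stderr = c(influx = NA_real_, beta = NA_real_,
                                     gamma = NA_real_),
         converged = converged, objective = NA_real_, method = method,
         ill_conditioned = NA, known_init = NULL,
         n_obs = nrow(records), starts = tibble::tibble()),
    class = "flux_fit"
  )
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit>", if (x$converged) "converged" else "NOT converged", "\n")
  if (!is.null(x$estimate)) {
    cat("  ", format(x$estimate), "\n", sep = "")
    cat(sprintf("  objective = %.4f on %d observations (%s)\n",
                x$objective, x$n_obs, x$method))
  }
  invisible(x)
}

#' @rdname fit_timecourse
#' @param x A `flux_fit` object.
#' @param ... Unused.
#' @method tidy flux_fit
#' @export
tidy.flux_fit <- function(x, ...) {
  if (is.null(x$estimate)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric()))
  }
  tibble::tibble(
    term = c("influx", "beta", "gamma"),
    estimate = c(x$estimate$influx, x$estimate$beta, x$estimate$gamma),
    std.error = unname(x$stderr[c("influx", "beta", "gamma")])
  )
}

#' @rdname fit_timecourse
#' @method glance flux_fit
#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    objective = x$objective,
    method = x$method,
    ill_conditioned = isTRUE(x$ill_conditioned),
    n_obs = x$n_obs,
    n_starts = nrow(x$starts)
  )
}

#' Profile log-likelihood of the flux on count data
#'
#' For each candidate flux J, maximizes the Poisson log-likelihood over
#' (beta, gamma) with J held fixed. On steady-state-only data the profile is
#' exactly flat — any J can be matched by co-scaling beta and gamma — which
#' is the likelihood face of the non-identifiability result; on relaxation
#' data the profile is curved and the flux is identified.
#'
#' @param records A data frame with columns `time`, `vesicle`, `count` (as in
#'   [fit_timecourse()]); steady-state-only data may use a single nominal
#'   time.
#' @param flux_grid Numeric vector of candidate fluxes (> 0).
#' @param known_init Initial [pool_state()] of the trajectory; for
#'   steady-state data use `NULL` (each flux is evaluated at its own steady
#'   state).
#' @return A tibble with columns `flux` and `loglik`.
#' @examples
#' cfg <- generator_config()
#' rec <- simulate_steady_state_counts(kinetic_params(12, 4, 2),
#'                                     n_animals = 30, seed = 1)
#' profile_flux_loglik(rec, flux_grid = c(6, 12, 24))
#' @export
profile_flux_loglik <- function(records, flux_grid, known_init = NULL) {
  stopifnot(is.numeric(flux_grid), all(flux_grid > 0))
  records <- tibble::as_tibble(records)
  if (!all(c("vesicle", "count") %in% names(records))) {
    abort("`records` needs columns vesicle and count.")
  }
  if (!"time" %in% names(records)) records$time <- 0

  steady_only <- is.null(known_init)
  purrr::map_dfr(flux_grid, function(J) {
    obj <- function(lbg) {
      b <- exp(lbg[1]); g <- exp(lbg[2])
      if (steady_only) {
        lam <- ifelse(records$vesicle == "AP", J / b, J / g)
      } else {
        traj <- closed_form_timecourse(kinetic_params(J, b, g), known_init,
                                       sort(unique(records$time)))
        lam <- ifelse(records$vesicle == "AP",
                      traj$ap[match(records$time, traj$time)],
                      traj$al[match(records$time, traj$time)])
      }
      -sum(dpois(records$count, pmax(lam, 1e-12), log = TRUE))
    }
    ap_bar <- max(mean(records$count[records$vesicle == "AP"]), 1e-6)
    al_bar <- max(mean(records$count[records$vesicle == "AL"]), 1e-6)
    start <- log(c(J / ap_bar, J / al_bar))
    opt <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    tibble::tibble(flux = J, loglik = -opt$value)
  })
}
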