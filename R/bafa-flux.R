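#' Multiplicative perturbation of the rate constants
#'
#' Bafilomycin A (BafA) blocks lysosomal acidification and is modelled as a
#' multiplicative reduction of both the AP-to-AL conversion rate constant
#' \eqn{\beta} and the AL degradation rate constant \eqn{\gamma}; a fusion
#' block such as rab-7 RNAi reduces \eqn{\beta} alone. The untreated control
#' is `perturbation(1, 1)`.
#'
#' @param f_beta Factor applied to beta (> 0).
#' @param f_gamma Factor applied to gamma (> 0).
#' @return An object of class `perturbation`.
#' @examples
#' perturbation(1 / 3, 1 / 2) # BafA-like
#' @export
perturbation <- function(f_beta, f_gamma) {
  stopifnot(is.numeric(f_beta), is.numeric(f_gamma),
            length(f_beta) == 1L, length(f_gamma) == 1L)
  if (!is.finite(f_beta) || f_beta <= 0 || !is.finite(f_gamma) || f_gamma <= 0) {
    abort("Perturbation factors must be finite and > 0.",
          class = "autoflux_invalid_parameter")
  }
  structure(list(f_beta = as.numeric(f_beta), f_gamma = as.numeric(f_gamma)),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf("<perturbation>  f_beta = %g, f_gamma = %g\n", x$f_beta, x$f_gamma))
  invisible(x)
}

as_perturbation <- function(x) {
  if (inherits(x, "perturbation")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(perturbation(x[[1]], x[[2]]))
  if (is.list(x) && all(c("f_beta", "f_gamma") %in% names(x))) {
    return(perturbation(x$f_beta, x$f_gamma))
  }
  abort("Cannot interpret input as a perturbation (need `f_beta`, `f_gamma`).")
}

#' Infer rate-constant fold-changes from paired steady-state pools
#'
#' Assuming the influx J is unchanged by the treatment and both conditions
#' are at steady state, \eqn{[AP] = J/\beta} in each arm, so the factor
#' applied to beta is inversely related to the change in AP number:
#' \deqn{f_\beta = \beta_{treated}/\beta_{control} = [AP]_{control}/[AP]_{treated},}
#' and likewise \eqn{f_\gamma = [AL]_{control}/[AL]_{treated}}. A threefold
#' AP increase and twofold AL increase under BafA therefore imply a
#' threefold decrease in beta and a twofold decrease in gamma.
#'
#' @param control Steady-state [pool_state()] of the control arm (pools > 0).
#' @param treated Steady-state [pool_state()] of the treated (e.g. BafA) arm.
#' @return A `perturbation` with the inferred factors.
#' @examples
#' infer_rate_fold_changes(pool_state(1, 1), pool_state(3, 2))
#' # f_beta = 1/3, f_gamma = 1/2
#' @export
infer_rate_fold_changes <- function(control, treated) {
  control <- as_pool_state(control)
  treated <- as_pool_state(treated)
  if (control$ap <= 0 || control$al <= 0 || treated$ap <= 0 || treated$al <= 0) {
    abort("All pool sizes must be > 0 to infer fold-changes (ratio undefined).",
          class = "autoflux_undefined_ratio")
  }
  perturbation(f_beta = control$ap / treated$ap,
               f_gamma = control$al / treated$al)
}

#' Apply a perturbation to kinetic parameters
#'
#' Returns new parameters with `beta` and `gamma` scaled by the perturbation
#' factors; the influx J is unchanged (treatments acting downstream of AP
#' formation do not alter it).
#'
#' @param params A [kinetic_params()] object.
#' @param pert A [perturbation()] object.
#' @return A `kinetic_params` object.
#' @examples
#' apply_perturbation(kinetic_params(12, 4, 2), perturbation(1 / 3, 1 / 2))
#' # J = 12, beta = 4/3, gamma = 1; new steady state (9, 12)
#' @export
apply_perturbation <- function(params, pert) {
  params <- as_kinetic_params(params)
  pert <- as_perturbation(pert)
  kinetic_params(params$influx, params$beta * pert$f_beta,
                 params$gamma * pert$f_gamma, time_unit = params$time_unit)
}

#' Statistical call on the direction of a pool-size change
#'
#' Wraps a rate ratio and p-value into a directional call: `"none"` when the
#' p-value is at or above the significance threshold, otherwise
#' `"increase"`/`"decrease"` by the sign of the log rate ratio.
#'
#' @param result A one-row data frame with columns `rate_ratio` and `p_value`
#'   (e.g. from [poisson_rate_ratio()]), or a numeric rate ratio.
#' @param alpha Significance threshold (default 0.01, the weakest reported
#'   significance tier of the assay this models).
#' @param p_value p-value, required when `result` is a bare rate ratio.
#' @return An object of class `change_call`: list with `direction`
#'   (`"increase"`, `"decrease"` or `"none"`), `p_value` and `rate_ratio`.
#' @examples
#' change_call(3, p_value = 0.001)
#' change_call(0.4, p_value = 0.5)
#' @export
change_call <- function(result, alpha = 0.01, p_value = NULL) {
  if (is.data.frame(result)) {
    stopifnot(nrow(result) == 1L)
    rr <- result$rate_ratio
    p <- result$p_value
  } else {
    rr <- as.numeric(result)
    p <- p_value
    if (is.null(p)) abort("`p_value` is required when `result` is a number.")
  }
  stopifnot(alpha > 0, alpha < 1)
  direction <- if (is.na(p) || p >= alpha) {
    "none"
  } else if (rr > 1) {
    "increase"
  } else {
    "decrease"
  }
  structure(list(direction = direction, p_value = p, rate_ratio = rr,
                 alpha = alpha),
            class = "change_call")
}

#' @export
print.change_call <- function(x, ...) {
  cat(sprintf("<change_call>  %s (rate ratio %.3g, p = %.3g)\n",
              x$direction, x$rate_ratio, x$p_value))
  invisible(x)
}

as_direction <- function(x) {
  if (inherits(x, "change_call")) return(x$direction)
  d <- as.character(x)
  if (!d %in% c("increase", "decrease", "none")) {
    abort("Direction must be one of 'increase', 'decrease', 'none'.")
  }
  d
}

#' Classify flux status from a paired BafA response
#'
#' Decision logic of the flux assay: no change in either the AP or AL pool
#' following BafA indicates a block in autophagy, while a change in either
#' pool is consistent with active autophagy. Active patterns are sub-labelled:
#' AP up with AL down is the signature of complete inhibition of lysosomal
#' acidification (GFP no longer quenched, so former ALs score as APs); AP up
#' with AL up is consistent with partial inhibition (reduced hydrolase
#' efficiency lets ALs accumulate too); any other active combination is
#' `"other"`.
#'
#' @param ap_call,al_call [change_call()] objects (or direction strings) for
#'   the AP and AL pools from the same paired experiment.
#' @return A tibble row with columns `status` (`"active"`/`"blocked"`) and
#'   `inhibition_pattern` (`"complete"`, `"partial"`, `"other"`, or
#'   `"not_applicable"` when blocked).
#' @examples
#' classify_flux("none", "none")        # blocked
#' classify_flux("increase", "decrease") # active / complete
#' classify_flux("increase", "increase") # active / partial
#' @export
classify_flux <- function(ap_call, al_call) {
  ap <- as_direction(ap_call)
  al <- as_direction(al_call)
  if (ap == "none" && al == "none") {
    status <- "blocked"
    pattern <- "not_applicable"
  } else {
    status <- "active"
    pattern <- if (ap == "increase" && al == "decrease") {
      "complete"
    } else if (ap == "increase" && al == "increase") {
      "partial"
    } else {
      "other"
    }
  }
  tibble::tibble(status = status, inhibition_pattern = pattern)
}

#' Fraction of BafA equilibration reached after a given time
#'
#' The flux assay reads out pools a fixed time (2 h) after treatment, on the
#' assumption that the perturbed system has reached its new steady state.
#' This diagnostic computes, per pool, how far along the relaxation from the
#' pre-treatment steady state towards the new steady state the system is at
#' time `t`, and flags regimes where the assumption fails.
#'
#' @param params Pre-treatment [kinetic_params()].
#' @param pert The applied [perturbation()].
#' @param t Readout time (default 2, in the parameter time unit).
#' @param threshold Minimum fraction considered equilibrated (default 0.95).
#' @return A tibble with columns `pool`, `fraction` (in \[0, 1\]) and
#'   `equilibrated`.
#' @examples
#' equilibration_fraction(kinetic_params(12, 4, 2), perturbation(1 / 3, 1 / 2))
#' @export
equilibration_fraction <- function(params, pert, t = 2, threshold = 0.95) {
  params <- as_kinetic_params(params)
  pert <- as_perturbation(pert)
  stopifnot(t > 0)
  p2 <- apply_perturbation(params, pert)
  start <- steady_state_pools(params)
  target <- steady_state_pools(p2)
  now <- closed_form_timecourse(p2, start, times = t)
  frac <- function(x0, xt, xi) {
    if (abs(xi - x0) < 1e-12) return(1)   # no change expected
    min(max(1 - abs(xt - xi) / abs(xi - x0), 0), 1)
  }
  tibble::tibble(
    pool = c("AP", "AL"),
    fraction = c(frac(start$ap, now$ap, target$ap),
                 frac(start$al, now$al, target$al)),
    equilibrated = .data$fraction >= threshold
  )
}

#' Run the paired control/BafA flux assay on a count table
#'
#' The tidy workhorse of the flux assay: takes animal-level puncta counts in
#' the standard record schema (`animal_id`, `tissue`, `day`, `genotype`,
#' `treatment`, `vesicle`, `count`), and for every (genotype, tissue, day)
#' cell compares the treated arm against control with a two-group Poisson
#' rate-ratio test per vesicle type, infers the rate-constant fold-changes
#' from the arm means, and classifies flux status from the BafA-response
#' pattern.
#'
#' @param records A data frame of count records containing a `"control"` arm
#'   and one treated arm.
#' @param alpha Significance threshold for the "no change" calls
#'   (default 0.01).
#' @param treatment Name of the treated arm (default `"bafa"`).
#' @return A tibble of class `flux_assay_result`, one row per
#'   (genotype, tissue, day), with rate ratios and p-values per vesicle,
#'   inferred `f_beta`/`f_gamma`, and the `status`/`inhibition_pattern`
#'   classification.
#' @examples
#' cfg <- generator_config(n_animals_per_cell = 30)
#' rec <- generate_flux_assay(cfg, genotype = "WT", tissue = "intestine",
#'                            day = 1, seed = 1)
#' flux_assay(rec)
#' @export
flux_assay <- function(records, alpha = 0.01, treatment = "bafa") {
  records <- validate_count_records(records)
  if (!treatment %in% records$treatment) {
    abort(sprintf("No '%s' arm present in `records`.", treatment))
  }
  if (!"control" %in% records$treatment) {
    abort("No 'control' arm present in `records`.")
  }
  records <- dplyr::filter(records, .data$treatment %in% c("control", !!treatment))

  one_cell <- function(cell) {
    per_vesicle <- function(ves) {
      a <- cell$count[cell$vesicle == ves & cell$treatment == "control"]
      b <- cell$count[cell$vesicle == ves & cell$treatment == treatment]
      res <- poisson_rate_ratio(a, b)
      list(res = res, call = change_call(res, alpha = alpha),
           mean_control = mean(a), mean_treated = mean(b),
           n_control = length(a), n_treated = length(b))
    }
    ap <- per_vesicle("AP")
    al <- per_vesicle("AL")
    cls <- classify_flux(ap$call, al$call)
    all_pos <- all(c(ap$mean_control, al$mean_control,
                     ap$mean_treated, al$mean_treated) > 0)
    if (all_pos) {
      fold <- infer_rate_fold_changes(
        pool_state(ap$mean_control, al$mean_control),
        pool_state(ap$mean_treated, al$mean_treated))
      f_beta <- fold$f_beta
      f_gamma <- fold$f_gamma
    } else {
      # a zero arm mean leaves the ratio undefined; report NA, never error
      f_beta <- NA_real_
      f_gamma <- NA_real_
    }
    tibble::tibble(
      ap_rate_ratio = ap$res$rate_ratio, ap_p_value = ap$res$p_value,
      al_rate_ratio = al$res$rate_ratio, al_p_value = al$res$p_value,
      ap_direction = ap$call$direction, al_direction = al$call$direction,
      f_beta = f_beta, f_gamma = f_gamma,
      status = cls$status, inhibition_pattern = cls$inhibition_pattern,
      n_control = ap$n_control, n_treated = ap$n_treated
    )
  }

  out <- records |>
    dplyr::group_by(.data$genotype, .data$tissue, .data$day) |>
    dplyr::group_modify(function(d, key) one_cell(d)) |>
    dplyr::ungroup()
  class(out) <- c("flux_assay_result", class(out))
  attr(out, "alpha") <- alpha
  out
}
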