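#' Kinetic parameters of the three-step autophagy model
#'
#' Autophagy is modelled as a linear chain
#' IM \eqn{\rightarrow} AP \eqn{\rightarrow} AL \eqn{\rightarrow} degradation,
#' with dynamics
#' \deqn{dAP/dt = J - \beta \, AP, \qquad dAL/dt = \beta \, AP - \gamma \, AL,}
#' where the influx \eqn{J} lumps the isolation-membrane pool with its
#' conversion rate constant (the product is all that is ever observable),
#' \eqn{\beta} is the AP \eqn{\rightarrow} AL conversion rate constant and
#' \eqn{\gamma} the AL degradation rate constant.
#'
#' @param influx Influx of new autophagosomes, vesicles per unit time
#'   (\eqn{J \ge 0}).
#' @param beta AP-to-AL conversion rate constant, per unit time
#'   (\eqn{\beta > 0}).
#' @param gamma AL degradation rate constant, per unit time
#'   (\eqn{\gamma > 0}).
#' @param time_unit Label for the time unit; rate constants in the BafA flux
#'   assay are naturally expressed per hour (the assay reads out 2 h after
#'   injection).
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(influx = 12, beta = 4, gamma = 2)
#' steady_state_pools(p)
#' @export
kinetic_params <- function(influx, beta, gamma, time_unit = "hour") {
  stopifnot(is.numeric(influx), is.numeric(beta), is.numeric(gamma),
            length(influx) == 1L, length(beta) == 1L, length(gamma) == 1L)
  if (!is.finite(influx) || influx < 0) {
    abort("`influx` must be finite and >= 0.", class = "autoflux_invalid_parameter")
  }
  if (!is.finite(beta) || beta <= 0) {
    abort("`beta` must be finite and > 0.", class = "autoflux_invalid_parameter")
  }
  if (!is.finite(gamma) || gamma <= 0) {
    abort("`gamma` must be finite and > 0.", class = "autoflux_invalid_parameter")
  }
  structure(
    list(influx = as.numeric(influx), beta = as.numeric(beta),
         gamma = as.numeric(gamma), time_unit = time_unit),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params>  J = %g, beta = %g, gamma = %g  [per %s]\n",
              x$influx, x$beta, x$gamma, x$time_unit))
  invisible(x)
}

#' @export
format.kinetic_params <- function(x, ...) {
  sprintf("kinetic_params(J = %g, beta = %g, gamma = %g)",
          x$influx, x$beta, x$gamma)
}

#' Autophagic vesicle pool sizes
#'
#' A pool state holds the expected autophagosome (AP) and autolysosome (AL)
#' counts per observation unit (a cell, a pharyngeal bulb, or a fixed-area
#' image patch). Pools are continuous expected counts; discreteness enters
#' only when synthetic counts are drawn.
#'
#' @param ap Expected AP count (>= 0).
#' @param al Expected AL count (>= 0).
#'
#' @return An object of class `pool_state`.
#' @examples
#' pool_state(ap = 3, al = 6)
#' @export
pool_state <- function(ap, al) {
  stopifnot(is.numeric(ap), is.numeric(al), length(ap) == 1L, length(al) == 1L)
  if (!is.finite(ap) || ap < 0 || !is.finite(al) || al < 0) {
    abort("Pool sizes `ap` and `al` must be finite and >= 0.",
          class = "autoflux_invalid_parameter")
  }
  structure(list(ap = as.numeric(ap), al = as.numeric(al)), class = "pool_state")
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("<pool_state>  AP = %g, AL = %g\n", x$ap, x$al))
  invisible(x)
}

as_pool_state <- function(x) {
  if (inherits(x, "pool_state")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(pool_state(x[[1]], x[[2]]))
  if (is.list(x) && all(c("ap", "al") %in% names(x))) {
    return(pool_state(x$ap, x$al))
  }
  abort("Cannot interpret input as a pool state (need `ap` and `al`).")
}

#' Steady-state AP and AL pool sizes
#'
#' Setting \eqn{dAP/dt = dAL/dt = 0} gives the closed-form steady state
#' \eqn{[AP] = J/\beta} and \eqn{[AL] = J/\gamma}.
#'
#' @param params A [kinetic_params()] object.
#'
#' @return A `pool_state` with components `ap = J/beta`, `al = J/gamma`.
#' @examples
#' steady_state_pools(kinetic_params(12, 4, 2)) # AP = 3, AL = 6
#' @export
steady_state_pools <- function(params) {
  params <- as_kinetic_params(params)
  pool_state(ap = params$influx / params$beta, al = params$influx / params$gamma)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (is.list(x) && all(c("influx", "beta", "gamma") %in% names(x))) {
    return(kinetic_params(x$influx, x$beta, x$gamma,
                          time_unit = x$time_unit %||% "hour"))
  }
  abort("Expected a `kinetic_params` object (see `kinetic_params()`).")
}

#' Autophagic flux at steady state
#'
#' At steady state the flux through every step of the pathway is equal:
#' \eqn{J = [AP]\,\beta = [AL]\,\gamma}. This function checks that the
#' supplied pools are consistent with the parameters and returns the flux.
#'
#' @param pools A [pool_state()] assumed to be at steady state for `params`.
#' @param params A [kinetic_params()] object.
#' @param tol Relative tolerance for the steady-state residuals
#'   \eqn{|J - ap\,\beta|} and \eqn{|ap\,\beta - al\,\gamma|}, scaled by
#'   `max(1, J)`.
#'
#' @return The flux `J` (vesicles per unit time), a single number.
#' @examples
#' p <- kinetic_params(12, 4, 2)
#' steady_state_flux(steady_state_pools(p), p) # 12
#' @export
steady_state_flux <- function(pools, params, tol = 1e-9) {
  pools <- as_pool_state(pools)
  params <- as_kinetic_params(params)
  scale <- max(1, params$influx)
  r1 <- abs(params$influx - pools$ap * params$beta)
  r2 <- abs(pools$ap * params$beta - pools$al * params$gamma)
  if (r1 > tol * scale || r2 > tol * scale) {
    abort(
      sprintf(paste0(
        "Pools are not at steady state for these parameters ",
        "(residuals %.3g and %.3g exceed tolerance %.3g)."),
        r1, r2, tol * scale),
      class = "autoflux_not_steady_state"
    )
  }
  params$influx
}

#' Steady-state AP:AL pool ratio
#'
#' At steady state \eqn{[AP]/[AL] = (J/\beta)/(J/\gamma) = \gamma/\beta}:
#' the pool ratio is inversely related to the ratio of the rate constants,
#' so observing fewer APs than ALs implies \eqn{\gamma < \beta}
#' (AL turnover is the slower, rate-limiting step).
#'
#' @param params A [kinetic_params()] object.
#'
#' @return The dimensionless ratio \eqn{\gamma/\beta}.
#' @examples
#' pool_ratio(kinetic_params(12, 4, 2)) # 0.5
#' @export
pool_ratio <- function(params) {
  params <- as_kinetic_params(params)
  params$gamma / params$beta
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    abort("`times` must be a non-empty numeric vector.", class = "autoflux_invalid_times")
  }
  if (times[1] < 0 || any(diff(times) <= 0)) {
    abort("`times` must be non-negative and strictly increasing.",
          class = "autoflux_invalid_times")
  }
  as.numeric(times)
}

#' Closed-form AP/AL time course
#'
#' Analytic solution of the linear chain from an arbitrary initial state.
#' With \eqn{A = AP_0 - J/\beta}:
#' \deqn{AP(t) = J/\beta + A e^{-\beta t}}
#' \deqn{AL(t) = J/\gamma + \frac{\beta A}{\gamma-\beta} e^{-\beta t}
#'   + \Big(AL_0 - J/\gamma - \frac{\beta A}{\gamma-\beta}\Big) e^{-\gamma t}}
#' for \eqn{\beta \ne \gamma}; the repeated-eigenvalue case \eqn{\beta = \gamma}
#' is handled by its exact limit
#' \eqn{AL(t) = J/\gamma + \beta A t e^{-\beta t} + (AL_0 - J/\gamma) e^{-\gamma t}},
#' never by perturbing parameters.
#'
#' @param params A [kinetic_params()] object.
#' @param init Initial [pool_state()].
#' @param times Strictly increasing numeric vector of times (same unit as the
#'   rate constants).
#'
#' @return A tibble with columns `time`, `ap`, `al`.
#' @examples
#' closed_form_timecourse(kinetic_params(12, 4, 2), pool_state(0, 0),
#'                        times = c(0, 1, 2, 8))
#' @export
closed_form_timecourse <- function(params, init, times) {
  params <- as_kinetic_params(params)
  init <- as_pool_state(init)
  times <- check_times(times)
  J <- params$influx; b <- params$beta; g <- params$gamma
  ap_inf <- J / b; al_inf <- J / g
  A <- init$ap - ap_inf
  ap <- ap_inf + A * exp(-b * times)
  if (b == g) {
    al <- al_inf + b * A * times * exp(-b * times) +
      (init$al - al_inf) * exp(-g * times)
  } else {
    k <- b * A / (g - b)
    al <- al_inf + k * exp(-b * times) + (init$al - al_inf - k) * exp(-g * times)
  }
  tibble::tibble(time = times, ap = ap, al = pmax(al, 0))
}

#' Numerically integrated AP/AL time course
#'
#' Integrates \eqn{dAP/dt = J - \beta AP}, \eqn{dAL/dt = \beta AP - \gamma AL}
#' with `deSolve::lsoda()`. The closed-form solution
#' ([closed_form_timecourse()]) is the exact reference; the integrator exists
#' so that the model can be checked against an independent numerical route
#' and extended.
#'
#' @inheritParams closed_form_timecourse
#' @param rtol,atol Relative and absolute integrator tolerances.
#'
#' @return A tibble with columns `time`, `ap`, `al`.
#' @examples
#' simulate_timecourse(kinetic_params(12, 4, 2), pool_state(0, 0),
#'                     times = c(0, 1, 2, 8))
#' @export
simulate_timecourse <- function(params, init, times, rtol = 1e-10, atol = 1e-10) {
  params <- as_kinetic_params(params)
  init <- as_pool_state(init)
  times <- check_times(times)
  # lsoda needs at least two time points; prepend 0 if a single time was given
  tt <- if (length(times) == 1L && times[1] > 0) c(0, times) else times
  if (tt[1] > 0) tt <- c(0, tt)
  deriv <- function(t, y, p) {
    list(c(p$influx - p$beta * y[1], p$beta * y[1] - p$gamma * y[2]))
  }
  out <- deSolve::lsoda(
    y = c(ap = init$ap, al = init$al), times = tt, func = deriv,
    parms = params, rtol = rtol, atol = atol
  )
  out <- tibble::as_tibble(as.data.frame(out))
  out <- out[match(times, out$time), , drop = FALSE]
  tibble::tibble(time = times, ap = pmax(out$ap, 0), al = pmax(out$al, 0))
}

#' Has a trajectory reached steady state?
#'
#' Relative distance of the final state of a trajectory from the analytic
#' steady state, used to declare an integrated trajectory "at steady state".
#'
#' @param trajectory A tibble as returned by [simulate_timecourse()].
#' @param params The [kinetic_params()] that generated it.
#' @param tol Relative tolerance (default 1e-4).
#' @return Logical.
#' @export
at_steady_state <- function(trajectory, params, tol = 1e-4) {
  params <- as_kinetic_params(params)
  ss <- steady_state_pools(params)
  n <- nrow(trajectory)
  scale <- max(1, ss$ap, ss$al)
  max(abs(trajectory$ap[n] - ss$ap), abs(trajectory$al[n] - ss$al)) <= tol * scale
}

#' Serialize kinetic parameters or pools to JSON
#'
#' Parameters serialize with keys `influx_J`, `beta`, `gamma`, `time_unit`;
#' pools with keys `ap`, `al`.
#'
#' @param x A [kinetic_params()] or [pool_state()] object.
#' @return A JSON string.
#' @examples
#' kinetics_to_json(kinetic_params(12, 4, 2))
#' kinetics_to_json(pool_state(3, 6))
#' @export
kinetics_to_json <- function(x) {
  if (inherits(x, "kinetic_params")) {
    obj <- list(influx_J = x$influx, beta = x$beta, gamma = x$gamma,
                time_unit = x$time_unit)
  } else if (inherits(x, "pool_state")) {
    obj <- list(ap = x$ap, al = x$al)
  } else {
    abort("`x` must be a kinetic_params or pool_state object.")
  }
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Deserialize kinetic parameters or pools from JSON
#'
#' @param txt A JSON string (or path to a JSON file) produced by
#'   [kinetics_to_json()].
#' @return A `kinetic_params` (if the keys `influx_J`, `beta`, `gamma` are
#'   present) or a `pool_state` (keys `ap`, `al`).
#' @export
kinetics_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  if (all(c("influx_J", "beta", "gamma") %in% names(obj))) {
    kinetic_params(obj$influx_J, obj$beta, obj$gamma,
                   time_unit = obj$time_unit %||% "hour")
  } else if (all(c("ap", "al") %in% names(obj))) {
    pool_state(obj$ap, obj$al)
  } else {
    abort("JSON does not contain kinetic parameters or a pool state.")
  }
}
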