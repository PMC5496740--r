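#' Two-group Poisson rate-ratio test
#'
#' Fits a Poisson GLM with log link and a single group indicator,
#' `count ~ group`, and reports the maximum-likelihood rate ratio of group b
#' versus group a with a Wald test on the group coefficient. The point
#' estimate equals the closed-form two-group Poisson MLE `mean(b)/mean(a)`.
#'
#' @param counts_a,counts_b Non-negative integer count vectors for the
#'   reference group (a) and comparison group (b).
#' @param test `"wald"` (default) or `"lrt"` for a likelihood-ratio test on
#'   the group term.
#' @param continuity If `TRUE`, a 0.5 continuity adjustment is added to each
#'   group total when a group is all-zero; by default all-zero groups are
#'   reported with an `undefined` flag and an infinite/undefined log-ratio
#'   rather than silently adjusted.
#' @return A one-row tibble with columns `log_rate_ratio`, `stderr`,
#'   `rate_ratio`, `p_value`, `n_a`, `n_b`, `mean_a`, `mean_b`, `undefined`.
#' @examples
#' poisson_rate_ratio(rpois(30, 4), rpois(30, 8))
#' @export
poisson_rate_ratio <- function(counts_a, counts_b, test = c("wald", "lrt"),
                               continuity = FALSE) {
  test <- match.arg(test)
  check_counts <- function(x, nm) {
    if (length(x) == 0L) abort(sprintf("`%s` must be non-empty.", nm))
    if (anyNA(x) || any(x < 0) || any(x != round(x))) {
      abort(sprintf("`%s` must be non-negative integers.", nm))
    }
  }
  check_counts(counts_a, "counts_a")
  check_counts(counts_b, "counts_b")
  n_a <- length(counts_a); n_b <- length(counts_b)
  s_a <- sum(counts_a); s_b <- sum(counts_b)

  if ((s_a == 0L || s_b == 0L) && !continuity) {
    lrr <- if (s_a == 0L && s_b == 0L) NA_real_ else if (s_a == 0L) Inf else -Inf
    return(tibble::tibble(
      log_rate_ratio = lrr, stderr = NA_real_,
      rate_ratio = exp(lrr), p_value = NA_real_,
      n_a = n_a, n_b = n_b, mean_a = s_a / n_a, mean_b = s_b / n_b,
      undefined = TRUE
    ))
  }

  if (s_a == 0L || s_b == 0L) {
    # continuity-adjusted closed form: totals + 0.5, Poisson-count variance
    lrr <- log((s_b + 0.5) / n_b) - log((s_a + 0.5) / n_a)
    se <- sqrt(1 / (s_a + 0.5) + 1 / (s_b + 0.5))
    p <- 2 * stats::pnorm(-abs(lrr / se))
    return(tibble::tibble(
      log_rate_ratio = lrr, stderr = se, rate_ratio = exp(lrr), p_value = p,
      n_a = n_a, n_b = n_b, mean_a = s_a / n_a, mean_b = s_b / n_b,
      undefined = FALSE
    ))
  }

  dat <- data.frame(
    count = c(counts_a, counts_b),
    group = factor(rep(c("a", "b"), c(n_a, n_b)), levels = c("a", "b"))
  )
  # tight IRLS tolerance so the estimate matches the closed-form MLE
  fit <- glm(count ~ group, family = poisson(link = "log"), data = dat,
             control = list(epsilon = 1e-14, maxit = 100))
  est <- coef(fit)[["groupb"]]
  se <- sqrt(vcov(fit)["groupb", "groupb"])
  p <- if (test == "wald") {
    2 * stats::pnorm(-abs(est / se))
  } else {
    null <- glm(count ~ 1, family = poisson(link = "log"), data = dat)
    stats::pchisq(as.numeric(2 * (stats::logLik(fit) - stats::logLik(null))),
                  df = 1, lower.tail = FALSE)
  }
  tibble::tibble(
    log_rate_ratio = est, stderr = se, rate_ratio = exp(est), p_value = p,
    n_a = n_a, n_b = n_b, mean_a = s_a / n_a, mean_b = s_b / n_b,
    undefined = FALSE
  )
}

#' Check and coerce a table of puncta-count records
#'
#' The standard record schema is one row per animal, vesicle type and design
#' cell: columns `animal_id`, `tissue`, `day`, `genotype`, `treatment`,
#' `vesicle` (`"AP"`/`"AL"`), `count`.
#'
#' @param records A data frame.
#' @return The records as a tibble, or an error naming the problem.
#' @keywords internal
validate_count_records <- function(records) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  needed <- c("animal_id", "tissue", "day", "genotype", "treatment",
              "vesicle", "count")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort(sprintf("`records` is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyNA(records$count) || any(records$count < 0) ||
      any(records$count != round(records$count))) {
    abort("`count` must be non-negative integers.")
  }
  tibble::as_tibble(records)
}

#' Age-trend contrasts against Day 1
#'
#' For records of a single genotype, tissue and vesicle type, fits a Poisson
#' GLM with day as a factor (reference Day 1) and returns one rate-ratio row
#' per non-reference day: the day-d versus Day-1 comparison of the ageing
#' time course.
#'
#' @param records A count-record data frame (see [validate_count_records()])
#'   for one genotype/tissue/vesicle, spanning at least two distinct days and
#'   including Day 1 (or `reference_day`).
#' @param reference_day Reference day (default 1).
#' @param alpha Passed through to the returned tibble as an attribute; not
#'   used in the fit.
#' @return A tibble with one row per non-reference day: columns `day`,
#'   `log_rate_ratio`, `stderr`, `rate_ratio`, `p_value`, `n_ref`, `n_day`.
#' @examples
#' cfg <- generator_config(n_animals_per_cell = 20)
#' rec <- generate_count_dataset(cfg, seed = 1) |>
#'   dplyr::filter(genotype == "WT", tissue == "muscle", vesicle == "AP")
#' age_trend_test(rec)
#' @export
age_trend_test <- function(records, reference_day = 1, alpha = 0.01) {
  records <- validate_count_records(records)
  for (col in c("genotype", "tissue", "vesicle")) {
    if (length(unique(records[[col]])) > 1L) {
      abort(sprintf("`records` must contain a single %s (found %d).",
                    col, length(unique(records[[col]]))))
    }
  }
  days <- sort(unique(records$day))
  if (length(days) < 2L) {
    abort("Age-trend test needs at least 2 distinct days.",
          class = "autoflux_single_day")
  }
  if (!reference_day %in% days) {
    abort(sprintf("Reference day %s is absent from `records`.", reference_day))
  }
  ref <- records$count[records$day == reference_day]
  purrr::map_dfr(setdiff(days, reference_day), function(d) {
    res <- poisson_rate_ratio(ref, records$count[records$day == d])
    tibble::tibble(day = d, log_rate_ratio = res$log_rate_ratio,
                   stderr = res$stderr, rate_ratio = res$rate_ratio,
                   p_value = res$p_value, n_ref = res$n_a, n_day = res$n_b,
                   undefined = res$undefined)
  })
}

#' Derive AL counts from total mCherry and GFP-positive counts
#'
#' In the tandem reporter, autolysosomes are mCherry-only punctae and are
#' derived per animal as (total mCherry-positive punctae) minus
#' (GFP-positive punctae). Negative differences (miscounts) are floored at 0.
#'
#' @param total_mcherry,gfp_positive Non-negative integer vectors of equal
#'   length.
#' @return Integer vector of derived AL (mCherry-only) counts.
#' @examples
#' al_from_mcherry(c(10, 8), c(3, 2)) # 7, 6
#' @export
al_from_mcherry <- function(total_mcherry, gfp_positive) {
  stopifnot(length(total_mcherry) == length(gfp_positive),
            all(total_mcherry >= 0), all(gfp_positive >= 0))
  pmax(as.integer(total_mcherry) - as.integer(gfp_positive), 0L)
}
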