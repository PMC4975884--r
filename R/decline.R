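#' Estimate the yearly decline rate of a spinal endpoint
#'
#' The package's front door: one call takes an age-aggregated table and
#' returns the endpoint's yearly decline rate with a 95% confidence
#' interval, dispatching on the table kind.
#'
#' For a prevalence table the reconstruction is deterministic
#' ([expand_prevalence()]), the model is logistic regression on age and the
#' reported rate is the average marginal effect of a one-year age increase
#' in percentage points per year ([average_marginal_effect()]).
#'
#' For a continuous table the estimate comes from the seeded Monte Carlo
#' simulation ([run_mc()]): the mean slope over iterations, with the normal
#' interval `mean(b) +/- 1.96 * mean(se)` (or the empirical percentile
#' interval via `ci_method`).
#'
#' Both paths also run the likelihood-ratio linearity check of the single
#' linear age predictor against the saturated age-group model (for the
#' Monte Carlo path, on one dedicated seeded draw).
#'
#' @param aggregate A `spine_aggregate`. Tables without representative ages
#'   get arithmetic midpoints, with a message.
#' @param iterations Monte Carlo iterations (continuous tables only).
#' @param rng An [rng_spec()] for the continuous path; defaults to seed 1
#'   with the endpoint name as stream.
#' @param ci_method `"normal"` or `"percentile"` (continuous tables only).
#' @param ... Passed between methods.
#' @return An object of class `decline_rate` with fields `endpoint`,
#'   `source`, `method` (`"logistic-AME"` or `"MC-gaussian"`), `estimate`,
#'   `se`, `ci_low`, `ci_high` (%/year), `n`, the linearity test `lr`, and
#'   the underlying `fit` (logistic path) or `mc` result (continuous path).
#' @examples
#' decline_rate(spine_fixtures("disk degeneration"))
#' decline_rate(spine_fixtures("Psoas (V)"), iterations = 500)
#' @export
decline_rate <- function(aggregate, ...) UseMethod("decline_rate")

#' @rdname decline_rate
#' @export
decline_rate.prevalence_aggregate <- function(aggregate, ...) {
  aggregate <- ensure_rep_ages(aggregate)
  rec <- expand_prevalence(aggregate)
  fit <- fit_logistic(rec, "linear-age")
  ame <- average_marginal_effect(fit)
  lr <- lr_linearity_test(fit_logistic(rec, "age-group-factor"), fit)
  structure(list(endpoint = aggregate$endpoint, source = aggregate$source,
                 method = "logistic-AME", estimate = ame$estimate,
                 se = ame$se, ci_low = ame$ci_low, ci_high = ame$ci_high,
                 n = fit$n, lr = lr, fit = fit, ame = ame,
                 aggregate = aggregate),
            class = "decline_rate")
}

#' @rdname decline_rate
#' @export
decline_rate.continuous_aggregate <- function(aggregate,
                                              iterations = 10000L,
                                              rng = NULL,
                                              ci_method = c("normal",
                                                            "percentile"),
                                              ...) {
  ci_method <- match.arg(ci_method)
  aggregate <- ensure_rep_ages(aggregate)
  if (is.null(rng)) rng <- rng_spec(1L, aggregate$endpoint)
  mc <- run_mc(aggregate, iterations = iterations, rng = rng)
  ci <- mc_confint(mc, method = ci_method)
  lin_rec <- draw_continuous(aggregate, substream(rng, "linearity"))
  lr <- lr_linearity_test(fit_gaussian(lin_rec, "age-group-factor"),
                          fit_gaussian(lin_rec, "linear-age"))
  structure(list(endpoint = aggregate$endpoint, source = aggregate$source,
                 method = "MC-gaussian", estimate = ci$point,
                 se = unname(mc$se["mean"]), ci_low = ci$ci_low,
                 ci_high = ci$ci_high, n = mc$n, lr = lr, mc = mc,
                 aggregate = aggregate),
            class = "decline_rate")
}

ensure_rep_ages <- function(aggregate) {
  if (anyNA(aggregate$groups$rep_age)) {
    message("assigning midpoint representative ages to '",
            aggregate$endpoint, "'")
    aggregate <- representative_ages(aggregate, "midpoint")
  }
  aggregate
}

#' @export
print.decline_rate <- function(x, digits = 3, ...) {
  cat(sprintf("Yearly decline rate, %s (%s, %s):\n", x$endpoint, x$source,
              x$method))
  cat(sprintf("  %.*f %%/year (se %.*f, 95%% CI %.*f to %.*f), n = %d\n",
              digits, x$estimate, digits, x$se, digits, x$ci_low, digits,
              x$ci_high, x$n))
  invisible(x)
}

#' @export
summary.decline_rate <- function(object, ...) {
  print(object)
  cat(sprintf("  linearity: LR %.3f on %d df, p = %.3f\n",
              object$lr$statistic, object$lr$df, object$lr$p_value))
  if (!is.null(object$mc)) {
    cat(sprintf("  Monte Carlo: %d iterations of n = %d\n",
                object$mc$iterations, object$mc$n))
    print(round(rbind(`b(age)` = object$mc$b, `se(b)` = object$mc$se), 4))
  } else {
    cat(sprintf("  logit slope %.4f (se %.4f), logLik %.2f\n",
                object$fit$slope, object$fit$se_slope, object$fit$loglik))
  }
  invisible(object)
}

#' @export
coef.decline_rate <- function(object, ...) {
  c(estimate = object$estimate)
}

#' @export
confint.decline_rate <- function(object, parm, level = 0.95, ...) {
  if (!missing(level) && level != 0.95)
    stop("only 95% intervals are computed", call. = FALSE)
  m <- matrix(c(object$ci_low, object$ci_high), 1,
              dimnames = list(object$endpoint, c("2.5 %", "97.5 %")))
  m
}

#' Run the full decline-rate pipeline over a set of aggregates
#'
#' Applies [decline_rate()] to every aggregate (by default all 15 bundled
#' endpoints) and assembles the combined [decline_report()].
#'
#' @param aggregates Named list of `spine_aggregate`s; defaults to
#'   [spine_fixtures()].
#' @param iterations Monte Carlo iterations for continuous endpoints.
#' @param seed Base seed; each continuous endpoint gets its own named
#'   stream.
#' @param ci_method Interval method for continuous endpoints.
#' @return A `decline_report`.
#' @export
run_pipeline <- function(aggregates = spine_fixtures(),
                         iterations = 10000L, seed = 1L,
                         ci_method = "normal") {
  fits <- lapply(aggregates, function(a) {
    if (inherits(a, "prevalence_aggregate")) decline_rate(a) else
      decline_rate(a, iterations = iterations,
                   rng = rng_spec(seed, a$endpoint), ci_method = ci_method)
  })
  decline_report(fits)
}
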