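#' Fit a logistic age-trend model to reconstructed binary records
#'
#' Maximum-likelihood logistic regression of a degenerative-feature
#' indicator on age, on either representation of the reconstructed data:
#' expanded Bernoulli records (columns `age`, `outcome` in 0/1) or grouped
#' binomial counts (columns `age`, `n_pos`, `n_neg`). Both representations
#' give identical estimates and standard errors. Age enters either as a
#' single linear predictor (`design = "linear-age"`) or as one indicator per
#' age group (`design = "age-group-factor"`, the saturated model used by the
#' linearity test).
#'
#' Fitting uses iteratively reweighted least squares ([stats::glm]) followed
#' by Newton refinement until the score norm is below `1e-8`. Complete
#' separation is a hard error (it signals malformed input, not a fittable
#' trend), as is non-convergence.
#'
#' @param records Data frame in one of the two representations above.
#' @param design `"linear-age"` or `"age-group-factor"`.
#' @return A `spine_fit` object: model kind, design, coefficients and their
#'   covariance, the age slope `slope` and its standard error `se_slope`
#'   (linear-age design), log-likelihood, sample size `n` and the per-row
#'   ages/weights needed by [average_marginal_effect()].
#' @examples
#' rec <- expand_prevalence(spine_fixtures("disk degeneration"))
#' fit_logistic(rec)$slope  # log-odds per year
#' @export
fit_logistic <- function(records, design = c("linear-age",
                                             "age-group-factor")) {
  design <- match.arg(design)
  stopifnot(is.data.frame(records), "age" %in% names(records))
  grouped <- all(c("n_pos", "n_neg") %in% names(records))
  if (!grouped && !"outcome" %in% names(records))
    stop("records need either an 'outcome' column or 'n_pos'/'n_neg'",
         call. = FALSE)
  ep <- if (!is.null(records$endpoint)) records$endpoint[1] else "records"

  if (grouped) {
    npos <- sum(records$n_pos); nneg <- sum(records$n_neg)
    n <- npos + nneg
    w <- records$n_pos + records$n_neg
    y <- records$n_pos / w
  } else {
    if (!all(records$outcome %in% c(0L, 1L)))
      stop("binary outcomes must be 0/1 for '", ep, "'", call. = FALSE)
    y <- records$outcome
    npos <- sum(y); nneg <- sum(1 - y)
    n <- length(y)
    w <- rep(1, n)
  }
  if (npos == 0L || nneg == 0L)
    stop("endpoint '", ep, "': both outcome classes must be present",
         call. = FALSE)
  age <- records$age
  if (design == "linear-age" && length(unique(age)) < 2L)
    stop("endpoint '", ep, "': linear-age design needs >= 2 distinct ages",
         call. = FALSE)

  X <- if (design == "linear-age") cbind(`(Intercept)` = 1, age = age) else
    stats::model.matrix(~ factor(age))
  fit <- suppressWarnings(stats::glm.fit(X, y, weights = w,
                                         family = stats::binomial(),
                                         control = stats::glm.control(
                                           epsilon = 1e-12, maxit = 50)))
  p <- fit$fitted.values
  if (any(p < 1e-10 | p > 1 - 1e-10))
    stop("complete separation detected for endpoint '", ep,
         "': fitted probabilities reached 0/1", call. = FALSE)
  if (!fit$converged)
    stop("logistic fit for '", ep, "' did not converge in 50 IRLS ",
         "iterations (deviance ", format(fit$deviance), ")", call. = FALSE)

  # Newton polish to the score-norm criterion.
  beta <- fit$coefficients
  succ <- if (grouped) records$n_pos else y
  tot <- w
  for (it in 0:10) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, succ - tot * p))
    if (sqrt(sum(score^2)) < 1e-8) break
    info <- crossprod(X * (tot * p * (1 - p)), X)
    beta <- beta + solve(info, score)
  }
  if (sqrt(sum(score^2)) >= 1e-8)
    stop("logistic score did not reach tolerance for '", ep, "'",
         call. = FALSE)
  info <- crossprod(X * (tot * p * (1 - p)), X)
  V <- solve(info)
  ll <- if (grouped)
    sum(stats::dbinom(records$n_pos, tot, p, log = TRUE)) else
    sum(stats::dbinom(y, 1, p, log = TRUE))

  new_spine_fit(kind = "logistic", design = design, coef = beta, vcov = V,
                loglik = ll, n = n, ages = age, weights = w,
                representation = if (grouped) "grouped" else "expanded",
                endpoint = ep, score_norm = sqrt(sum(score^2)))
}

new_spine_fit <- function(kind, design, coef, vcov, loglik, n, ages, weights,
                          representation, endpoint, se_slope = NULL,
                          sigma = NULL, score_norm = NA_real_) {
  slope <- if (design == "linear-age") unname(coef["age"]) else NA_real_
  if (is.null(se_slope))
    se_slope <- if (design == "linear-age")
      sqrt(vcov["age", "age"]) else NA_real_
  structure(list(kind = kind, design = design, coef = coef, vcov = vcov,
                 slope = slope, se_slope = se_slope,
                 intercept = unname(coef[1]), loglik = loglik, n = n,
                 ages = ages, weights = weights,
                 representation = representation, endpoint = endpoint,
                 sigma = sigma, score_norm = score_norm),
            class = "spine_fit")
}

#' @export
print.spine_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s design) for '%s': n = %d, logLik = %s\n",
              x$kind, x$design, x$endpoint, x$n, format(x$loglik)))
  if (x$design == "linear-age")
    cat(sprintf("  age slope b = %.6g (se %.6g)\n", x$slope, x$se_slope))
  invisible(x)
}

#' @export
logLik.spine_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef) +
              (object$kind == "gaussian"), nobs = object$n, class = "logLik")
}

#' @export
coef.spine_fit <- function(object, ...) object$coef

#' @export
vcov.spine_fit <- function(object, ...) object$vcov

# Closed-form simple OLS used by the Gaussian linear-age design (and the
# Monte Carlo hot loop). Cross-checked against stats::lm in the test suite.
ols_simple <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("degenerate age design: no age variation",
                     call. = FALSE)
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  s2ml <- rss / n
  ll <- if (s2ml > 0) -n / 2 * (log(2 * pi * s2ml) + 1) else Inf
  list(slope = slope, intercept = intercept, se = se, rss = rss,
       loglik = ll, sigma = sqrt(s2ml))
}

#' Fit a Gaussian age-trend model to continuous records
#'
#' Ordinary least squares of a continuous outcome (muscle fat-infiltration
#' percent) on age. Under the Gaussian linear model the marginal effect of a
#' one-year age change is the slope coefficient itself, so `slope` /
#' `se_slope` are the decline-rate estimate and its standard error. The
#' log-likelihood is the Gaussian maximum-likelihood value (ML variance),
#' the quantity the likelihood-ratio linearity test needs.
#'
#' @param records Data frame with columns `age` and continuous `outcome`.
#' @param design `"linear-age"` (single numeric age predictor) or
#'   `"age-group-factor"` (saturated one-mean-per-group model).
#' @return A `spine_fit` of kind `"gaussian"`.
#' @examples
#' rec <- draw_continuous(spine_fixtures("MF (C)"), rng_spec(1, "ex"))
#' fit_gaussian(rec)$slope  # FI %/year
#' @export
fit_gaussian <- function(records, design = c("linear-age",
                                             "age-group-factor")) {
  design <- match.arg(design)
  stopifnot(is.data.frame(records),
            all(c("age", "outcome") %in% names(records)))
  ep <- if (!is.null(records$endpoint)) records$endpoint[1] else "records"
  age <- records$age; y <- records$outcome
  n <- length(y)
  if (n < 3L) stop("endpoint '", ep, "': need at least 3 records",
                   call. = FALSE)
  if (length(unique(age)) < 2L)
    stop("endpoint '", ep, "': need >= 2 distinct ages", call. = FALSE)

  if (design == "linear-age") {
    o <- ols_simple(age, y)
    coefs <- c(`(Intercept)` = o$intercept, age = o$slope)
    s2 <- if (is.na(o$se)) NA_real_ else o$rss / (n - 2)
    V <- s2 * solve(crossprod(cbind(1, age)))
    dimnames(V) <- list(names(coefs), names(coefs))
    new_spine_fit("gaussian", design, coefs, V, o$loglik, n, age,
                  rep(1, n), "expanded", ep,
                  se_slope = if (is.na(o$se)) NA_real_ else o$se,
                  sigma = o$sigma)
  } else {
    X <- stats::model.matrix(~ factor(age))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    s2ml <- rss / n
    ll <- if (s2ml > 0) -n / 2 * (log(2 * pi * s2ml) + 1) else Inf
    coefs <- f$coefficients
    new_spine_fit("gaussian", design, coefs,
                  matrix(NA_real_, length(coefs), length(coefs),
                         dimnames = list(names(coefs), names(coefs))),
                  ll, n, age, rep(1, n), "expanded", ep,
                  se_slope = NA_real_, sigma = sqrt(s2ml))
  }
}

#' Average marginal effect of age, in percentage points per year
#'
#' For a logistic fit, the per-subject marginal effect of a one-year age
#' increase on predicted prevalence is `b * p_i * (1 - p_i)`; the average
#' marginal effect (AME) is its sample mean, scaled by 100 into percentage
#' points per year. Its standard error propagates the full coefficient
#' covariance through the AME gradient by the delta method, and the 95%
#' confidence interval is `estimate +/- 1.96 * se`. For a Gaussian fit the
#' marginal effect is the slope itself and the OLS standard error is used.
#'
#' @param fit A converged `spine_fit`.
#' @return A `marginal_effect` object with `estimate`, `se`, `ci_low`,
#'   `ci_high` (all %/year).
#' @examples
#' rec <- expand_prevalence(spine_fixtures("disk degeneration"))
#' average_marginal_effect(fit_logistic(rec))  # 1.429 %/year
#' @export
average_marginal_effect <- function(fit) {
  stopifnot(inherits(fit, "spine_fit"))
  if (fit$kind == "gaussian") {
    if (fit$design != "linear-age")
      stop("marginal effect needs the linear-age design", call. = FALSE)
    return(new_marginal_effect(fit$slope, fit$se_slope, fit$endpoint))
  }
  if (fit$design != "linear-age")
    stop("marginal effect needs the linear-age design", call. = FALSE)
  b <- fit$coef
  w <- fit$weights / sum(fit$weights)
  p <- stats::plogis(b["(Intercept)"] + b["age"] * fit$ages)
  est <- 100 * sum(w * b["age"] * p * (1 - p))
  # gradient of the AME in (intercept, slope)
  d <- p * (1 - p)
  g <- c(100 * sum(w * b["age"] * d * (1 - 2 * p)),
         100 * sum(w * (d + b["age"] * fit$ages * d * (1 - 2 * p))))
  se <- sqrt(drop(g %*% fit$vcov %*% g))
  new_marginal_effect(unname(est), se, fit$endpoint)
}

new_marginal_effect <- function(estimate, se, endpoint) {
  structure(list(endpoint = endpoint, estimate = estimate, se = se,
                 ci_low = estimate - 1.96 * se,
                 ci_high = estimate + 1.96 * se),
            class = "marginal_effect")
}

#' @export
print.marginal_effect <- function(x, ...) {
  cat(sprintf("%s: %.3f %%/year (se %.3f, 95%% CI %.3f to %.3f)\n",
              x$endpoint, x$estimate, x$se, x$ci_low, x$ci_high))
  invisible(x)
}

#' Likelihood-ratio test of age-trend linearity
#'
#' Compares the saturated model (one parameter per age group) with the
#' nested linear-age model on the same records:
#' `LR = 2 (logLik_saturated - logLik_linear)` on `#groups - 2` degrees of
#' freedom, referred to the chi-square distribution. With two age groups the
#' linear model is itself saturated: the statistic is 0 on 0 degrees of
#' freedom and the p-value is reported as 1. A non-significant result backs
#' the use of a single linear age predictor.
#'
#' @param saturated_fit A `spine_fit` with `design = "age-group-factor"`.
#' @param linear_fit A `spine_fit` with `design = "linear-age"`, fitted to
#'   the same records in the same representation.
#' @return A list of class `lr_test`: `statistic`, `df`, `p_value`.
#' @examples
#' rec <- expand_prevalence(spine_fixtures("disk bulge"))
#' lr_linearity_test(fit_logistic(rec, "age-group-factor"),
#'                   fit_logistic(rec, "linear-age"))
#' @export
lr_linearity_test <- function(saturated_fit, linear_fit) {
  stopifnot(inherits(saturated_fit, "spine_fit"),
            inherits(linear_fit, "spine_fit"))
  if (saturated_fit$design != "age-group-factor" ||
      linear_fit$design != "linear-age")
    stop("expected a saturated (age-group-factor) and a linear-age fit",
         call. = FALSE)
  if (saturated_fit$kind != linear_fit$kind ||
      saturated_fit$n != linear_fit$n ||
      saturated_fit$representation != linear_fit$representation ||
      !isTRUE(all.equal(sort(unique(saturated_fit$ages)),
                        sort(unique(linear_fit$ages)))))
    stop("fits are not nested: they must come from identical records",
         call. = FALSE)
  k <- length(unique(saturated_fit$ages))
  df <- k - 2L
  # near-perfect fits on both sides (zero residual noise): the Gaussian
  # log-likelihood degenerates and its rounding-level difference is
  # meaningless, so the statistic is 0 by definition
  degenerate <- (is.infinite(saturated_fit$loglik) &&
                   is.infinite(linear_fit$loglik)) ||
    (!is.null(saturated_fit$sigma) && !is.null(linear_fit$sigma) &&
       isTRUE(saturated_fit$sigma < 1e-8) && isTRUE(linear_fit$sigma < 1e-8))
  lr <- if (degenerate) 0 else
    2 * (saturated_fit$loglik - linear_fit$loglik)
  if (lr < -1e-8)
    stop("negative likelihood-ratio statistic (", format(lr),
         "): fits are inconsistent", call. = FALSE)
  lr <- max(lr, 0)
  p <- if (df == 0L) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  structure(list(statistic = lr, df = df, p_value = p), class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("LR linearity test: statistic %.4f on %d df, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
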