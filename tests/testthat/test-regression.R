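test_that("logistic fit matches an independent grouped-binomial ML oracle", {
  rec <- expand_prevalence(spine_fixtures("disk degeneration"))
  fit <- fit_logistic(rec)
  # frozen from a direct Newton maximisation of the grouped-binomial
  # likelihood (counts 101/273, 314/604, 282/415, 249/311 at 25/35/45/55),
  # iterated to score norm < 1e-12 outside the package
  expect_equal(fit$slope, 0.0646372380, tolerance = 1e-7)
  expect_equal(fit$intercept, -2.1675240651, tolerance = 1e-7)
  expect_identical(fit$n, 1603L)
  expect_lt(fit$score_norm, 1e-8)
})

test_that("grouped-binomial and expanded-Bernoulli fits are equivalent", {
  for (ep in c("disk degeneration", "spondylolisthesis", "annular fissure")) {
    agg <- spine_fixtures(ep)
    rec <- expand_prevalence(agg)
    cts <- t(vapply(seq_len(nrow(agg$groups)), function(j)
      binary_counts(agg$groups$n[j], agg$groups$prevalence_pct[j]),
      c(n_pos = 0L, n_neg = 0L)))
    grouped <- data.frame(age = agg$groups$rep_age, n_pos = cts[, 1],
                          n_neg = cts[, 2])
    fe <- fit_logistic(rec)
    fg <- fit_logistic(grouped)
    expect_equal(fe$coef, fg$coef, tolerance = 1e-8)
    expect_equal(fe$vcov, fg$vcov, tolerance = 1e-8)
    ae <- average_marginal_effect(fe)
    ag <- average_marginal_effect(fg)
    expect_equal(ae$estimate, ag$estimate, tolerance = 1e-8)
    expect_equal(ae$se, ag$se, tolerance = 1e-8)
  }
})

test_that("logistic preconditions and separation are hard, named errors", {
  rec <- data.frame(endpoint = "ones", age = rep(c(25, 35), each = 5),
                    outcome = 1L)
  expect_error(fit_logistic(rec), "ones.*both outcome classes")

  sep <- data.frame(endpoint = "sep", age = rep(c(25, 35, 45, 55), each = 20),
                    outcome = rep(c(0L, 0L, 1L, 1L), each = 20))
  expect_error(fit_logistic(sep), "separation.*sep|sep.*separation")

  one_age <- data.frame(age = rep(25, 10), outcome = rep(c(0L, 1L), 5))
  expect_error(fit_logistic(one_age), "2 distinct ages")

  flat <- data.frame(age = rep(c(25, 35), each = 10),
                     outcome = rep(c(1L, 0L, 1L, 0L), each = 5))
  expect_lt(abs(fit_logistic(flat)$slope), 1e-10)
})

test_that("AME reproduces the published disk-degeneration row and its CI", {
  ame <- average_marginal_effect(
    fit_logistic(expand_prevalence(spine_fixtures("disk degeneration"))))
  expect_equal(ame$estimate, 1.429, tolerance = 5e-4)
  expect_equal(ame$se, 0.106, tolerance = 5e-3)
  expect_equal(ame$ci_low, 1.221, tolerance = 5e-3)
  expect_equal(ame$ci_high, 1.637, tolerance = 5e-3)
  expect_equal(ame$ci_high - ame$estimate, 1.96 * ame$se)
})

test_that("delta-method AME SE agrees with numerical and bootstrap oracles", {
  skip_if_not_installed("MASS")
  for (ep in c("disk degeneration", "facet degeneration",
               "annular fissure")) {
    fit <- fit_logistic(expand_prevalence(spine_fixtures(ep)))
    ame <- average_marginal_effect(fit)
    expect_equal(ame$se, fd_ame_se(fit), tolerance = 1e-6)
    boot <- boot_ame_se(fit, draws = 1e5)
    expect_lt(abs(ame$se - boot) / boot, 0.02)
  }
  # with few cases (3-14% prevalence, n = 284) the AME is visibly curved in
  # the coefficients, so the parametric bootstrap carries a genuine
  # second-order component the first-order delta method omits; agreement is
  # looser but the FD-Jacobian identity still holds exactly
  fit <- fit_logistic(expand_prevalence(spine_fixtures("spondylolisthesis")))
  ame <- average_marginal_effect(fit)
  expect_equal(ame$se, fd_ame_se(fit), tolerance = 1e-6)
  expect_lt(abs(ame$se - boot_ame_se(fit, draws = 1e5)) / ame$se, 0.10)
})

test_that("gaussian fit matches stats::lm and closed-form identities", {
  set.seed(31)
  rec <- data.frame(age = rep(c(25, 35, 45, 55), each = 10),
                    outcome = rnorm(40, 12, 4))
  fit <- fit_gaussian(rec)
  ref <- lm(outcome ~ age, data = rec)
  expect_equal(fit$slope, unname(coef(ref)["age"]), tolerance = 1e-12)
  expect_equal(fit$se_slope,
               unname(sqrt(diag(vcov(ref))["age"])), tolerance = 1e-12)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)

  sat <- fit_gaussian(rec, "age-group-factor")
  ref_sat <- lm(outcome ~ factor(age), data = rec)
  expect_equal(sat$loglik, as.numeric(logLik(ref_sat)), tolerance = 1e-10)

  # two-group balanced data: slope is the mean difference over the age gap
  two <- data.frame(age = rep(c(21.5, 52.5), each = 12),
                    outcome = rnorm(24, 38, 2))
  m <- tapply(two$outcome, two$age, mean)
  expect_equal(fit_gaussian(two)$slope,
               unname((m[2] - m[1]) / 31), tolerance = 1e-12)

  # records at exactly the psoas group means recover the closed-form slope
  psoas_exact <- data.frame(age = rep(c(21.5, 52.5), each = 12),
                            outcome = rep(c(35.7, 37.1), each = 12))
  expect_equal(fit_gaussian(psoas_exact)$slope, 0.04516129, tolerance = 1e-7)

  const <- data.frame(age = rep(c(25, 35), each = 5), outcome = 3)
  cf <- fit_gaussian(const)
  expect_identical(cf$slope, 0)
  expect_identical(cf$se_slope, 0)

  expect_error(fit_gaussian(data.frame(age = rep(25, 5), outcome = 1:5)),
               "2 distinct ages")
  expect_error(fit_gaussian(data.frame(age = c(25, 35), outcome = 1:2)),
               "3 records")
})

test_that("LR linearity test behaves across saturation, nesting and fixtures", {
  # two groups: the linear model is saturated, df 0, LR ~ 0
  two <- draw_continuous(spine_fixtures("ES (V)"), rng_spec(2, "lr"))
  lr2 <- lr_linearity_test(fit_gaussian(two, "age-group-factor"),
                           fit_gaussian(two, "linear-age"))
  expect_identical(lr2$df, 0L)
  expect_lt(lr2$statistic, 1e-8)
  expect_identical(lr2$p_value, 1)

  # exactly linear group means with zero noise: perfect fit on both sides
  exact <- draw_continuous(recovery_aggregate(0.2, 10, 0,
                                              crawford_shaped_groups()),
                           rng_spec(1))
  lre <- lr_linearity_test(fit_gaussian(exact, "age-group-factor"),
                           fit_gaussian(exact, "linear-age"))
  expect_identical(lre$statistic, 0)

  # every prevalence endpoint is compatible with a linear age trend
  fx <- spine_fixtures()
  for (a in fx[vapply(fx, inherits, TRUE, "prevalence_aggregate")]) {
    rec <- expand_prevalence(a)
    lr <- lr_linearity_test(fit_logistic(rec, "age-group-factor"),
                            fit_logistic(rec, "linear-age"))
    expect_gte(lr$statistic, 0)
    expect_identical(lr$df, 2L)
    expect_gt(lr$p_value, 0.05)
  }

  # seeded draws of every continuous endpoint are likewise compatible with
  # linearity (2-group designs are saturated: df 0, p 1 by convention)
  for (a in fx[vapply(fx, inherits, TRUE, "continuous_aggregate")]) {
    rec <- draw_continuous(a, rng_spec(1, paste0(a$endpoint, "-linearity")))
    lr <- lr_linearity_test(fit_gaussian(rec, "age-group-factor"),
                            fit_gaussian(rec, "linear-age"))
    expect_identical(lr$df, max(nrow(a$groups) - 2L, 0L))
    expect_gt(lr$p_value, 0.05)
  }

  # non-nested inputs are refused
  other <- expand_prevalence(fx[["disk bulge"]])
  expect_error(
    lr_linearity_test(fit_logistic(expand_prevalence(fx[["annular fissure"]]),
                                   "age-group-factor"),
                      fit_logistic(other, "linear-age")),
    "not nested")
  expect_error(lr_linearity_test(fit_gaussian(two, "linear-age"),
                                 fit_gaussian(two, "linear-age")),
               "saturated")
})

test_that("slopes, SEs and AMEs are invariant under age translation", {
  # logistic path
  rec <- expand_prevalence(spine_fixtures("disk height loss"))
  shifted <- transform(rec, age = age + 100)
  f0 <- fit_logistic(rec); f1 <- fit_logistic(shifted)
  expect_equal(f0$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f0$se_slope, f1$se_slope, tolerance = 1e-10)
  a0 <- average_marginal_effect(f0); a1 <- average_marginal_effect(f1)
  expect_equal(a0$estimate, a1$estimate, tolerance = 1e-10)
  expect_equal(a0$se, a1$se, tolerance = 1e-10)

  # gaussian path (closed form: exact)
  d <- draw_continuous(spine_fixtures("MF (C)"), rng_spec(4, "shift"))
  g0 <- fit_gaussian(d)
  g1 <- fit_gaussian(transform(d, age = age + 100))
  expect_equal(g0$slope, g1$slope, tolerance = 1e-12)
  expect_equal(g0$se_slope, g1$se_slope, tolerance = 1e-12)
})
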