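# Independent oracles used across tests. These never call the code paths
# they check.

# Finite-difference delta-method SE for the logistic AME: numerical Jacobian
# of the AME as a function of (intercept, slope), propagated through vcov.
fd_ame_se <- function(fit, h = 1e-6) {
  ame_of <- function(beta) {
    p <- plogis(beta[1] + beta[2] * fit$ages)
    w <- fit$weights / sum(fit$weights)
    100 * sum(w * beta[2] * p * (1 - p))
  }
  b <- unname(fit$coef)
  g <- vapply(1:2, function(j) {
    e <- c(0, 0); e[j] <- h
    (ame_of(b + e) - ame_of(b - e)) / (2 * h)
  }, 0)
  sqrt(drop(g %*% fit$vcov %*% g))
}

# Parametric-bootstrap SE of the AME: resample coefficients from the
# estimated Gaussian sampling distribution and take the SD of the AME.
boot_ame_se <- function(fit, draws = 1e5, seed = 42) {
  set.seed(seed)
  B <- MASS::mvrnorm(draws, unname(fit$coef), fit$vcov)
  w <- fit$weights / sum(fit$weights)
  ames <- vapply(seq_len(draws), function(i) {
    p <- plogis(B[i, 1] + B[i, 2] * fit$ages)
    100 * sum(w * B[i, 2] * p * (1 - p))
  }, 0)
  sd(ames)
}

# Small two-decade continuous table used where the fixture detail is
# irrelevant.
toy_continuous <- function(means = c(10, 14), sds = c(2, 2), n = c(15, 15)) {
  representative_ages(
    continuous_aggregate("toy", "synthetic", c(20, 40), c(29, 49), n,
                         means, sds), "midpoint")
}

crawford_shaped_groups <- function() {
  data.frame(age_low = c(20, 30, 40, 50), age_high = c(29, 39, 49, 59),
             n = 20)
}
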