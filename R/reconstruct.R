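#' Seeded, named random-number streams
#'
#' Continuous reconstruction must be reproducible and endpoints must be
#' regenerable in isolation, so every stochastic draw is tied to an
#' `rng_spec`: a base seed plus a stream label. The pair is hashed to a
#' 31-bit seed for R's Mersenne-Twister, so identical specs give
#' bit-identical draws and distinct stream labels give effectively
#' independent streams. The Monte Carlo engine derives one stream per
#' (endpoint, iteration).
#'
#' @param seed Integer base seed.
#' @param stream Character stream label (default `""`).
#' @return An object of class `rng_spec`.
#' @export
rng_spec <- function(seed, stream = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L)
  structure(list(seed = as.integer(seed), stream = stream),
            class = "rng_spec")
}

# Polynomial string hash folded with the base seed, kept inside [0, 2^31-2].
# Doubles are exact here: intermediate products stay well below 2^53.
stream_seed <- function(spec) {
  m <- 2147483647
  h <- as.numeric(spec$seed %% m)
  for (b in utf8ToInt(spec$stream)) h <- (h * 31 + b) %% m
  # one multiplicative scramble so seed/stream contribute asymmetrically
  as.integer((h * 48271 + 11) %% m)
}

# Derive a sub-stream of an rng_spec (used per Monte Carlo iteration).
substream <- function(spec, suffix) {
  rng_spec(spec$seed, paste0(spec$stream, "#", suffix))
}

with_stream <- function(spec, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(stream_seed(spec), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

#' Split a group's sample size into positives and negatives
#'
#' Converts a group prevalence into integer case counts by rounding
#' `n * prevalence_pct / 100` half away from zero at the group level, the
#' rule under which the reconstructed counts agree with the published
#' per-group worked examples (e.g. 37% of 273 gives 101 positives).
#'
#' @param n Group sample size (`>= 1`).
#' @param prevalence_pct Prevalence in percent, in `[0, 100]`.
#' @return Named integer vector `c(n_pos, n_neg)` with `n_pos + n_neg == n`.
#' @examples
#' binary_counts(273, 37)  # 101 positives, 172 negatives
#' @export
binary_counts <- function(n, prevalence_pct) {
  stopifnot(length(n) == 1L, length(prevalence_pct) == 1L)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(prevalence_pct) || prevalence_pct < 0 ||
      prevalence_pct > 100)
    stop("prevalence_pct must be in [0, 100]", call. = FALSE)
  n_pos <- as.integer(floor(n * prevalence_pct / 100 + 0.5))
  c(n_pos = n_pos, n_neg = n - n_pos)
}

#' Expand a prevalence table into synthetic binary individual records
#'
#' Deterministically reconstructs one record per subject: every subject in a
#' group carries the group's representative age, and exactly
#' [binary_counts()] positives per group get outcome 1. The construction is
#' deterministic (no Bernoulli sampling) because the published proportions
#' are fixed quantities, not estimates to be re-randomised; the single
#' logistic fit downstream then reproduces the source analysis exactly.
#'
#' @param aggregate A `prevalence_aggregate` with representative ages
#'   assigned.
#' @return A data frame of individual records with columns `endpoint`, `age`
#'   and binary `outcome`, one row per reconstructed subject.
#' @examples
#' a <- spine_fixtures("disk degeneration")
#' nrow(expand_prevalence(a))  # 1603
#' @export
expand_prevalence <- function(aggregate) {
  stopifnot(inherits(aggregate, "prevalence_aggregate"))
  require_rep_ages(aggregate)
  g <- aggregate$groups
  recs <- lapply(seq_len(nrow(g)), function(j) {
    ct <- binary_counts(g$n[j], g$prevalence_pct[j])
    data.frame(endpoint = aggregate$endpoint, age = g$rep_age[j],
               outcome = rep(c(1L, 0L), ct), stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Draw synthetic continuous individual records from group summaries
#'
#' For each age group j draws exactly `n_j` normal variates with the group's
#' published mean and standard deviation, all carrying the group's
#' representative age — one Monte Carlo realisation of the reconstructed
#' sample. Draws are plain (untruncated) normals: clamping to the [0, 100]
#' fat-infiltration range would bias the group means that the simulation is
#' meant to preserve.
#'
#' @param aggregate A `continuous_aggregate` with representative ages
#'   assigned.
#' @param rng An [rng_spec()]; identical specs reproduce the draw
#'   bit-identically.
#' @return A data frame with columns `endpoint`, `age` and continuous
#'   `outcome`, `sum(n_j)` rows, groups in table order.
#' @examples
#' a <- spine_fixtures("Psoas (V)")
#' head(draw_continuous(a, rng_spec(1, "demo")))
#' @export
draw_continuous <- function(aggregate, rng = rng_spec(1L)) {
  stopifnot(inherits(aggregate, "continuous_aggregate"),
            inherits(rng, "rng_spec"))
  require_rep_ages(aggregate)
  g <- aggregate$groups
  outcome <- with_stream(rng,
    stats::rnorm(sum(g$n), mean = rep(g$mean, g$n), sd = rep(g$sd, g$n)))
  data.frame(endpoint = aggregate$endpoint, age = rep(g$rep_age, g$n),
             outcome = outcome, stringsAsFactors = FALSE)
}

#' Fabricate a continuous aggregate from a known linear age trend
#'
#' Parameter-recovery harness: builds a continuous table whose group means
#' lie exactly on `true_intercept + true_slope * rep_age` with constant
#' within-group standard deviation, so the Monte Carlo pipeline run on the
#' result must recover `true_slope` (up to Monte Carlo error). Used to
#' validate the whole reconstruction-plus-regression chain against a ground
#' truth no published table provides.
#'
#' @param true_slope Linear trend in outcome units per year.
#' @param true_intercept Outcome value at age 0.
#' @param noise_sd Common within-group standard deviation (`>= 0`).
#' @param groups Data frame with columns `age_low`, `age_high`, `n` (and
#'   optionally `rep_age`; midpoints are used otherwise). At least 2 groups.
#' @param endpoint Endpoint label for the fabricated table.
#' @return A `continuous_aggregate` with representative ages assigned.
#' @examples
#' g <- data.frame(age_low = c(20, 30, 40, 50), age_high = c(29, 39, 49, 59),
#'                 n = 20)
#' recovery_aggregate(0.2, 10, 5, g)$groups$mean
#' @export
recovery_aggregate <- function(true_slope, true_intercept, noise_sd, groups,
                               endpoint = "recovery") {
  stopifnot(is.data.frame(groups),
            all(c("age_low", "age_high", "n") %in% names(groups)))
  if (nrow(groups) < 2L)
    stop("at least 2 age groups are required: the slope is unidentifiable ",
         "from one group", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  rep_age <- if ("rep_age" %in% names(groups)) groups$rep_age else
    (groups$age_low + groups$age_high) / 2
  agg <- continuous_aggregate(endpoint, "synthetic",
                              groups$age_low, groups$age_high, groups$n,
                              mean = true_intercept + true_slope * rep_age,
                              sd = rep(noise_sd, nrow(groups)))
  agg$groups$rep_age <- rep_age
  agg
}

#' Export synthetic individual records as long-format CSV
#'
#' @param records A record data frame from [expand_prevalence()] or
#'   [draw_continuous()].
#' @param path Output CSV path.
#' @param iteration Optional iteration index column value (left blank for
#'   the deterministic binary reconstruction).
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path, iteration = NA_integer_) {
  stopifnot(is.data.frame(records),
            all(c("endpoint", "age", "outcome") %in% names(records)))
  out <- data.frame(endpoint = records$endpoint, iteration = iteration,
                    age = records$age, outcome = records$outcome)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
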