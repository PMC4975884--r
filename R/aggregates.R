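#' Age-aggregated summary tables
#'
#' The pipeline's sole inputs are age-aggregated summaries of imaging
#' endpoints: either a prevalence table (per age group, a sample size and the
#' percentage of subjects showing a degenerative feature) or a continuous
#' table (per age group, a sample size plus mean and standard deviation of
#' muscle fat-infiltration percentage). `prevalence_aggregate()` and
#' `continuous_aggregate()` build validated aggregate objects from per-group
#' vectors.
#'
#' @param endpoint Endpoint name, e.g. `"disk degeneration"` or `"MF (C)"`.
#'   Endpoints from different source studies should carry distinct names
#'   (the same muscle can appear in two studies on very different
#'   fat-infiltration scales).
#' @param source Source study label, e.g. `"Brinjikji"`.
#' @param age_low,age_high Integer vectors of group age bounds (years),
#'   one entry per group, `age_low <= age_high`.
#' @param n Integer vector of group sample sizes (all `>= 1`).
#' @param prevalence_pct Numeric vector of group prevalences in `[0, 100]`.
#' @param mean,sd Numeric vectors of group means and standard deviations of
#'   the continuous outcome (fat infiltration %); `sd >= 0`.
#' @param assumed_n Logical vector flagging groups whose sample size was not
#'   reported and had to be assumed (kept as first-class data so reports can
#'   disclose the imputation). Defaults to all `FALSE`.
#' @param label Optional character vector of group labels; defaults to
#'   `"low-high"`.
#'
#' @return An object of class `prevalence_aggregate` or
#'   `continuous_aggregate` (both inherit from `spine_aggregate`): a list
#'   with elements `endpoint`, `source` and `groups`, the latter a data frame
#'   with one row per age group. The `rep_age` column (the single
#'   representative age used for regression) is `NA` until assigned by
#'   [representative_ages()].
#'
#' @examples
#' prevalence_aggregate("disk degeneration", "Brinjikji",
#'   age_low = c(20, 30, 40, 50), age_high = c(29, 39, 49, 59),
#'   n = c(273, 604, 415, 311), prevalence_pct = c(37, 52, 68, 80))
#' @export
prevalence_aggregate <- function(endpoint, source, age_low, age_high, n,
                                 prevalence_pct, assumed_n = NULL,
                                 label = NULL) {
  groups <- build_groups(endpoint, age_low, age_high, n, assumed_n, label)
  prevalence_pct <- as.numeric(prevalence_pct)
  if (length(prevalence_pct) != nrow(groups))
    stop("'prevalence_pct' length does not match the number of groups for ",
         endpoint, call. = FALSE)
  bad <- which(!is.finite(prevalence_pct) | prevalence_pct < 0 |
                 prevalence_pct > 100)
  if (length(bad))
    stop(sprintf("endpoint '%s', group %d: prevalence_pct %s outside [0, 100]",
                 endpoint, bad[1], format(prevalence_pct[bad[1]])),
         call. = FALSE)
  groups$prevalence_pct <- prevalence_pct
  structure(list(endpoint = endpoint, source = source, groups = groups),
            class = c("prevalence_aggregate", "spine_aggregate"))
}

#' @rdname prevalence_aggregate
#' @export
continuous_aggregate <- function(endpoint, source, age_low, age_high, n,
                                 mean, sd, label = NULL) {
  groups <- build_groups(endpoint, age_low, age_high, n, NULL, label)
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (length(mean) != nrow(groups) || length(sd) != nrow(groups))
    stop("'mean'/'sd' length does not match the number of groups for ",
         endpoint, call. = FALSE)
  bad <- which(!is.finite(sd) | sd < 0)
  if (length(bad))
    stop(sprintf("endpoint '%s', group %d: sd %s is negative", endpoint,
                 bad[1], format(sd[bad[1]])), call. = FALSE)
  groups$mean <- mean
  groups$sd <- sd
  structure(list(endpoint = endpoint, source = source, groups = groups),
            class = c("continuous_aggregate", "spine_aggregate"))
}

# Shared group-frame construction and validation.
build_groups <- function(endpoint, age_low, age_high, n, assumed_n, label) {
  age_low <- as.integer(age_low); age_high <- as.integer(age_high)
  n <- as.integer(n)
  k <- length(age_low)
  if (length(age_high) != k || length(n) != k)
    stop("age_low, age_high and n must have equal length for ", endpoint,
         call. = FALSE)
  if (k < 1L) stop("at least one age group is required", call. = FALSE)
  if (any(age_low > age_high))
    stop(sprintf("endpoint '%s': age_low > age_high in group %d", endpoint,
                 which(age_low > age_high)[1]), call. = FALSE)
  bad <- which(is.na(n) | n < 1L)
  if (length(bad))
    stop(sprintf("endpoint '%s', group %d: sample size n must be >= 1",
                 endpoint, bad[1]), call. = FALSE)
  if (is.null(assumed_n)) assumed_n <- rep(FALSE, k)
  if (length(assumed_n) != k)
    stop("'assumed_n' length mismatch for ", endpoint, call. = FALSE)
  if (is.null(label)) label <- paste0(age_low, "-", age_high)
  data.frame(label = label, age_low = age_low, age_high = age_high,
             rep_age = rep(NA_real_, k), n = n,
             assumed_n = as.logical(assumed_n),
             stringsAsFactors = FALSE)
}

#' Assign representative ages to the groups of an aggregate
#'
#' Regression on grouped cross-sectional data needs one age value per group.
#' Three coding schemes are supported: the arithmetic midpoint of each
#' group's bounds, equal decade spacing (25, 35, 45, ... following group
#' order), or an explicit list. Because the age enters a linear predictor,
#' any equally spaced coding of equally wide groups yields identical slopes;
#' the decade scheme is the conventional choice for decade-binned prevalence
#' tables, while true midpoints suit unequal-width designs.
#'
#' @param aggregate A `spine_aggregate`.
#' @param scheme One of `"midpoint"`, `"decade"` (equally spaced 25, 35, ...)
#'   or `"explicit"`.
#' @param ages Numeric vector of representative ages, required when
#'   `scheme = "explicit"`; must have one entry per group.
#' @return The aggregate with its `rep_age` column filled. Idempotent for the
#'   derived schemes; an explicit override simply replaces the column.
#' @examples
#' a <- continuous_aggregate("Psoas (V)", "Valentin", c(18, 45), c(25, 60),
#'                           c(12, 12), c(35.7, 37.1), c(2.0, 1.5))
#' representative_ages(a, "midpoint")$groups$rep_age  # 21.5 52.5
#' @export
representative_ages <- function(aggregate,
                                scheme = c("midpoint", "decade", "explicit"),
                                ages = NULL) {
  stopifnot(inherits(aggregate, "spine_aggregate"))
  scheme <- match.arg(scheme)
  g <- aggregate$groups
  rep_age <- switch(scheme,
    midpoint = (g$age_low + g$age_high) / 2,
    decade = 25 + 10 * (seq_len(nrow(g)) - 1),
    explicit = {
      if (is.null(ages) || length(ages) != nrow(g))
        stop("scheme 'explicit' needs one age per group (got ",
             length(ages), " for ", nrow(g), " groups)", call. = FALSE)
      as.numeric(ages)
    })
  if (scheme == "midpoint" &&
      any(rep_age < g$age_low | rep_age > g$age_high))
    stop("midpoint representative age outside its group bounds", call. = FALSE)
  aggregate$groups$rep_age <- rep_age
  aggregate
}

# Representative ages must be present before reconstruction/regression.
require_rep_ages <- function(aggregate) {
  if (anyNA(aggregate$groups$rep_age))
    stop("aggregate '", aggregate$endpoint,
         "' has no representative ages; call representative_ages() first",
         call. = FALSE)
  invisible(aggregate)
}

#' @export
print.spine_aggregate <- function(x, ...) {
  kind <- if (inherits(x, "prevalence_aggregate")) "prevalence" else
    "continuous"
  cat(sprintf("Age-aggregated %s table: %s (%s), %d groups, n = %d\n",
              kind, x$endpoint, x$source, nrow(x$groups),
              sum(x$groups$n)))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Read and write aggregate tables as CSV
#'
#' One row per age group, columns `source`, `endpoint`, `age_low`,
#' `age_high`, `n` and either `prevalence_pct` (prevalence table) or
#' `mean`,`sd` (continuous table); an optional logical `assumed_n` column
#' flags imputed sample sizes. A file may carry several endpoints;
#' `read_aggregate_csv()` then returns a named list of aggregates, and a
#' single aggregate when only one endpoint is present. A file mixing
#' prevalence and mean/sd values within one endpoint is rejected as
#' ambiguous. `write_aggregate_csv()` accepts one aggregate or a list and is
#' the exact inverse on valid tables (`rep_age` is not serialized; reassign
#' it after reading).
#'
#' @param path CSV file path.
#' @param aggregates A `spine_aggregate` or a list of them.
#' @return `read_aggregate_csv()`: a `spine_aggregate` or named list of them;
#'   `write_aggregate_csv()`: `path`, invisibly.
#' @export
read_aggregate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("source", "endpoint", "age_low", "age_high", "n")
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stop("aggregate CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_prev <- "prevalence_pct" %in% names(d)
  has_cont <- all(c("mean", "sd") %in% names(d))
  if (!has_prev && !has_cont)
    stop("aggregate CSV needs either a 'prevalence_pct' column or ",
         "'mean' and 'sd' columns", call. = FALSE)
  if (is.null(d$assumed_n)) d$assumed_n <- FALSE
  out <- lapply(split(d, factor(d$endpoint, levels = unique(d$endpoint))),
                function(rows) {
    prev_here <- has_prev && any(!is.na(rows$prevalence_pct))
    cont_here <- has_cont && any(!is.na(rows$mean) | !is.na(rows$sd))
    if (prev_here && cont_here)
      stop("ambiguous table kind for endpoint '", rows$endpoint[1],
           "': both prevalence_pct and mean/sd are populated", call. = FALSE)
    src <- rows$source[1]
    if (prev_here)
      prevalence_aggregate(rows$endpoint[1], src, rows$age_low, rows$age_high,
                           rows$n, rows$prevalence_pct, rows$assumed_n)
    else
      continuous_aggregate(rows$endpoint[1], src, rows$age_low, rows$age_high,
                           rows$n, rows$mean, rows$sd)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname read_aggregate_csv
#' @export
write_aggregate_csv <- function(aggregates, path) {
  if (inherits(aggregates, "spine_aggregate")) aggregates <- list(aggregates)
  rows <- lapply(aggregates, function(a) {
    stopifnot(inherits(a, "spine_aggregate"))
    g <- a$groups
    base <- data.frame(source = a$source, endpoint = a$endpoint,
                       age_low = g$age_low, age_high = g$age_high, n = g$n,
                       stringsAsFactors = FALSE)
    if (inherits(a, "prevalence_aggregate")) {
      base$prevalence_pct <- g$prevalence_pct
      base$mean <- NA_real_; base$sd <- NA_real_
    } else {
      base$prevalence_pct <- NA_real_
      base$mean <- g$mean; base$sd <- g$sd
    }
    base$assumed_n <- g$assumed_n
    base
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
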