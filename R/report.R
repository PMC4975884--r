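#' Combined decline-rate comparison report
#'
#' Assembles per-endpoint decline-rate estimates into the cross-endpoint
#' comparison: one row per endpoint sorted by estimate (fastest decline
#' first) and the pairwise confidence-interval separation matrix.
#' `separated[a, b]` is `TRUE` when endpoint a's CI lower bound lies
#' strictly above endpoint b's upper bound — the basis of statements like
#' "this feature declined faster than every other". Separation is decided
#' on bounds rounded to 3 decimals, the precision of the machine-readable
#' outputs; the flag is asymmetric.
#'
#' @param fits A list of `decline_rate` objects (endpoint names must be
#'   unique).
#' @return A `decline_report`: list with `table` (data frame with columns
#'   `endpoint`, `source`, `estimate`, `ci_low`, `ci_high`, `method`,
#'   sorted by estimate descending) and the logical `separated` matrix.
#' @examples
#' fits <- lapply(spine_fixtures()[c("disk bulge", "annular fissure")],
#'                decline_rate)
#' decline_report(fits)
#' @export
decline_report <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "decline_rate")))
  eps <- vapply(fits, `[[`, "", "endpoint")
  if (anyDuplicated(eps))
    stop("duplicate endpoint id(s): ",
         paste(unique(eps[duplicated(eps)]), collapse = ", "), call. = FALSE)
  tab <- data.frame(
    endpoint = eps,
    source = vapply(fits, `[[`, "", "source"),
    estimate = vapply(fits, `[[`, 0, "estimate"),
    ci_low = vapply(fits, `[[`, 0, "ci_low"),
    ci_high = vapply(fits, `[[`, 0, "ci_high"),
    method = vapply(fits, `[[`, "", "method"),
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$estimate), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, separated = separation_matrix(tab)),
            class = "decline_report")
}

# Pairwise CI separation on 3-decimal-rounded bounds; pure function of the
# report table so the matrix can be re-derived from any serialisation.
separation_matrix <- function(tab) {
  lo <- round(tab$ci_low, 3)
  hi <- round(tab$ci_high, 3)
  m <- outer(lo, hi, ">")
  dimnames(m) <- list(tab$endpoint, tab$endpoint)
  diag(m) <- FALSE
  m
}

#' @export
print.decline_report <- function(x, digits = 2, ...) {
  cat("Yearly decline rates (%/year), fastest first:\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  print(tab, row.names = FALSE)
  top <- x$table$endpoint[1]
  beaten <- names(which(x$separated[top, ]))
  if (length(beaten))
    cat(sprintf("'%s' separated (CI lower bound above CI upper bound) from: %s\n",
                top, paste(beaten, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.decline_report <- function(x, ...) x$table

#' Plot a decline-rate comparison as points with CI whiskers
#'
#' @param x A `decline_report`.
#' @param ... Passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.decline_report <- function(x, ...) {
  tab <- x$table
  k <- nrow(tab)
  old <- graphics::par(mar = c(9, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(seq_len(k), tab$estimate, xlim = c(0.5, k + 0.5),
                 ylim = range(tab$ci_low, tab$ci_high), xaxt = "n",
                 xlab = "", ylab = "Yearly decline (%/year)", pch = 19, ...)
  graphics::arrows(seq_len(k), tab$ci_low, seq_len(k), tab$ci_high,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, lty = 3)
  graphics::axis(1, at = seq_len(k), labels = tab$endpoint, las = 2,
                 cex.axis = 0.8)
  invisible(x)
}

#' Export a decline report (or re-import it)
#'
#' `"csv"` writes the report table; `"json"` writes the table plus the
#' separation matrix; `"plot-data"` writes one row per endpoint
#' (estimate and whisker bounds, fastest first) for external plotting.
#' `read_report_json()` rebuilds a `decline_report` from the JSON export;
#' the separation matrix is re-derived from the stored bounds, so a
#' round-trip is lossless.
#'
#' @param report A `decline_report`.
#' @param path Output file path.
#' @param format `"csv"`, `"json"` or `"plot-data"`.
#' @return `path`, invisibly (`read_report_json()`: a `decline_report`).
#' @export
export_report <- function(report, path, format = c("csv", "json",
                                                   "plot-data")) {
  stopifnot(inherits(report, "decline_report"))
  if (length(format) != 1L || !format %in% c("csv", "json", "plot-data"))
    stop("unknown format '", paste(format, collapse = ","),
         "': use csv, json or plot-data", call. = FALSE)
  tab <- report$table
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else if (format == "plot-data") {
    utils::write.csv(tab[, c("endpoint", "estimate", "ci_low", "ci_high")],
                     path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(table = tab,
                              separated = report$separated), path,
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(path)
}

#' @rdname export_report
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as.data.frame(x$table, stringsAsFactors = FALSE)
  structure(list(table = tab, separated = separation_matrix(tab)),
            class = "decline_report")
}

#' Serialize a fit, marginal effect or Monte Carlo result to JSON
#'
#' @param x A `spine_fit`, `marginal_effect`, `mc_result` or `mc_ci`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
to_json <- function(x, path = NULL) {
  lst <- if (inherits(x, "spine_fit")) {
    list(kind = x$kind, design = x$design, endpoint = x$endpoint,
         slope = x$slope, se = x$se_slope, intercept = x$intercept,
         loglik = x$loglik, n = x$n)
  } else if (inherits(x, "marginal_effect")) {
    list(endpoint = x$endpoint, estimate = x$estimate, se = x$se,
         ci_low = x$ci_low, ci_high = x$ci_high)
  } else if (inherits(x, "mc_result")) {
    list(endpoint = x$endpoint, iterations = x$iterations, n = x$n,
         b = as.list(x$b), se = as.list(x$se),
         rng = list(seed = x$rng$seed, stream = x$rng$stream))
  } else if (inherits(x, "mc_ci")) {
    list(endpoint = x$endpoint, point = x$point, ci_low = x$ci_low,
         ci_high = x$ci_high, method = x$method)
  } else stop("unsupported object of class ", class(x)[1], call. = FALSE)
  if (is.null(path))
    return(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
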