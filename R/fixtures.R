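#' Bundled reference tables of age-specific degeneration summaries
#'
#' Returns the published age-aggregated summaries the package analyses:
#' eight prevalence endpoints for degenerative features of the spinal column
#' in asymptomatic adults aged 20-59 (meta-analytic decade prevalences,
#' Brinjikji source), three continuous fat-infiltration endpoints across four
#' decades (Crawford source, n = 20 per decade) and four continuous
#' endpoints across two age groups 18-25 / 45-60 (Valentin source, n = 12
#' per group). Sample sizes that the source did not report (facet
#' degeneration and spondylolisthesis, 20s and 30s groups) are imputed as
#' n = 100 and flagged in `assumed_n`.
#'
#' Representative ages are pre-assigned with the package defaults:
#' equally spaced decade coding 25/35/45/55 for the decade-binned Brinjikji
#' and Crawford tables, and true group midpoints 21.5/52.5 for the
#' unequal-width Valentin groups.
#'
#' @param endpoint Optional endpoint name; if given, the single matching
#'   aggregate is returned.
#' @return A named list of 15 `spine_aggregate` objects (8 prevalence,
#'   7 continuous), or one aggregate when `endpoint` is given.
#' @examples
#' fx <- spine_fixtures()
#' names(fx)
#' spine_fixtures("disk degeneration")$groups
#' @export
spine_fixtures <- function(endpoint = NULL) {
  prev <- read_aggregate_csv(system.file("extdata", "table1_prevalence.csv",
                                         package = "spinedecline",
                                         mustWork = TRUE))
  cont <- read_aggregate_csv(system.file("extdata", "table1_continuous.csv",
                                         package = "spinedecline",
                                         mustWork = TRUE))
  prev <- lapply(prev, representative_ages, scheme = "decade")
  cont <- lapply(cont, function(a) {
    representative_ages(a, if (a$source == "Crawford") "decade" else
      "midpoint")
  })
  fx <- c(prev, cont)
  if (is.null(endpoint)) return(fx)
  if (!endpoint %in% names(fx))
    stop("unknown endpoint '", endpoint, "'; available: ",
         paste(names(fx), collapse = ", "), call. = FALSE)
  fx[[endpoint]]
}
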