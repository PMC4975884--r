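# minimal hand-built decline_rate stub for report-logic tests
stub_rate <- function(endpoint, est, lo, hi, method = "logistic-AME") {
  structure(list(endpoint = endpoint, source = "stub", method = method,
                 estimate = est, se = (hi - lo) / (2 * 1.96),
                 ci_low = lo, ci_high = hi, n = 10L),
            class = "decline_rate")
}

test_that("report rows sort by estimate and separation follows the CIs", {
  fits <- list(stub_rate("a", 1.0, 0.8, 1.2),
               stub_rate("b", 2.0, 1.5, 2.5),
               stub_rate("c", 0.3, 0.1, 0.5))
  rep <- decline_report(fits)
  expect_equal(rep$table$endpoint, c("b", "a", "c"))
  expect_true(rep$separated["b", "a"])    # 1.5 > 1.2
  expect_true(rep$separated["a", "c"])    # 0.8 > 0.5
  expect_false(rep$separated["a", "b"])   # asymmetric
  expect_false(any(diag(rep$separated)))

  same <- list(stub_rate("x", 1, 0.5, 1.5), stub_rate("y", 1, 0.5, 1.5))
  rs <- decline_report(same)
  expect_false(rs$separated["x", "y"] || rs$separated["y", "x"])

  expect_error(decline_report(list(stub_rate("a", 1, 0, 2),
                                   stub_rate("a", 2, 1, 3))),
               "duplicate endpoint")
})

test_that("separation uses 3-decimal rounded bounds", {
  # bounds that separate only after rounding ties are respected
  fits <- list(stub_rate("hi", 1, 0.5004, 1.5),
               stub_rate("lo", 0.2, 0.1, 0.5001))
  rep <- decline_report(fits)
  # round(0.5004,3)=0.5 vs round(0.5001,3)=0.5: not strictly greater
  expect_false(rep$separated["hi", "lo"])
  fits2 <- list(stub_rate("hi", 1, 0.5006, 1.5),
                stub_rate("lo", 0.2, 0.1, 0.5001))
  expect_true(decline_report(fits2)$separated["hi", "lo"])
})

test_that("report export round-trips and rejects unknown formats", {
  fits <- lapply(spine_fixtures()[c("disk bulge", "annular fissure",
                                    "spondylolisthesis")], decline_rate)
  rep <- decline_report(fits)

  jpath <- withr::local_tempfile(fileext = ".json")
  export_report(rep, jpath, "json")
  back <- read_report_json(jpath)
  expect_equal(back$table, rep$table, tolerance = 1e-12)
  expect_identical(back$separated, rep$separated)

  cpath <- withr::local_tempfile(fileext = ".csv")
  export_report(rep, cpath, "csv")
  tab <- utils::read.csv(cpath, stringsAsFactors = FALSE)
  expect_equal(tab$estimate, rep$table$estimate, tolerance = 1e-12)

  ppath <- withr::local_tempfile(fileext = ".csv")
  export_report(rep, ppath, "plot-data")
  pd <- utils::read.csv(ppath)
  expect_identical(nrow(pd), nrow(rep$table))
  expect_named(pd, c("endpoint", "estimate", "ci_low", "ci_high"))

  expect_error(export_report(rep, tempfile(), "yaml"), "unknown format")
})

test_that("the full pipeline covers all 15 endpoints, fastest to slowest", {
  rep <- run_pipeline(iterations = 150, seed = 5)
  expect_identical(nrow(rep$table), 15L)
  expect_identical(rep$table$endpoint[1], "disk signal loss")
  expect_identical(rep$table$endpoint[15], "Psoas (V)")
  expect_identical(sum(rep$table$method == "MC-gaussian"), 7L)
  # re-deriving separation from the stored table reproduces the matrix
  expect_identical(spinedecline:::separation_matrix(rep$table),
                   rep$separated)
})

test_that("the command-line interface is reproducible and pipeline-safe", {
  script <- file.path("..", "..", "scripts", "decline-cli.R")
  skip_if_not(file.exists(script), "CLI script not found relative to tests")
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run <- function(...) {
    out <- tempfile()
    err <- tempfile()
    status <- system2(rscript, c(script, shQuote(c(...))), stdout = out,
                      stderr = err, env = env)
    list(status = status, out = readLines(out), err = readLines(err))
  }

  r1 <- run("fit-prevalence", "--endpoint", "disk degeneration")
  expect_identical(r1$status, 0L)
  got <- jsonlite::fromJSON(paste(r1$out, collapse = "\n"))
  expect_equal(got$estimate, 1.429, tolerance = 5e-4)
  # logs go to stderr only; stdout is valid JSON
  expect_true(any(grepl("fitted", r1$err)))

  r2 <- run("fit-prevalence", "--endpoint", "disk degeneration")
  expect_identical(r1$out, r2$out)

  r3 <- run("mc-continuous", "--endpoint", "Psoas (V)",
            "--iterations", "50", "--seed", "4")
  r4 <- run("mc-continuous", "--endpoint", "Psoas (V)",
            "--iterations", "50", "--seed", "4")
  expect_identical(r3$status, 0L)
  expect_identical(r3$out, r4$out)

  r5 <- run("fit-prevalence", "--endpoint", "no such endpoint")
  expect_identical(r5$status, 1L)
  expect_true(any(grepl("unknown endpoint", r5$err)))
})
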