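test_that("the report orders scenarios and keeps its columns consistent", {
  ps <- small_ps()
  sc <- list(tax300_both = scenario_preset("tax300_both"),
             smokefree = scenario_preset("smokefree"))
  adt <- run_uncertainty(ps, sc,
                         uncertainty_spec(n_runs = 2,
                                          n_per_cohort = 200,
                                          master_seed = 3))
  rb <- build_report(adt)
  expect_s3_class(rb, "report_bundle")
  expect_equal(nrow(rb$comparison), 4)  # 2 scenarios x 2 causes
  # tobacco-control single measures come before tax combinations
  expect_equal(unique(rb$comparison$scenario),
               c("smokefree", "tax300_both"))
  expect_equal(rb$comparison$percent,
               100 * rb$comparison$averted / rb$comparison$baseline,
               tolerance = 1e-9)
  for (s in rb$shares) {
    # shares sum to one whenever any deaths were averted in the cause
    if (any(s$gender_location != 0)) {
      expect_equal(sum(s$gender_location), 1, tolerance = 1e-9)
    }
    if (any(s$age_band != 0)) {
      expect_equal(sum(s$age_band), 1, tolerance = 1e-9)
    }
  }
})

test_that("a baseline-only comparison reports zero averted deaths", {
  ps <- small_ps()
  adt <- run_uncertainty(ps, list(none = scenario_preset("none")),
                         uncertainty_spec(n_runs = 1,
                                          n_per_cohort = 150,
                                          master_seed = 2))
  expect_true(all(adt$table$averted == 0))
})

test_that("report regeneration from persisted results is lossless", {
  ps <- small_ps()
  adt <- run_uncertainty(ps,
                         list(smokefree = scenario_preset("smokefree")),
                         uncertainty_spec(n_runs = 2,
                                          n_per_cohort = 150,
                                          master_seed = 6))
  rb <- build_report(adt)
  out1 <- withr::local_tempdir()
  write_report(rb, out1)
  expect_true(file.exists(file.path(out1, "comparison.csv")))
  expect_true(file.exists(file.path(out1, "summary.json")))

  out2 <- withr::local_tempdir()
  status <- cli_main(c("report", "--in", out1, "--out", out2))
  expect_equal(status, 0L)
  a <- utils::read.csv(file.path(out1, "comparison.csv"))
  b <- utils::read.csv(file.path(out2, "comparison.csv"))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the CLI runs the pipeline end to end and rejects bad usage", {
  expect_equal(suppressMessages(cli_main(character())), 2L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 2L)
  expect_equal(suppressMessages(
    cli_main(c("run", "--params", file.path(tempdir(), "missing_dir"),
               "--out", tempdir()))), 2L)

  dir <- withr::local_tempdir()
  expect_equal(suppressMessages(
    cli_main(c("synth", "--seed", "1", "--out",
               file.path(dir, "params")))), 0L)
  expect_true(file.exists(file.path(dir, "params", "params.yaml")))

  out <- file.path(dir, "run")
  expect_equal(suppressMessages(
    cli_main(c("run", "--params", file.path(dir, "params"),
               "--scenario", "none", "--n", "100", "--seed", "3",
               "--out", out))), 0L)
  j <- jsonlite::read_json(file.path(out, "averted.json"),
                           simplifyVector = TRUE)
  expect_equal(j$mi$averted, 0)
  expect_equal(j$stroke$averted, 0)
})

test_that("per-year trend series aggregate the deaths array", {
  ps <- small_ps()
  res <- run_scenario(ps, scenario_preset("none"), 150, seed = 2)
  tr <- mortality_trend(res)
  expect_setequal(unique(tr$year), 2013:2022)
  expect_equal(sum(tr$deaths), sum(res$deaths))
})
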