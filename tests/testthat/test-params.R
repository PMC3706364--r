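test_that("default intervention effects carry the published central values and CIs", {
  eff <- default_intervention_effects()
  sf_pass <- eff[eff$name == "smokefree" & eff$target == "passive", ]
  expect_equal(sf_pass$central, 0.64)
  expect_equal(c(sf_pass$lo, sf_pass$hi), c(0.39, 0.89))
  sf_act <- eff[eff$name == "smokefree" & eff$target != "passive", ]
  expect_equal(sf_act$central, c(0.01, 0.01))
  expect_equal(sf_act$hi, c(0.02, 0.02))
  ban <- eff[eff$name == "ad_ban", ]
  expect_equal(unique(ban$central), 0.06)
  expect_equal(unique(ban$lo), 0.05)
  expect_equal(unique(ban$hi), 0.07)
  advice <- eff[eff$name == "brief_advice", ]
  expect_equal(unique(advice$central), 0.01)
  expect_equal(unique(advice$hi), 0.03)
  media <- eff[eff$name == "mass_media", ]
  expect_equal(unique(media$central), 0.05)
  expect_true(all(eff$lo <= eff$central & eff$central <= eff$hi))
})

test_that("a generated parameter set validates with no errors", {
  v <- validate_parameter_set(full_ps())
  expect_length(v$errors, 0)
  expect_length(v$warnings, 0)
})

test_that("validation flags bad tobacco probabilities and missing cohorts", {
  ps <- full_ps()
  ps$marginals$tob_never[3] <- ps$marginals$tob_never[3] + 0.2
  v <- validate_parameter_set(ps)
  expect_true(any(grepl("tobacco probabilities", v$errors)))

  ps2 <- full_ps()
  drop <- ps2$marginals$cohort_id != "70-79_female_rural"
  ps2$marginals <- ps2$marginals[drop, ]
  v2 <- validate_parameter_set(ps2)
  expect_true(any(grepl("70-79_female_rural", v2$errors)))
})

test_that("near-PSD correlation matrices are repaired with a bounded delta", {
  ps <- full_ps()
  # push the matrix just past PSD
  m <- ps$correlation
  m["sbp", "chol"] <- m["chol", "sbp"] <- 0.99
  m["sbp", "diabetes"] <- m["diabetes", "sbp"] <- 0.99
  m["chol", "diabetes"] <- m["diabetes", "chol"] <- -0.5
  expect_lt(min(eigen(m, symmetric = TRUE)$values), 0)
  rep <- tryCatch(nearest_psd(m, max_dist = 10), error = function(e) e)
  expect_false(inherits(rep, "error"))
  ev <- eigen(rep$matrix, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-9)
  expect_equal(unname(diag(rep$matrix)), rep(1, 6))
  expect_gt(rep$delta, 0)
  # default bound treats a gross repair as a data error
  expect_error(nearest_psd(m), "Frobenius")
})

test_that("save/load round-trips a parameter bundle identically", {
  ps <- small_ps()
  dir <- withr::local_tempdir()
  save_parameter_set(ps, dir)
  ps2 <- load_parameter_set(dir)
  for (field in c("cohorts", "marginals", "mortality",
                  "relative_risks", "quit_lag_months", "trends")) {
    expect_equal(ps2[[field]], ps[[field]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(ps2$correlation, ps$correlation, tolerance = 1e-12)
  expect_equal(ps2$tax$share, ps$tax$share)
  expect_equal(ps2$tax$elasticity$elasticity,
               ps$tax$elasticity$elasticity)
  expect_equal(ps2$medications$rrr$rrr, ps$medications$rrr$rrr)
  expect_equal(ps2$intervention_effects$central,
               ps$intervention_effects$central)
})

test_that("the loader names schema violations", {
  ps <- small_ps()
  dir <- withr::local_tempdir()
  save_parameter_set(ps, dir)

  mg <- utils::read.csv(file.path(dir, "marginals.csv"),
                        check.names = FALSE)
  names(mg)[names(mg) == "sbp_mean_mmHg"] <- "sbp_mean_kPa"
  utils::write.csv(mg, file.path(dir, "marginals.csv"),
                   row.names = FALSE)
  expect_error(load_parameter_set(dir), "sbp_mean_mmHg")

  save_parameter_set(ps, dir)
  mg <- utils::read.csv(file.path(dir, "marginals.csv"),
                        check.names = FALSE)
  mg <- mg[mg$cohort_id != "20-29_male_rural", ]
  utils::write.csv(mg, file.path(dir, "marginals.csv"),
                   row.names = FALSE)
  expect_error(load_parameter_set(dir), "20-29_male_rural")
})
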