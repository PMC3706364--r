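test_that("a single run collapses the interval to the point estimate", {
  ps <- small_ps()
  adt <- run_uncertainty(ps, list(tax300_both =
                                    scenario_preset("tax300_both")),
                         uncertainty_spec(n_runs = 1,
                                          n_per_cohort = 200,
                                          master_seed = 5))
  expect_equal(adt$table$lo, adt$table$averted)
  expect_equal(adt$table$hi, adt$table$averted)
})

test_that("the uncertainty layer is deterministic in its master seed", {
  ps <- small_ps()
  spec <- uncertainty_spec(n_runs = 3, n_per_cohort = 150,
                           master_seed = 9)
  sc <- list(smokefree = scenario_preset("smokefree"))
  a <- run_uncertainty(ps, sc, spec)
  b <- run_uncertainty(ps, sc, spec)
  expect_identical(a$table, b$table)
})

test_that("degenerate parameter CIs leave only outcome-sampling noise", {
  ps <- small_ps()
  # collapse every drawn parameter's CI onto its central value
  ie <- ps$intervention_effects
  ie$lo <- ie$central; ie$hi <- ie$central
  ps$intervention_effects <- ie
  ps$relative_risks$rr_lo <- ps$relative_risks$rr
  ps$relative_risks$rr_hi <- ps$relative_risks$rr
  ps$tax$elasticity$rel_halfwidth <- 0
  ps$medications$rrr$lo <- ps$medications$rrr$rrr
  ps$medications$rrr$hi <- ps$medications$rrr$rrr
  for (s in names(ps$medications$adherence)) {
    ps$medications$adherence_ci[[s]] <-
      rep(ps$medications$adherence[[s]], 2)
  }
  ps$cohorts$growth <- 0

  drawn <- draw_parameter_variant(ps, 5, 1)
  expect_equal(drawn$intervention_effects$central,
               ps$intervention_effects$central)
  expect_equal(drawn$relative_risks$rr, ps$relative_risks$rr)
  expect_equal(drawn$tax$elasticity$elasticity,
               ps$tax$elasticity$elasticity)

  sc <- list(tax = scenario_preset("tax300_both"))
  with_draws <- run_uncertainty(ps, sc,
                                uncertainty_spec(n_runs = 3,
                                                 n_per_cohort = 150,
                                                 master_seed = 2,
                                                 draw_params = TRUE))
  frozen <- run_uncertainty(ps, sc,
                            uncertainty_spec(n_runs = 3,
                                             n_per_cohort = 150,
                                             master_seed = 2,
                                             draw_params = FALSE))
  expect_equal(with_draws$table, frozen$table)
})

test_that("parameter draws stay inside their stated intervals and domains", {
  ps <- small_ps()
  for (r in 1:5) {
    d <- draw_parameter_variant(ps, 7, r)
    expect_true(all(d$intervention_effects$central >= 0 &
                      d$intervention_effects$central <= 1))
    expect_true(all(d$relative_risks$rr > 0))
    expect_true(all(d$tax$elasticity$elasticity > -2 &
                      d$tax$elasticity$elasticity < 0))
    expect_true(all(d$medications$rrr$rrr >= 0 &
                      d$medications$rrr$rrr <= 1))
    expect_true(all(d$medications$adherence >= 0 &
                      d$medications$adherence <= 1))
  }
  # distinct replicates draw distinct values
  d1 <- draw_parameter_variant(ps, 7, 1)
  d2 <- draw_parameter_variant(ps, 7, 2)
  expect_false(identical(d1$intervention_effects$central,
                         d2$intervention_effects$central))
})

test_that("nested tax doses keep their ordering across Monte Carlo runs", {
  ps <- full_ps()
  sc <- list(
    t50 = scenario_spec("tax", tax_increase = c(cigarette = 50,
                                                bidi = 50)),
    t300 = scenario_spec("tax", tax_increase = c(cigarette = 300,
                                                 bidi = 300)))
  adt <- run_uncertainty(ps, sc,
                         uncertainty_spec(n_runs = 2,
                                          n_per_cohort = 300,
                                          master_seed = 4))
  tab <- adt$table
  tot <- tapply(tab$averted, tab$scenario, sum)
  expect_lt(tot[["t50"]], tot[["t300"]])
})
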