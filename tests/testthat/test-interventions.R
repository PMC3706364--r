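test_that("combine_effects matches its closed forms", {
  expect_equal(combine_effects(numeric(), "cumulative"), 0)
  expect_equal(combine_effects(0.24, "cumulative"), 0.24)
  expect_equal(combine_effects(c(0.5, 0.5), "cumulative"), 0.75)
  expect_equal(combine_effects(c(0.04, 0.31), "max_only"), 0.31)

  # full cigarette-pathway package, direct product oracle
  e <- c(0.01, 0.01, 0.05, 0.06, 0.31)
  oracle <- 1 - (1 - e[1]) * (1 - e[2]) * (1 - e[3]) * (1 - e[4]) *
    (1 - e[5])
  expect_equal(combine_effects(e, "cumulative"), oracle,
               tolerance = 1e-12)
  expect_equal(combine_effects(e, "cumulative"), 0.3961, tolerance = 1e-4)

  oracle25 <- 1 - prod(1 - pmin(1, 1.25 * e))
  expect_equal(combine_effects(e, "synergy25"), oracle25,
               tolerance = 1e-12)
})

test_that("combine_effects is permutation-invariant and mode-ordered", {
  set.seed(21)
  for (i in 1:25) {
    e <- runif(sample(1:6, 1))
    perm <- sample(e)
    for (mode in c("max_only", "cumulative", "synergy25")) {
      expect_equal(combine_effects(e, mode), combine_effects(perm, mode))
      expect_lte(combine_effects(e, mode), 1)
    }
    expect_lte(combine_effects(e, "max_only"),
               combine_effects(e, "cumulative"))
    expect_lte(combine_effects(e, "cumulative"),
               combine_effects(e, "synergy25") + 1e-12)
  }
})

test_that("tax dose-response reproduces the published anchors", {
  expect_equal(tax_effect("bidi", "urban", 0), 0)
  expect_equal(tax_effect("cigarette", "rural", 0), 0)

  # closed form: bidi, rural, 50% increase
  expect_equal(tax_effect("bidi", "rural", 50), 0.92 * 0.09 * 0.5,
               tolerance = 1e-12)

  # all six published anchors within 3 percentage points after
  # location averaging
  anchors <- data.frame(
    product = rep(c("bidi", "cigarette"), each = 3),
    pct = rep(c(50, 300, 500), 2),
    published = c(0.04, 0.24, 0.40, 0.06, 0.31, 0.52))
  for (i in seq_len(nrow(anchors))) {
    got <- tax_effect(anchors$product[i], "average", anchors$pct[i])
    expect_lt(abs(got - anchors$published[i]), 0.03)
  }

  # nondecreasing and piecewise-linear in the increase
  grid <- seq(0, 900, by = 50)
  eff <- vapply(grid, function(x) tax_effect("cigarette", "rural", x), 0)
  expect_true(all(diff(eff) >= 0))
  lin <- eff < 1
  expect_equal(diff(eff[lin]) / diff(grid[seq_len(sum(lin))]),
               rep(0.34 * 0.38 / 100, sum(lin) - 1), tolerance = 1e-12)
})

test_that("coverage ramps and realized effect trajectories behave", {
  expect_equal(coverage_ramp("baseline_10yr_linear", 9), 1)
  expect_equal(coverage_ramp("baseline_10yr_linear", 0), 0.1)
  expect_equal(coverage_ramp("delayed_80pct_5yr", 9), 0.8)
  expect_equal(coverage_ramp("delayed_80pct_5yr", 2), 0.48)

  # baseline: immediate full legislative coverage, effect linear over
  # the decade
  expect_equal(vapply(0:9, function(y)
    effect_trajectory("baseline_10yr_linear", y), 0), (1:10) / 10)
  # delayed: strictly weaker in every year, 0.64 realized by year 9
  del <- vapply(0:9, function(y)
    effect_trajectory("delayed_80pct_5yr", y), 0)
  expect_true(all(del < (1:10) / 10))
  expect_equal(del[10], 0.64, tolerance = 1e-12)
  expect_true(all(diff(del) > 0))
})

test_that("quit benefit decays exponentially to its floor", {
  expect_equal(quit_benefit(2.0, 0), 2.0)
  expect_equal(quit_benefit(1.5, 19.1), 1 + 0.5 * exp(-1),
               tolerance = 1e-12)
  # floored at 10 years even though the raw value is slightly above 1
  expect_equal(quit_benefit(2.0, 120), 1.0)
  expect_gt(1 + (2 - 1) * exp(-120 / 19.1), 1)

  m <- seq(0, 119, by = 0.5)
  v <- quit_benefit(2.0, m)
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 1))
  # custom floor for dual users who only quit smoking
  expect_equal(quit_benefit(2.3, 1e6, floor = 1.3), 1.3)
})

test_that("scenario application hits its quit targets and is monotone", {
  ps <- small_ps()
  cid <- ps$cohorts$cohort_id[1]
  pop <- sample_profiles(cid, 20000, ps, seed = 3)

  # empty scenario: no change
  expect_identical(apply_tobacco_scenario(pop, scenario_preset("none"),
                                          3, ps), pop)

  # brief advice, full phase-in: ~1% of smokers quit (binomial tolerance)
  sc <- scenario_preset("brief_advice")
  p9 <- apply_tobacco_scenario(pop, sc, 9, ps)
  smokers <- pop$tobacco %in% c("cigarette", "bidi", "dual")
  quit <- smokers & (p9$tobacco != pop$tobacco)
  n_s <- sum(smokers)
  expect_lt(abs(sum(quit) - 0.01 * n_s), 4 * sqrt(0.01 * n_s) + 1)

  # smoke-free laws convert 64% * ramp of the passive-exposed
  sf <- scenario_preset("smokefree")
  p4 <- apply_tobacco_scenario(pop, sf, 4, ps)
  passive <- pop$tobacco == "passive"
  conv <- sum(p4$passive_removed[passive])
  target <- 0.64 * effect_trajectory("baseline_10yr_linear", 4)
  expect_lt(abs(conv - target * sum(passive)),
            4 * sqrt(target * sum(passive)) + 1)

  # monotone: cumulative quitting never reverses across years
  sc3 <- scenario_preset("tax300_both")
  prev_active <- sum(pop$tobacco %in% c("cigarette", "bidi", "dual"))
  cur <- pop
  for (y in 0:9) {
    cur <- apply_tobacco_scenario(cur, sc3, y, ps)
    act <- sum(cur$tobacco %in% c("cigarette", "bidi", "dual"))
    expect_lte(act, prev_active)
    prev_active <- act
  }
  # dual users who quit keep chewing and a decaying smoked excess
  exdual <- pop$tobacco == "dual" & cur$tobacco == "chewing"
  expect_true(all(!is.na(cur$months_since_quit[exdual])))
})
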