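test_that("individual relative risk composes per-factor multipliers", {
  ps <- small_ps()
  rr <- ps$relative_risks
  prof <- reference_profile()
  expect_equal(individual_rr(prof, rr, "mi"), 1)
  expect_equal(individual_rr(prof, rr, "stroke"), 1)

  # one binary factor present, everything else at reference
  rr2 <- rr
  rr2$rr[rr2$factor == "diabetes" & rr2$cause == "mi"] <- 2
  prof$diabetes <- TRUE
  rr2$rr[rr2$factor %in% c("sbp", "chol")] <- 1
  expect_equal(individual_rr(prof, rr2, "mi"), 2)

  # continuous factor: 20 mmHg above reference at RR 1.3 per 10 mmHg
  rr3 <- rr
  rr3$rr[rr3$factor == "sbp" & rr3$cause == "mi"] <- 1.3
  prof2 <- reference_profile()
  prof2$sbp <- 135
  expect_equal(individual_rr(prof2, rr3, "mi"), 1.3^2, tolerance = 1e-12)

  # active-smoker categories multiply in their per-state RR
  prof3 <- reference_profile()
  prof3$tobacco <- "cigarette"
  expect_equal(individual_rr(prof3, rr, "mi"),
               rr$rr[rr$factor == "tobacco_cigarette" & rr$cause == "mi"])
})

test_that("raising a risk factor with RR > 1 weakly raises both CVD risks", {
  ps <- small_ps()
  prof <- reference_profile()
  for (cs in c("mi", "stroke")) {
    base <- individual_rr(prof, ps$relative_risks, cs)
    up <- prof; up$sbp <- prof$sbp + 15
    expect_gte(individual_rr(up, ps$relative_risks, cs), base)
    dm <- prof; dm$diabetes <- TRUE
    expect_gte(individual_rr(dm, ps$relative_risks, cs), base)
    smk <- prof; smk$tobacco <- "bidi"
    expect_gte(individual_rr(smk, ps$relative_risks, cs), base)
  }
})

test_that("removing tobacco excess risk never raises individual risk", {
  ps <- small_ps()
  for (cat in c("cigarette", "bidi", "dual", "passive")) {
    prof <- reference_profile()
    prof$tobacco <- cat
    if (cat == "dual") prof$smoked_product <- "cigarette"
    before <- individual_rr(prof, ps$relative_risks, "mi")
    quit <- prof
    if (cat == "passive") {
      quit$passive_removed <- TRUE
      quit$months_since_passive <- 24
    } else if (cat == "dual") {
      quit$tobacco <- "chewing"
      quit$months_since_quit <- 24
    } else {
      quit$tobacco <- "former"
      quit$smoked_product <- cat
      quit$months_since_quit <- 24
    }
    expect_lte(individual_rr(quit, ps$relative_risks, "mi"), before)
    expect_gte(individual_rr(quit, ps$relative_risks, "mi"), 1)
  }
})

test_that("cause probabilities are calibrated to the cohort rate", {
  # identical profiles: everyone gets exactly the cohort rate
  p <- normalized_cause_probs(rep(2.5, 40), m_2013 = 0.01)
  expect_equal(p, rep(0.01, 40))

  # hand-computed normalization for a two-person cohort
  p2 <- normalized_cause_probs(c(1, 3), m_2013 = 0.01)
  expect_equal(p2, c(0.005, 0.015))

  # conservation to 1e-12 for heterogeneous RRs
  set.seed(11)
  rr <- rlnorm(5000, 0, 0.6)
  p3 <- normalized_cause_probs(rr, m_2013 = 0.007)
  expect_equal(mean(p3), 0.007, tolerance = 1e-12)

  # secular trend closed form: -2%/yr after two years
  p4 <- normalized_cause_probs(rep(1, 3), m_2013 = 0.01, trend = -0.02,
                               year_index = 2)
  expect_equal(p4, rep(0.01 * 0.98^2, 3), tolerance = 1e-12)

  # scaling past 1 clamps with a warning
  expect_warning(pc <- normalized_cause_probs(c(1, 1000), 0.5,
                                              rr_reference = c(1, 1)),
                 "clamped")
  expect_lte(max(pc), 0.999)
})

test_that("a reference population keeps intervention benefit from being normalized away", {
  rr_scenario <- c(1, 1, 2, 2)   # two smokers quit: RR halves for them
  rr_reference <- c(1, 1, 4, 4)
  p <- normalized_cause_probs(rr_scenario, m_2013 = 0.01,
                              rr_reference = rr_reference)
  expect_lt(mean(p), 0.01)
  expect_equal(mean(p), 0.01 * mean(rr_scenario) / mean(rr_reference),
               tolerance = 1e-12)
})
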