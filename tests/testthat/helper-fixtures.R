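# Shared fixtures, built once per test run. All synthetic: the generator
# is itself under test elsewhere.

fixture_env <- new.env()

full_ps <- function() {
  if (is.null(fixture_env$full)) {
    fixture_env$full <- generate_parameter_set(synthetic_spec(seed = 7))
  }
  fixture_env$full
}

small_ps <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- generate_fixture(n_cohorts = 4, seed = 7)
  }
  fixture_env$small
}

# a deliberately homogeneous parameter set: every relative risk 1, so the
# population is risk-homogeneous and binomial expectations are exact
flat_rr_ps <- function(m_mi = 0.01) {
  ps <- generate_fixture(n_cohorts = 1, seed = 7)
  ps$relative_risks$rr <- 1
  ps$relative_risks$rr_lo <- 1
  ps$relative_risks$rr_hi <- 1
  ps$mortality$rate[ps$mortality$cause == "mi"] <- m_mi
  ps$trends$risk_factors[] <- 0
  ps$trends$mortality[] <- 0
  ps
}

# a reference profile at all reference values, never-user
reference_profile <- function() {
  data.frame(age = 45, sbp = 115, chol = 3.8, diabetes = FALSE,
             chd_hist = FALSE, cvd_hist = FALSE, tobacco = "never",
             smoked_product = NA_character_,
             months_since_quit = NA_real_, passive_removed = FALSE,
             months_since_passive = NA_real_, alive = TRUE,
             stringsAsFactors = FALSE)
}
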