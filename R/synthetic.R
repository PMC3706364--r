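#' Synthetic India-like parameter sets
#'
#' Real WHO/GATS risk-factor tables are not redistributable and are not
#' shipped; this generator emulates their statistical structure so the whole
#' pipeline is testable offline: 24 cohorts, normal blood-pressure and
#' cholesterol marginals rising with age, binary disease prevalences
#' rising with age and higher in urban cohorts, a 7-category tobacco
#' variable with male and urban use highest, a positive-definite
#' risk-factor correlation matrix, cause-specific mortality rising with
#' age (largest absolute CVD death burden in the 60-69 band), mild upward
#' secular trends in metabolic risk factors and CVD mortality, and the
#' published intervention-effect, taxation and quit-lag constants. The
#' numeric prevalence levels are emulation, not survey estimates.
#'
#' @name synthetic_params
NULL

#' Specification for the synthetic generator
#'
#' @param seed integer seed; a fixed seed gives identical parameter sets.
#' @param scale multiplier on cohort census sizes.
#' @param n_cohorts number of cohorts to keep (1-24); subsets are for fast
#'   unit tests and are taken in `cohort_keys()` order.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, scale = 1, n_cohorts = 24L) {
  stopifnot(n_cohorts >= 1L, n_cohorts <= 24L, scale > 0)
  structure(list(seed = as.integer(seed), scale = scale,
                 n_cohorts = as.integer(n_cohorts)),
            class = "synthetic_spec")
}

# Band census sizes (persons, both genders and locations combined are split
# below); shaped like a developing-country age pyramid.
.band_census <- c("20-29" = 230e6, "30-39" = 190e6, "40-49" = 150e6,
                  "50-59" = 110e6, "60-69" = 70e6, "70-79" = 30e6)

.tobacco_base <- list(
  male_urban   = c(never = 0.41, passive = 0.12, former = 0.05,
                   cigarette = 0.18, bidi = 0.08, chewing = 0.10,
                   dual = 0.06),
  male_rural   = c(never = 0.44, passive = 0.10, former = 0.04,
                   cigarette = 0.07, bidi = 0.17, chewing = 0.12,
                   dual = 0.06),
  female_urban = c(never = 0.72, passive = 0.15, former = 0.01,
                   cigarette = 0.02, bidi = 0.01, chewing = 0.08,
                   dual = 0.01),
  female_rural = c(never = 0.70, passive = 0.14, former = 0.01,
                   cigarette = 0.005, bidi = 0.025, chewing = 0.10,
                   dual = 0.02))

#' Generate a full synthetic parameter set
#'
#' Deterministic given `spec$seed`; every generated set passes
#' [validate_parameter_set()] with zero errors. Attaches the published
#' intervention-effect table ([default_intervention_effects()]), tax
#' shares 0.38/0.09 with elasticities (cigarette -0.34 rural / -0.19
#' urban; bidi -0.92 rural / -0.85 urban), the default medication policy
#' and the 19.1-month quit lag.
#'
#' @param spec a [synthetic_spec()].
#' @return a validated `parameter_set`.
#' @export
generate_parameter_set <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$scale <= 0) stop("degenerate spec: zero or negative populations")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$seed)

  keys <- cohort_keys()
  keys <- keys[seq_len(spec$n_cohorts), , drop = FALSE]
  band_idx <- match(keys$age_band, AGE_BANDS) - 1L

  # census split: males 52%, urban 35% of each band, small seeded jitter
  split <- ifelse(keys$gender == "male", 0.52, 0.48) *
    ifelse(keys$location == "urban", 0.35, 0.65)
  jitter <- stats::runif(nrow(keys), 0.97, 1.03)
  cohorts <- data.frame(
    keys,
    census = .band_census[keys$age_band] * split * jitter * spec$scale,
    growth = 0.012,
    row.names = NULL)

  male <- keys$gender == "male"
  urban <- keys$location == "urban"
  marginals <- data.frame(
    cohort_id = keys$cohort_id,
    sbp_mean = 118 + 3.2 * band_idx + 2 * male + 2 * urban +
      stats::rnorm(nrow(keys), 0, 0.5),
    sbp_sd = 14,
    chol_mean = 4.4 + 0.15 * band_idx + 0.3 * urban +
      stats::rnorm(nrow(keys), 0, 0.05),
    chol_sd = 0.9,
    diabetes_prev = pmin(0.35, (0.02 + 0.016 * band_idx) *
                           ifelse(urban, 1.5, 1.0)),
    chd_prev = pmin(0.2, c(0.002, 0.005, 0.012, 0.03, 0.06,
                           0.09)[band_idx + 1L] *
                     ifelse(urban, 1.2, 1.0) * ifelse(male, 1.2, 0.9)),
    cvd_hist_prev = pmin(0.15, c(0.001, 0.003, 0.006, 0.015, 0.03,
                                 0.05)[band_idx + 1L] *
                          ifelse(urban, 1.1, 1.0)),
    row.names = NULL)
  tob <- t(vapply(paste(keys$gender, keys$location, sep = "_"),
                  function(k) .tobacco_base[[k]],
                  numeric(length(TOBACCO_CATEGORIES))))
  tob <- tob / rowSums(tob)
  colnames(tob) <- tobacco_prob_cols()
  marginals <- cbind(marginals, as.data.frame(tob, row.names = NULL))

  correlation <- matrix(c(
    #      sbp   chol  dm    chd   cvd   tob
    1.00, 0.20, 0.15, 0.10, 0.10, 0.05,
    0.20, 1.00, 0.10, 0.10, 0.05, 0.00,
    0.15, 0.10, 1.00, 0.15, 0.10, 0.00,
    0.10, 0.10, 0.15, 1.00, 0.20, 0.05,
    0.10, 0.05, 0.10, 0.20, 1.00, 0.05,
    0.05, 0.00, 0.00, 0.05, 0.05, 1.00), 6, 6, byrow = TRUE,
    dimnames = list(RISK_FACTORS, RISK_FACTORS))

  relative_risks <- synthetic_relative_risks()

  # annual death rates, rising with age; MI > stroke; male and urban excess
  mi_base <- c(2e-4, 6e-4, 1.8e-3, 4.5e-3, 1.1e-2, 2.2e-2)
  stroke_base <- c(1.2e-4, 3.6e-4, 1.1e-3, 2.9e-3, 7.5e-3, 1.6e-2)
  other_base <- c(2e-3, 3e-3, 5e-3, 1.0e-2, 2.5e-2, 6.0e-2)
  gmul <- ifelse(male, 1.3, 0.85)
  lmul <- ifelse(urban, 1.15, 0.95)
  mortality <- rbind(
    data.frame(cohort_id = keys$cohort_id, cause = "mi",
               rate = mi_base[band_idx + 1L] * gmul * lmul),
    data.frame(cohort_id = keys$cohort_id, cause = "stroke",
               rate = stroke_base[band_idx + 1L] * gmul * lmul),
    data.frame(cohort_id = keys$cohort_id, cause = "other",
               rate = other_base[band_idx + 1L]))
  rownames(mortality) <- NULL

  trends <- list(
    risk_factors = c(sbp = 0.003, chol = 0.003, diabetes = 0.02,
                     chd_hist = 0.01, cvd_hist = 0.01, tobacco = 0),
    mortality = c(mi = 0.015, stroke = 0.010, other = -0.005))

  ps <- new_parameter_set(
    cohorts = cohorts, marginals = marginals, correlation = correlation,
    relative_risks = relative_risks, mortality = mortality,
    trends = trends,
    intervention_effects = default_intervention_effects(),
    tax = default_tax_parameters(),
    medications = default_medication_policy(),
    quit_lag_months = 19.1)
  if (spec$n_cohorts < 24L) attr(ps, "partial") <- TRUE
  v <- validate_parameter_set(ps)
  if (length(v$errors)) {
    stop("synthetic generator produced an invalid parameter set:\n  ",
         paste(v$errors, collapse = "\n  "))
  }
  ps
}

# Relative risks of MI/stroke death per risk factor. Continuous factors
# are per-unit (10 mmHg above 115 for sbp; 1 mmol/l above 3.8 for
# cholesterol); tobacco categories are per-state. rr_lo/rr_hi bound the
# Monte Carlo draws.
synthetic_relative_risks <- function() {
  rr <- function(factor, cause, rr, unit = NA_real_,
                 reference = NA_real_) {
    data.frame(factor = factor, cause = cause, rr = rr,
               rr_lo = rr * 0.85, rr_hi = rr * 1.15,
               unit = unit, reference = reference)
  }
  out <- rbind(
    rr("sbp", "mi", 1.25, unit = 10, reference = 115),
    rr("sbp", "stroke", 1.35, unit = 10, reference = 115),
    rr("chol", "mi", 1.30, unit = 1, reference = 3.8),
    rr("chol", "stroke", 1.10, unit = 1, reference = 3.8),
    rr("diabetes", "mi", 2.0), rr("diabetes", "stroke", 1.8),
    rr("chd_hist", "mi", 3.0), rr("chd_hist", "stroke", 1.5),
    rr("cvd_hist", "mi", 1.5), rr("cvd_hist", "stroke", 3.0),
    rr("tobacco_passive", "mi", 1.25), rr("tobacco_passive", "stroke", 1.2),
    rr("tobacco_cigarette", "mi", 2.0), rr("tobacco_cigarette", "stroke", 1.8),
    rr("tobacco_bidi", "mi", 1.9), rr("tobacco_bidi", "stroke", 1.7),
    rr("tobacco_chewing", "mi", 1.3), rr("tobacco_chewing", "stroke", 1.25),
    rr("tobacco_dual", "mi", 2.3), rr("tobacco_dual", "stroke", 2.0))
  # never-users and the 'former' category are handled through the quit-lag
  # decay of the quit product's RR; reference multiplier is 1.
  rownames(out) <- NULL
  out
}

#' Generate a reduced synthetic fixture
#'
#' Same generator, keeping only the first `n_cohorts` cohorts (in
#' `cohort_keys()` order) for fast unit tests. With `n_cohorts = 24` the
#' result equals [generate_parameter_set()] on the matched spec.
#'
#' @param n_cohorts integer in 1..24.
#' @param seed integer seed.
#' @param scale census multiplier.
#' @return a validated `parameter_set`.
#' @export
generate_fixture <- function(n_cohorts = 2L, seed = 1L, scale = 1) {
  generate_parameter_set(synthetic_spec(seed = seed, scale = scale,
                                        n_cohorts = n_cohorts))
}
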