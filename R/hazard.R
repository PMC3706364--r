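#' Hazard layer: from risk profile to annual death probabilities
#'
#' Each alive individual's relative risk (RR) of MI death and stroke death
#' is the product of per-factor multipliers: continuous factors contribute
#' `rr^((x - reference)/unit)`, binary factors contribute their per-state
#' RR when present, and tobacco contributes the category RR -- decayed by
#' the quit lag for former users. Cause probabilities are the cohort's
#' (trend-scaled) mortality rate scaled by each person's RR and normalized
#' by the mean RR over the reference (intervention-free) population, so
#' simulated cohort mortality is calibrated to the input rates. Annual
#' rates are small, so the rate-to-probability conversion is taken as the
#' identity.
#'
#' @name hazard
NULL

rr_lookup <- function(rr_table, cause) {
  sub <- rr_table[rr_table$cause == cause, ]
  out <- stats::setNames(sub$rr, sub$factor)
  attr(out, "unit") <- stats::setNames(sub$unit, sub$factor)
  attr(out, "reference") <- stats::setNames(sub$reference, sub$factor)
  out
}

# Tobacco RR per person (vectorized). Former users (and ex-passive, and
# dual users who lost the smoked component) carry an exponentially
# decaying residual: floor + (full - floor) * exp(-months/tau), hard
# floor after 120 months.
tobacco_rr_vec <- function(pop, rr, tau) {
  rr_of <- function(cat) {
    v <- rr[[paste0("tobacco_", cat)]]
    if (is.null(v) || is.na(v)) 1 else v
  }
  cat_rr <- c(never = 1, passive = rr_of("passive"), former = 1,
              cigarette = rr_of("cigarette"), bidi = rr_of("bidi"),
              chewing = rr_of("chewing"), dual = rr_of("dual"))
  out <- unname(cat_rr[pop$tobacco])

  former <- pop$tobacco == "former"
  if (any(former)) {
    full <- ifelse(pop$smoked_product[former] == "bidi",
                   rr_of("bidi"), rr_of("cigarette"))
    out[former] <- quit_benefit(full, pop$months_since_quit[former],
                                tau = tau)
  }
  # ex-dual users: category has become "chewing" but the smoked excess
  # decays from the dual RR down to the chewing RR
  exdual <- pop$tobacco == "chewing" & !is.na(pop$months_since_quit)
  if (any(exdual)) {
    out[exdual] <- quit_benefit(rr_of("dual"),
                                pop$months_since_quit[exdual],
                                tau = tau, floor = rr_of("chewing"))
  }
  # formerly passive-exposed (smoke-free laws): excess decays to 1
  expass <- pop$tobacco == "passive" & pop$passive_removed
  if (any(expass)) {
    out[expass] <- quit_benefit(rr_of("passive"),
                                pop$months_since_passive[expass],
                                tau = tau)
  }
  out
}

#' Individual relative risk for one cause
#'
#' @param profile one profile (list or one-row data.frame) as produced by
#'   [sample_profiles()].
#' @param rr_table the parameter set's `relative_risks` table.
#' @param cause "mi" or "stroke".
#' @param tau quit-lag time constant in months.
#' @return scalar multiplier (1 at all reference values for a never-user).
#' @export
individual_rr <- function(profile, rr_table, cause, tau = 19.1) {
  individual_rr_vec(as.data.frame(profile), rr_table, cause, tau)
}

# Vectorized RR over the population data.frame.
individual_rr_vec <- function(pop, rr_table, cause, tau = 19.1) {
  rr <- rr_lookup(rr_table, cause)
  unit <- attr(rr, "unit")
  ref <- attr(rr, "reference")
  out <- rep(1, nrow(pop))
  if (!is.na(rr["sbp"])) {
    out <- out * rr[["sbp"]]^((pop$sbp - ref[["sbp"]]) / unit[["sbp"]])
  }
  if (!is.na(rr["chol"])) {
    out <- out * rr[["chol"]]^((pop$chol - ref[["chol"]]) / unit[["chol"]])
  }
  for (b in c("diabetes", "chd_hist", "cvd_hist")) {
    if (!is.na(rr[b])) out <- out * ifelse(pop[[b]], rr[[b]], 1)
  }
  out * tobacco_rr_vec(pop, rr, tau)
}

#' Cohort-calibrated cause probabilities
#'
#' `p_cause(i) = m(year) * rr[i] / mean(rr_reference over alive)`, with
#' `m(year) = m_2013 * (1 + trend_cause)^(year - 2013)`. With
#' `rr_reference = rr` (the default) the alive-population mean of
#' `p_cause` equals the cohort rate exactly -- the calibration identity.
#' Scenario runs pass the intervention-free RRs as the reference so that
#' intervention benefits are measured against the calibrated baseline
#' scale rather than being normalized away. Other-cause death uses no
#' individual RR. Probabilities reaching 1 after scaling are clamped to
#' 0.999 with a warning.
#'
#' @param rr numeric vector of individual RRs (alive individuals).
#' @param m_2013 cohort annual death rate for the cause in 2013.
#' @param trend annual proportional change in the rate.
#' @param year_index 0-based year (0 = 2013).
#' @param rr_reference RRs defining the normalizing mean (defaults to
#'   `rr`).
#' @return numeric vector of annual death probabilities.
#' @export
normalized_cause_probs <- function(rr, m_2013, trend = 0, year_index = 0,
                                   rr_reference = rr) {
  if (!length(rr)) return(numeric())
  m <- m_2013 * (1 + trend)^year_index
  p <- m * rr / mean(rr_reference)
  if (any(p >= 1)) {
    warning(sprintf(
      "cause probability >= 1 for %d individual(s) (year_index=%d); clamped to 0.999",
      sum(p >= 1), year_index))
    p[p >= 1] <- 0.999
  }
  p
}
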