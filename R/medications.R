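#' Pharmacological comparator: aspirin, antihypertensives, statins
#'
#' A `medication_policy` is a list describing eligibility thresholds,
#' per-class per-cause annual relative risk reductions (RRR) with 95% CIs,
#' adherence by history stratum, and the linear coverage-expansion path.
#'
#' @name medications
NULL

DRUG_CLASSES <- c("aspirin", "antihypertensive", "statin")

#' Default medication policy
#'
#' Eligibility: aspirin for those with coronary or cerebrovascular disease
#' history; statins for total cholesterol at or above 5.2 mmol/l or
#' history; antihypertensives for systolic blood pressure at or above
#' 140 mmHg or history (the regimen differs by history -- ACE inhibitor
#' plus thiazide without history, beta-blocker added with history -- but
#' shares one effect size). Adherence is 40% (95% CI 20%-60%) without
#' history and 60% (40%-80%) with history. Coverage expands linearly from
#' 15% to 45% over the 10 simulated years ("who_45pct"); the "who_80pct"
#' preset ends at 80%. Per-class RRR values are synthetic
#' literature-plausible placeholders (no trial-derived table is bundled)
#' and are configurable.
#'
#' @param preset "who_45pct" (default) or "who_80pct".
#' @return a `medication_policy` list.
#' @export
default_medication_policy <- function(preset = c("who_45pct", "who_80pct")) {
  preset <- match.arg(preset)
  rrr <- rbind(
    data.frame(class = "aspirin", cause = c("mi", "stroke"),
               rrr = c(0.23, 0.10), lo = c(0.13, 0.04), hi = c(0.33, 0.16)),
    data.frame(class = "antihypertensive", cause = c("mi", "stroke"),
               rrr = c(0.16, 0.38), lo = c(0.08, 0.28), hi = c(0.24, 0.48)),
    data.frame(class = "statin", cause = c("mi", "stroke"),
               rrr = c(0.30, 0.12), lo = c(0.20, 0.04), hi = c(0.40, 0.20)))
  rownames(rrr) <- NULL
  pol <- list(
    rrr = rrr,
    adherence = c(no_history = 0.40, history = 0.60),
    adherence_ci = list(no_history = c(0.20, 0.60),
                        history = c(0.40, 0.80)),
    coverage_start = 0.15,
    coverage_end = if (preset == "who_80pct") 0.80 else 0.45,
    coverage_years = 10,
    chol_threshold = 5.2,   # mmol/l
    sbp_threshold = 140,    # mmHg
    multiplier_floor = 0.1,
    preset = preset)
  class(pol) <- "medication_policy"
  pol
}

validate_medication_policy <- function(pol) {
  errors <- character()
  if (is.null(pol)) return("medication policy missing")
  r <- pol$rrr
  if (any(r$rrr < 0 | r$rrr > 1 | r$lo < 0 | r$hi > 1 | r$lo > r$rrr |
            r$rrr > r$hi)) {
    errors <- c(errors, "medication RRR CIs out of order or outside [0,1]")
  }
  if (any(pol$adherence < 0 | pol$adherence > 1)) {
    errors <- c(errors, "medication adherence outside [0,1]")
  }
  if (pol$coverage_end < pol$coverage_start ||
        pol$coverage_start < 0 || pol$coverage_end > 1) {
    errors <- c(errors, "medication coverage path must be nondecreasing in [0,1]")
  }
  errors
}

#' Medication coverage at a simulation year
#'
#' Linear expansion from `coverage_start` to `coverage_end` over
#' `coverage_years` annual cycles: year index 9 reaches the endpoint under
#' the default 10-year path.
#'
#' @param policy a `medication_policy`.
#' @param year_index 0-based year of the simulation.
#' @return coverage fraction in [0,1].
#' @export
medication_coverage <- function(policy, year_index) {
  frac <- pmin(1, (year_index + 1) / policy$coverage_years)
  policy$coverage_start +
    (policy$coverage_end - policy$coverage_start) * frac
}

#' Drug-class eligibility for one risk profile
#'
#' @param profile list or one-row data.frame with `sbp`, `chol`,
#'   `chd_hist`, `cvd_hist`.
#' @param policy a `medication_policy`.
#' @return character vector of eligible drug classes (possibly empty).
#' @export
eligible <- function(profile, policy) {
  history <- isTRUE(as.logical(profile$chd_hist)) ||
    isTRUE(as.logical(profile$cvd_hist))
  out <- character()
  if (history) out <- c(out, "aspirin")
  if (history || profile$chol >= policy$chol_threshold) {
    out <- c(out, "statin")
  }
  if (history || profile$sbp >= policy$sbp_threshold) {
    out <- c(out, "antihypertensive")
  }
  intersect(DRUG_CLASSES, out)
}

# Vectorized eligibility over the engine's population data.frame.
# Returns a logical matrix persons x DRUG_CLASSES.
eligibility_matrix <- function(pop, policy) {
  history <- pop$chd_hist | pop$cvd_hist
  cbind(aspirin = history,
        antihypertensive = history | pop$sbp >= policy$sbp_threshold,
        statin = history | pop$chol >= policy$chol_threshold)
}

#' Per-cause hazard multiplier from medication treatment
#'
#' A person is covered with probability equal to the year's coverage and
#' adherent with the stratum's adherence probability; both are person-level
#' Bernoulli draws fixed at assignment (`u_cov`, `u_adh` uniforms drawn
#' once from the medication stream). If covered and adherent, the
#' multiplier is `1 - sum(RRR)` over the person's eligible classes
#' (additive RRR stacking), floored at `policy$multiplier_floor`;
#' otherwise 1.
#'
#' @param profile list/one-row data.frame with `sbp`, `chol`, `chd_hist`,
#'   `cvd_hist`, `u_cov`, `u_adh`.
#' @param policy a `medication_policy`.
#' @param year_index 0-based simulation year.
#' @param cause "mi" or "stroke".
#' @return multiplier in [floor, 1].
#' @export
medication_multiplier <- function(profile, policy, year_index, cause) {
  classes <- eligible(profile, policy)
  if (!length(classes)) return(1)
  covered <- profile$u_cov < medication_coverage(policy, year_index)
  stratum <- if (isTRUE(as.logical(profile$chd_hist)) ||
                   isTRUE(as.logical(profile$cvd_hist))) "history"
             else "no_history"
  adherent <- profile$u_adh < policy$adherence[[stratum]]
  if (!covered || !adherent) return(1)
  r <- policy$rrr
  tot <- sum(r$rrr[r$cause == cause & r$class %in% classes])
  if (tot > 0.9) {
    warning("summed medication RRR ", format(tot),
            " exceeds 0.9; flooring multiplier")
  }
  max(policy$multiplier_floor, 1 - tot)
}

# Vectorized multiplier used by the engine: pop is the population
# data.frame with u_cov/u_adh columns. Returns numeric vector.
medication_multiplier_vec <- function(pop, policy, year_index, cause) {
  n <- nrow(pop)
  if (is.null(policy) || n == 0L) return(rep(1, n))
  elig <- eligibility_matrix(pop, policy)
  history <- pop$chd_hist | pop$cvd_hist
  adh <- ifelse(history, policy$adherence[["history"]],
                policy$adherence[["no_history"]])
  on_treat <- (pop$u_cov < medication_coverage(policy, year_index)) &
    (pop$u_adh < adh)
  r <- policy$rrr[policy$rrr$cause == cause, ]
  rrr <- stats::setNames(r$rrr, r$class)[DRUG_CLASSES]
  tot <- as.numeric(elig %*% ifelse(is.na(rrr), 0, rrr))
  mult <- rep(1, n)
  idx <- on_treat & tot > 0
  mult[idx] <- pmax(policy$multiplier_floor, 1 - tot[idx])
  mult
}
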