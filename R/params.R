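#' Parameter model
#'
#' A `parameter_set` is a plain list with class `"parameter_set"` holding
#' everything the simulator needs:
#' \describe{
#'   \item{cohorts}{data.frame: `cohort_id`, `age_band`, `gender`,
#'     `location`, `census` (persons in 2013), `growth` (annual
#'     proportional census growth).}
#'   \item{marginals}{data.frame keyed by `cohort_id`: `sbp_mean`, `sbp_sd`
#'     (mmHg), `chol_mean`, `chol_sd` (mmol/l), `diabetes_prev`,
#'     `chd_prev`, `cvd_hist_prev`, and `tob_<category>` columns for the
#'     seven tobacco categories.}
#'   \item{correlation}{6x6 correlation matrix over `RISK_FACTORS`.}
#'   \item{relative_risks}{data.frame: `factor`, `cause`, `rr`, `rr_lo`,
#'     `rr_hi`, `unit`, `reference`. Continuous factors contribute
#'     `rr^((x - reference)/unit)`; binary and tobacco-category factors
#'     contribute `rr` when the state is present.}
#'   \item{mortality}{data.frame: `cohort_id`, `cause`, `rate` (annual
#'     probability of death in 2013).}
#'   \item{trends}{list with `risk_factors` (named annual proportional
#'     change per factor) and `mortality` (named per cause).}
#'   \item{intervention_effects}{data.frame of the five tobacco-control
#'     measures: `name`, `target` (exposure channel), `central`, `lo`,
#'     `hi`.}
#'   \item{tax}{list: `share` (tax share of retail price per product) and
#'     `elasticity` (per product x location, negative).}
#'   \item{medications}{a `medication_policy`, see
#'     [default_medication_policy()].}
#'   \item{quit_lag_months}{time constant of the exponential decay of
#'     excess cardiovascular risk after quitting (months).}
#' }
#'
#' @name parameter_set
NULL

new_parameter_set <- function(cohorts, marginals, correlation,
                              relative_risks, mortality, trends,
                              intervention_effects, tax, medications,
                              quit_lag_months = 19.1) {
  ps <- list(cohorts = cohorts, marginals = marginals,
             correlation = correlation, relative_risks = relative_risks,
             mortality = mortality, trends = trends,
             intervention_effects = intervention_effects, tax = tax,
             medications = medications,
             quit_lag_months = quit_lag_months)
  class(ps) <- "parameter_set"
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  cohorts:           ", nrow(x$cohorts), "\n")
  cat("  census total:      ", format(sum(x$cohorts$census), big.mark = ","),
      "persons\n")
  cat("  risk factors:      ", paste(RISK_FACTORS, collapse = ", "), "\n")
  cat("  interventions:     ",
      paste(unique(x$intervention_effects$name), collapse = ", "), "\n")
  cat("  quit-lag tau:      ", x$quit_lag_months, "months\n")
  invisible(x)
}

#' Default tobacco-control intervention effects
#'
#' The five FCTC measures with their central prevalence-reduction fractions
#' and 95% CIs. Smoke-free laws act on the passive-exposure channel (64%,
#' 39-89%) and weakly on both active-smoking channels (1%, 0-2%); brief
#' cessation advice (1%, 0-3%), mass media campaigns (5%, 1-11%) and an
#' advertising ban (6%, 5-7%) act on both active channels. Tax effects are
#' computed mechanistically by [tax_effect()] and are not listed here.
#'
#' @return data.frame with columns `name`, `target` (one of
#'   `active_cigarette`, `active_bidi`, `passive`), `central`, `lo`, `hi`.
#' @export
default_intervention_effects <- function() {
  eff <- rbind(
    data.frame(name = "smokefree", target = "passive",
               central = 0.64, lo = 0.39, hi = 0.89),
    data.frame(name = "smokefree", target = c("active_cigarette",
                                              "active_bidi"),
               central = 0.01, lo = 0.00, hi = 0.02),
    data.frame(name = "brief_advice", target = c("active_cigarette",
                                                 "active_bidi"),
               central = 0.01, lo = 0.00, hi = 0.03),
    data.frame(name = "mass_media", target = c("active_cigarette",
                                               "active_bidi"),
               central = 0.05, lo = 0.01, hi = 0.11),
    data.frame(name = "ad_ban", target = c("active_cigarette",
                                           "active_bidi"),
               central = 0.06, lo = 0.05, hi = 0.07))
  rownames(eff) <- NULL
  eff
}

#' Default taxation parameters
#'
#' Tax share of retail price (cigarettes 38%, bidis 9%) and price
#' elasticities of consumption (cigarettes: -0.34 rural / -0.19 urban;
#' bidis: -0.92 rural / -0.85 urban), with a relative half-width used when
#' elasticities are drawn in Monte Carlo replicates.
#'
#' @return list with elements `share` and `elasticity`.
#' @export
default_tax_parameters <- function() {
  list(share = c(cigarette = 0.38, bidi = 0.09),
       elasticity = data.frame(
         product = c("cigarette", "cigarette", "bidi", "bidi"),
         location = c("rural", "urban", "rural", "urban"),
         elasticity = c(-0.34, -0.19, -0.92, -0.85),
         rel_halfwidth = 0.2))
}

#' Nearest positive-semidefinite repair of a correlation matrix
#'
#' Eigenvalues below zero are clipped to zero and the matrix is rescaled
#' back to unit diagonal. Printed supplementary matrices are often rounded
#' just past PSD; a repair moving the matrix further than Frobenius
#' distance 0.05 is treated as a data error.
#'
#' @param m square symmetric matrix.
#' @param max_dist maximum allowed Frobenius distance of the repair.
#' @return list `matrix` (repaired), `delta` (Frobenius distance),
#'   `repaired` (logical).
#' @export
nearest_psd <- function(m, max_dist = 0.05) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) >= -1e-12) {
    return(list(matrix = m, delta = 0, repaired = FALSE))
  }
  v <- pmax(e$values, 0)
  r <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / outer(d, d)
  diag(r) <- 1
  dimnames(r) <- dimnames(m)
  delta <- sqrt(sum((r - m)^2))
  if (delta > max_dist) {
    stop("correlation matrix is not positive semidefinite and the repair ",
         "moves it by Frobenius distance ", format(delta),
         " (> ", max_dist, ")")
  }
  list(matrix = r, delta = delta, repaired = TRUE)
}

tobacco_prob_cols <- function() paste0("tob_", TOBACCO_CATEGORIES)

#' Validate a parameter set
#'
#' Checks structural completeness (all 24 cohorts), probability bounds,
#' tobacco-category probabilities summing to one, positive scale
#' parameters, correlation-matrix symmetry/PSD (repairable matrices yield a
#' warning with the repair distance), intervention-effect CI ordering, tax
#' shares/elasticity domains, trend bounds, and (as warnings) mortality
#' rates non-decreasing in age within gender x location.
#'
#' @param ps a `parameter_set`.
#' @return list with character vectors `errors` and `warnings`; empty
#'   `errors` means the set is usable.
#' @export
validate_parameter_set <- function(ps) {
  errors <- character()
  warnings <- character()
  keys <- cohort_keys()

  # reduced test fixtures carry attr(ps, "partial"); full sets must cover
  # all 24 cohorts
  if (!isTRUE(attr(ps, "partial"))) {
    missing_cohorts <- setdiff(keys$cohort_id, ps$cohorts$cohort_id)
    if (length(missing_cohorts)) {
      errors <- c(errors, paste0("missing cohort(s) in cohorts table: ",
                                 paste(missing_cohorts, collapse = ", ")))
    }
  }
  missing_marg <- setdiff(ps$cohorts$cohort_id, ps$marginals$cohort_id)
  if (length(missing_marg)) {
    errors <- c(errors, paste0("missing marginals for cohort(s): ",
                               paste(missing_marg, collapse = ", ")))
  }
  for (cs in CAUSES) {
    miss <- setdiff(ps$cohorts$cohort_id,
                    ps$mortality$cohort_id[ps$mortality$cause == cs])
    if (length(miss)) {
      errors <- c(errors, paste0("missing ", cs,
                                 " mortality for cohort(s): ",
                                 paste(miss, collapse = ", ")))
    }
  }
  if (any(ps$cohorts$census <= 0)) {
    errors <- c(errors, "census sizes must be positive")
  }

  m <- ps$marginals
  if (any(m$sbp_sd <= 0) || any(m$chol_sd <= 0)) {
    errors <- c(errors, "marginal sds must be > 0")
  }
  probs <- as.matrix(m[, c("diabetes_prev", "chd_prev", "cvd_hist_prev",
                           tobacco_prob_cols())])
  if (any(probs < 0 | probs > 1)) {
    bad <- colnames(probs)[apply(probs < 0 | probs > 1, 2, any)]
    errors <- c(errors, paste0("probability outside [0,1] in field(s): ",
                               paste(bad, collapse = ", ")))
  }
  tsum <- rowSums(as.matrix(m[, tobacco_prob_cols()]))
  off <- abs(tsum - 1) > 1e-9
  if (any(off)) {
    errors <- c(errors,
                paste0("tobacco probabilities do not sum to 1 for cohort(s): ",
                       paste(m$cohort_id[off], collapse = ", ")))
  }

  cm <- ps$correlation
  if (!isTRUE(all.equal(dim(cm), c(length(RISK_FACTORS),
                                   length(RISK_FACTORS))))) {
    errors <- c(errors, "correlation matrix has wrong dimensions")
  } else {
    if (max(abs(cm - t(cm))) > 1e-9) {
      errors <- c(errors, "correlation matrix is not symmetric")
    } else if (max(abs(diag(cm) - 1)) > 1e-9) {
      errors <- c(errors, "correlation matrix diagonal is not 1")
    } else {
      rep <- tryCatch(nearest_psd(cm), error = function(e) e)
      if (inherits(rep, "error")) {
        errors <- c(errors, conditionMessage(rep))
      } else if (rep$repaired) {
        warnings <- c(warnings,
                      paste0("correlation matrix repaired to PSD; ",
                             "Frobenius delta = ",
                             format(rep$delta, digits = 3)))
      }
    }
  }

  if (any(ps$relative_risks$rr <= 0)) {
    errors <- c(errors, "relative risks must be > 0")
  }

  mt <- ps$mortality
  if (any(mt$rate <= 0 | mt$rate >= 1)) {
    errors <- c(errors, "mortality rates must lie in (0, 1)")
  }
  km <- merge(mt, keys, by = "cohort_id")
  for (g in GENDERS) for (l in LOCATIONS) for (cs in CAUSES) {
    sub <- km[km$gender == g & km$location == l & km$cause == cs, ]
    sub <- sub[match(AGE_BANDS, sub$age_band), ]
    if (any(diff(sub$rate) < 0, na.rm = TRUE)) {
      warnings <- c(warnings,
                    paste0("mortality (", cs, ") not non-decreasing in age ",
                           "for ", g, "/", l))
    }
  }

  tr <- unlist(ps$trends)
  if (any(!is.finite(tr)) || any(abs(tr) >= 0.20)) {
    errors <- c(errors, "secular trends must be finite and |trend| < 20%/yr")
  }

  ie <- ps$intervention_effects
  bad_ci <- ie$lo > ie$central | ie$central > ie$hi | ie$lo < 0 | ie$hi > 1
  if (any(bad_ci)) {
    errors <- c(errors, paste0("intervention effect CI out of order for: ",
                               paste(unique(ie$name[bad_ci]),
                                     collapse = ", ")))
  }

  if (any(ps$tax$share <= 0 | ps$tax$share >= 1)) {
    errors <- c(errors, "tax shares must lie in (0, 1)")
  }
  el <- ps$tax$elasticity$elasticity
  if (any(el <= -2 | el >= 0)) {
    errors <- c(errors, "price elasticities must lie in (-2, 0)")
  }

  if (!is.numeric(ps$quit_lag_months) || ps$quit_lag_months <= 0) {
    errors <- c(errors, "quit-lag time constant must be > 0")
  }

  merr <- validate_medication_policy(ps$medications)
  errors <- c(errors, merr)

  list(errors = errors, warnings = warnings)
}

stop_on_invalid <- function(ps) {
  v <- validate_parameter_set(ps)
  if (length(v$errors)) {
    stop("invalid parameter set:\n  ",
         paste(v$errors, collapse = "\n  "))
  }
  invisible(ps)
}
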