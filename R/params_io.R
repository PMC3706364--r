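#' Parameter bundle I/O
#'
#' A parameter set is persisted as a directory bundle: `params.yaml` (tax,
#' intervention effects, medication policy, trends, quit lag) plus CSV
#' tables with fixed, unit-bearing column names:
#' \itemize{
#'   \item `cohorts.csv`: cohort_id, age_band, gender, location,
#'     census_persons, growth_per_year
#'   \item `marginals.csv`: cohort_id, sbp_mean_mmHg, sbp_sd_mmHg,
#'     chol_mean_mmol_l, chol_sd_mmol_l, diabetes_prev, chd_prev,
#'     cvd_hist_prev, tob_never ... tob_dual
#'   \item `correlation.csv`: the 6x6 risk-factor correlation matrix
#'   \item `relative_risks.csv`: factor, cause, rr, rr_lo, rr_hi, unit,
#'     reference
#'   \item `mortality.csv`: cohort_id, cause, rate_per_year
#' }
#' The loader rejects unknown or missing columns (including wrong units in
#' the header) and names the offending cohort when a stratum is missing.
#'
#' @name params_io
NULL

.marginal_cols <- function() {
  c("cohort_id", "sbp_mean_mmHg", "sbp_sd_mmHg", "chol_mean_mmol_l",
    "chol_sd_mmol_l", "diabetes_prev", "chd_prev", "cvd_hist_prev",
    tobacco_prob_cols())
}

.check_cols <- function(df, expected, file) {
  if (!identical(sort(names(df)), sort(expected))) {
    extra <- setdiff(names(df), expected)
    miss <- setdiff(expected, names(df))
    stop("schema error in ", file, ": ",
         if (length(miss)) paste0("missing column(s) [",
                                  paste(miss, collapse = ", "), "] "),
         if (length(extra)) paste0("unknown column(s) [",
                                   paste(extra, collapse = ", "), "]"))
  }
  df[, expected]
}

#' Save a parameter set as a config bundle
#'
#' @param ps a `parameter_set`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_parameter_set <- function(ps, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  co <- ps$cohorts
  names(co)[names(co) == "census"] <- "census_persons"
  names(co)[names(co) == "growth"] <- "growth_per_year"
  utils::write.csv(co, file.path(path, "cohorts.csv"), row.names = FALSE)

  mg <- ps$marginals
  names(mg) <- sub("^sbp_mean$", "sbp_mean_mmHg",
               sub("^sbp_sd$", "sbp_sd_mmHg",
               sub("^chol_mean$", "chol_mean_mmol_l",
               sub("^chol_sd$", "chol_sd_mmol_l", names(mg)))))
  utils::write.csv(mg, file.path(path, "marginals.csv"), row.names = FALSE)

  cm <- as.data.frame(ps$correlation)
  cm <- cbind(factor = rownames(ps$correlation), cm)
  utils::write.csv(cm, file.path(path, "correlation.csv"),
                   row.names = FALSE)

  utils::write.csv(ps$relative_risks,
                   file.path(path, "relative_risks.csv"),
                   row.names = FALSE)

  mt <- ps$mortality
  names(mt)[names(mt) == "rate"] <- "rate_per_year"
  utils::write.csv(mt, file.path(path, "mortality.csv"), row.names = FALSE)

  pol <- ps$medications
  yaml::write_yaml(list(
    schema = "cvdmicrosim-params-v1",
    partial = isTRUE(attr(ps, "partial")),
    quit_lag_months = ps$quit_lag_months,
    trends = lapply(ps$trends, as.list),
    tax = list(share = as.list(ps$tax$share),
               elasticity = unname(split(ps$tax$elasticity,
                                         seq_len(nrow(ps$tax$elasticity))))),
    intervention_effects = unname(
      split(ps$intervention_effects,
            seq_len(nrow(ps$intervention_effects)))),
    medications = list(
      rrr = unname(split(pol$rrr, seq_len(nrow(pol$rrr)))),
      adherence = as.list(pol$adherence),
      adherence_ci = lapply(pol$adherence_ci, as.list),
      coverage_start = pol$coverage_start,
      coverage_end = pol$coverage_end,
      coverage_years = pol$coverage_years,
      chol_threshold = pol$chol_threshold,
      sbp_threshold = pol$sbp_threshold,
      multiplier_floor = pol$multiplier_floor,
      preset = pol$preset)),
    file.path(path, "params.yaml"))
  invisible(path)
}

.bind_rows <- function(lst) {
  do.call(rbind, lapply(lst, function(r) as.data.frame(r)))
}

#' Load a parameter set from a config bundle
#'
#' Inverse of [save_parameter_set()]; the loaded set is validated and any
#' validation error aborts the load.
#'
#' @param path bundle directory.
#' @return a validated `parameter_set`.
#' @export
load_parameter_set <- function(path) {
  need <- c("params.yaml", "cohorts.csv", "marginals.csv",
            "correlation.csv", "relative_risks.csv", "mortality.csv")
  have <- file.exists(file.path(path, need))
  if (!all(have)) {
    stop("parameter bundle at ", path, " is missing: ",
         paste(need[!have], collapse = ", "))
  }
  y <- yaml::read_yaml(file.path(path, "params.yaml"))
  if (!identical(y$schema, "cvdmicrosim-params-v1")) {
    stop("schema error: unknown bundle schema '", y$schema, "'")
  }

  co <- utils::read.csv(file.path(path, "cohorts.csv"))
  co <- .check_cols(co, c("cohort_id", "age_band", "gender", "location",
                          "census_persons", "growth_per_year"),
                    "cohorts.csv")
  names(co)[names(co) == "census_persons"] <- "census"
  names(co)[names(co) == "growth_per_year"] <- "growth"

  mg <- utils::read.csv(file.path(path, "marginals.csv"),
                        check.names = FALSE)
  mg <- .check_cols(mg, .marginal_cols(), "marginals.csv")
  names(mg) <- sub("^sbp_mean_mmHg$", "sbp_mean",
               sub("^sbp_sd_mmHg$", "sbp_sd",
               sub("^chol_mean_mmol_l$", "chol_mean",
               sub("^chol_sd_mmol_l$", "chol_sd", names(mg)))))
  missing_marg <- setdiff(co$cohort_id, mg$cohort_id)
  if (length(missing_marg)) {
    stop("schema error in marginals.csv: missing marginals for cohort(s) ",
         paste(missing_marg, collapse = ", "))
  }

  cm <- utils::read.csv(file.path(path, "correlation.csv"),
                        check.names = FALSE)
  cm <- .check_cols(cm, c("factor", RISK_FACTORS), "correlation.csv")
  correlation <- as.matrix(cm[, RISK_FACTORS])
  rownames(correlation) <- cm$factor
  correlation <- correlation[RISK_FACTORS, RISK_FACTORS]

  rr <- utils::read.csv(file.path(path, "relative_risks.csv"))
  rr <- .check_cols(rr, c("factor", "cause", "rr", "rr_lo", "rr_hi",
                          "unit", "reference"), "relative_risks.csv")

  mt <- utils::read.csv(file.path(path, "mortality.csv"))
  mt <- .check_cols(mt, c("cohort_id", "cause", "rate_per_year"),
                    "mortality.csv")
  names(mt)[names(mt) == "rate_per_year"] <- "rate"

  elast <- .bind_rows(y$tax$elasticity)
  pol <- y$medications
  policy <- structure(list(
    rrr = .bind_rows(pol$rrr),
    adherence = unlist(pol$adherence),
    adherence_ci = lapply(pol$adherence_ci, unlist),
    coverage_start = pol$coverage_start,
    coverage_end = pol$coverage_end,
    coverage_years = pol$coverage_years,
    chol_threshold = pol$chol_threshold,
    sbp_threshold = pol$sbp_threshold,
    multiplier_floor = pol$multiplier_floor,
    preset = pol$preset), class = "medication_policy")

  ps <- new_parameter_set(
    cohorts = co, marginals = mg, correlation = correlation,
    relative_risks = rr, mortality = mt,
    trends = lapply(y$trends, unlist),
    intervention_effects = .bind_rows(y$intervention_effects),
    tax = list(share = unlist(y$tax$share), elasticity = elast),
    medications = policy,
    quit_lag_months = y$quit_lag_months)
  if (isTRUE(y$partial)) attr(ps, "partial") <- TRUE
  v <- validate_parameter_set(ps)
  if (length(v$errors)) {
    stop("invalid parameter bundle at ", path, ":\n  ",
         paste(v$errors, collapse = "\n  "))
  }
  ps
}
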