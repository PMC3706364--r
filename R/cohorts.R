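#' Cohort structure
#'
#' The simulated population is stratified into 24 cohorts: six 10-year age
#' bands (20-29 through 70-79) crossed with gender (male/female) and
#' location (urban/rural).
#'
#' @name cohorts
NULL

AGE_BANDS <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")
GENDERS <- c("male", "female")
LOCATIONS <- c("urban", "rural")

#' Tobacco-use categories, in the fixed order used for inverse-CDF
#' assignment from the copula's latent tobacco dimension.
#' @export
TOBACCO_CATEGORIES <- c("never", "passive", "former", "cigarette", "bidi",
                        "chewing", "dual")

#' Risk factors, in the order of the correlation matrix. Tobacco enters the
#' copula through one latent dimension.
#' @export
RISK_FACTORS <- c("sbp", "chol", "diabetes", "chd_hist", "cvd_hist",
                  "tobacco")

CAUSES <- c("mi", "stroke", "other")

#' Enumerate the 24 cohort keys
#'
#' @return A data.frame with columns `age_band`, `gender`, `location` and a
#'   unique `cohort_id` string, one row per cohort (24 rows).
#' @export
cohort_keys <- function() {
  keys <- expand.grid(age_band = AGE_BANDS, gender = GENDERS,
                      location = LOCATIONS,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  keys$cohort_id <- with(keys, paste(age_band, gender, location, sep = "_"))
  keys[order(keys$cohort_id), c("cohort_id", "age_band", "gender",
                                "location")]
}

#' Lower and upper age bounds of an age band
#' @param age_band character vector of band labels like "20-29".
#' @return data.frame with `lo` and `hi` (inclusive integer years).
#' @keywords internal
age_band_bounds <- function(age_band) {
  parts <- strsplit(age_band, "-", fixed = TRUE)
  data.frame(lo = as.numeric(vapply(parts, `[`, "", 1L)),
             hi = as.numeric(vapply(parts, `[`, "", 2L)))
}

#' Age band for a continuous age
#'
#' Ages of 80 and above map to NA: such individuals keep the 70-79 mortality
#' rates inside the engine but are excluded from the reported 20-79 tallies.
#' @param age numeric vector of ages in years.
#' @return character vector of band labels (NA outside 20-79).
#' @keywords internal
age_to_band <- function(age) {
  idx <- findInterval(age, c(20, 30, 40, 50, 60, 70, 80))
  out <- rep(NA_character_, length(age))
  ok <- idx >= 1 & idx <= 6
  out[ok] <- AGE_BANDS[idx[ok]]
  out
}
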