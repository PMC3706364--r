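#' Correlated risk-profile sampling
#'
#' Individual risk-factor profiles are drawn through a Gaussian copula: a
#' multivariate standard normal with the parameter set's correlation
#' matrix is transformed marginal-by-marginal -- continuous factors by
#' mean + sd * z (clamped to physiologic ranges), binary factors by
#' thresholding at the prevalence quantile, and the 7-category tobacco
#' variable by inverse-CDF over one latent dimension.
#'
#' @name cohort_sampler
NULL

SBP_RANGE <- c(60, 300)    # mmHg
CHOL_RANGE <- c(1, 15)     # mmol/l

#' Inverse-CDF tobacco-category assignment
#'
#' Categories are assigned over the fixed order `TOBACCO_CATEGORIES`
#' (never, passive, former, cigarette, bidi, chewing, dual): a deviate u
#' falls in the first category whose cumulative probability exceeds it.
#'
#' @param u numeric vector of deviates in [0,1).
#' @param probs named numeric vector of category probabilities (order
#'   `TOBACCO_CATEGORIES`), summing to 1.
#' @return character vector of categories.
#' @export
assign_tobacco <- function(u, probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  probs <- probs[TOBACCO_CATEGORIES]
  cum <- cumsum(probs)
  idx <- findInterval(u, cum, left.open = FALSE) + 1L
  idx[idx > length(TOBACCO_CATEGORIES)] <- length(TOBACCO_CATEGORIES)
  TOBACCO_CATEGORIES[idx]
}

# Latent multivariate-normal draws: n x d matrix with correlation R.
# chol() keeps the column order (and hence the seed pathway) explicit.
latent_mvn <- function(n, R) {
  L <- chol(nearest_psd(R)$matrix + diag(1e-10, nrow(R)))
  z <- matrix(stats::rnorm(n * nrow(R)), nrow = n)
  z %*% L
}

#' Sample correlated risk profiles for one cohort
#'
#' Draws `n` profiles whose empirical marginals and pairwise correlations
#' converge to the cohort's specification as n grows. Age is uniform
#' within the 10-year band; baseline former users get a quit duration
#' uniform on [0, 120] months and a quit product assigned by the cohort's
#' cigarette:bidi prevalence ratio (dual users get a smoked-product
#' sub-flag the same way). Clamping of continuous draws beyond the
#' physiologic ranges (sbp 60-300 mmHg, chol 1-15 mmol/l) is tracked and
#' warns if it exceeds 0.1%.
#'
#' @param cohort a cohort_id string or a row of [cohort_keys()].
#' @param n number of profiles (>= 1).
#' @param ps a `parameter_set`.
#' @param seed integer seed (profile stream).
#' @return data.frame of profiles: `age`, `sbp`, `chol`, `diabetes`,
#'   `chd_hist`, `cvd_hist`, `tobacco`, `smoked_product`,
#'   `months_since_quit`, `alive`, plus pre-drawn uniforms used by the
#'   intervention (`u_quit_cig`, `u_quit_bidi`, `u_quit_passive`),
#'   medication (`u_cov`, `u_adh`) and secular-trend (`u_inc_*`) layers.
#' @export
sample_profiles <- function(cohort, n, ps, seed = 1L) {
  stopifnot(n >= 1)
  if (is.character(cohort)) {
    key <- ps$cohorts[ps$cohorts$cohort_id == cohort, ]
    if (nrow(key) != 1L) stop("unknown cohort key: ", cohort)
  } else {
    key <- as.data.frame(cohort)
  }
  m <- ps$marginals[ps$marginals$cohort_id == key$cohort_id, ]
  if (nrow(m) != 1L) stop("no marginals for cohort ", key$cohort_id)
  with_stream(seed, "profile", .sample_profiles_impl(key, n, m, ps))
}

.sample_profiles_impl <- function(key, n, m, ps) {
  z <- latent_mvn(n, ps$correlation)
  bounds <- age_band_bounds(key$age_band)

  sbp_raw <- m$sbp_mean + m$sbp_sd * z[, 1]
  chol_raw <- m$chol_mean + m$chol_sd * z[, 2]
  sbp <- pmin(pmax(sbp_raw, SBP_RANGE[1]), SBP_RANGE[2])
  chol <- pmin(pmax(chol_raw, CHOL_RANGE[1]), CHOL_RANGE[2])
  n_clamped <- sum(sbp != sbp_raw | chol != chol_raw)
  clamped <- n_clamped / n
  # a systematic-misspecification guard, not a tail-draw alarm: at small
  # n a single extreme deviate would otherwise trip the 0.1% threshold
  if (clamped > 0.001 && n_clamped >= 5) {
    warning("cohort ", key$cohort_id, ": ",
            format(100 * clamped, digits = 2),
            "% of continuous draws clamped to physiologic range")
  }

  diabetes <- z[, 3] < stats::qnorm(m$diabetes_prev)
  chd_hist <- z[, 4] < stats::qnorm(m$chd_prev)
  cvd_hist <- z[, 5] < stats::qnorm(m$cvd_hist_prev)

  tprobs <- stats::setNames(as.numeric(m[, tobacco_prob_cols()]),
                            TOBACCO_CATEGORIES)
  tobacco <- assign_tobacco(stats::pnorm(z[, 6]), tprobs)

  # smoked product for dual users and quit product for baseline formers:
  # cohort cigarette:bidi ratio (0.5 if neither is used in the cohort)
  p_cig <- tprobs[["cigarette"]] /
    max(tprobs[["cigarette"]] + tprobs[["bidi"]], 1e-12)
  if (tprobs[["cigarette"]] + tprobs[["bidi"]] == 0) p_cig <- 0.5
  smoked_product <- rep(NA_character_, n)
  need <- tobacco %in% c("dual", "former")
  smoked_product[need] <- ifelse(stats::runif(sum(need)) < p_cig,
                                 "cigarette", "bidi")

  months_since_quit <- rep(NA_real_, n)
  former <- tobacco == "former"
  months_since_quit[former] <- stats::runif(sum(former), 0, 120)

  data.frame(
    cohort_id = key$cohort_id, gender = key$gender,
    location = key$location,
    age = stats::runif(n, bounds$lo, bounds$hi + 1),
    sbp = sbp, chol = chol,
    diabetes = diabetes, chd_hist = chd_hist, cvd_hist = cvd_hist,
    tobacco = tobacco, smoked_product = smoked_product,
    months_since_quit = months_since_quit,
    passive_removed = FALSE, months_since_passive = NA_real_,
    alive = TRUE,
    u_quit_cig = stats::runif(n), u_quit_bidi = stats::runif(n),
    u_quit_passive = stats::runif(n),
    u_cov = stats::runif(n), u_adh = stats::runif(n),
    u_inc_diabetes = stats::runif(n), u_inc_chd = stats::runif(n),
    u_inc_cvd = stats::runif(n),
    stringsAsFactors = FALSE)
}
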