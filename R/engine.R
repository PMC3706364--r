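#' Simulation engine
#'
#' Runs the annual discrete-time loop over 2013-2022 for one parameter
#' draw: sample correlated risk profiles per cohort, each year apply
#' secular trends, the tobacco-control scenario and medication policy,
#' compute cohort-calibrated cause probabilities, draw one competing-risk
#' outcome per alive person from {MI death, stroke death, other death,
#' survive}, scale simulated deaths to the projected census, age
#' survivors, and add new 20-year-old entrants.
#'
#' All randomness is split into named streams derived from the master
#' seed (profile sampling, outcome uniforms, intervention assignment,
#' medication assignment), and every per-person deviate a scenario might
#' consult is pre-drawn at profile creation, so two runs with the same
#' seed share all randomness and differ only through the interventions
#' themselves (common random numbers).
#'
#' @name engine
NULL

SIM_YEARS <- 10L
BASE_YEAR <- 2013L

params_digest <- function(ps) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(ps, f)
  unname(tools::md5sum(f))
}

# Build the full roster: initial samples per cohort plus pre-generated
# 20-year-old entrants for years 1..9 (census-projection inflow).
build_roster <- function(ps, n_per_cohort, seed, add_entrants) {
  keys <- ps$cohorts
  pops <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    pop <- sample_profiles(k$cohort_id, n_per_cohort, ps,
                           seed = seed + 1000L * i)
    pop$entry_year <- 0L
    if (add_entrants && k$age_band == "20-29") {
      n_e <- round(n_per_cohort / 10 * (1 + k$growth)^(1:9))
      ent <- sample_profiles(k$cohort_id, sum(n_e), ps,
                             seed = seed + 1000L * i + 499L)
      ent$entry_year <- rep(1:9, times = n_e)
      ent$age <- 20 + (ent$age - floor(ent$age))  # enter at age 20
      pop <- rbind(pop, ent)
    }
    pops[[i]] <- pop
  }
  pop <- do.call(rbind, pops)
  # freeze the baseline (counterfactual) risk attributes
  pop$sbp0 <- pop$sbp
  pop$chol0 <- pop$chol
  pop$diabetes0 <- pop$diabetes
  pop$chd_hist0 <- pop$chd_hist
  pop$cvd_hist0 <- pop$cvd_hist
  pop$tobacco0 <- pop$tobacco
  pop$smoked_product0 <- pop$smoked_product
  pop$months_since_quit0 <- pop$months_since_quit
  rownames(pop) <- NULL
  pop
}

# Secular-trend update, identical across scenarios: continuous levels are
# scaled from baseline; binary factors gain incident cases toward the
# trend-projected prevalence through pre-drawn uniforms (one-way; falling
# prevalence does not remove existing disease).
apply_trends <- function(pop, ps, year_index) {
  tr <- ps$trends$risk_factors
  pop$sbp <- pmin(pmax(pop$sbp0 * (1 + tr[["sbp"]])^year_index,
                       SBP_RANGE[1]), SBP_RANGE[2])
  pop$chol <- pmin(pmax(pop$chol0 * (1 + tr[["chol"]])^year_index,
                        CHOL_RANGE[1]), CHOL_RANGE[2])
  binmap <- c(diabetes = "diabetes_prev", chd_hist = "chd_prev",
              cvd_hist = "cvd_hist_prev")
  umap <- c(diabetes = "u_inc_diabetes", chd_hist = "u_inc_chd",
            cvd_hist = "u_inc_cvd")
  m <- ps$marginals[match(pop$cohort_id, ps$marginals$cohort_id), ]
  for (b in names(binmap)) {
    t_b <- tr[[b]]
    if (is.na(t_b) || t_b <= 0 || year_index == 0) {
      pop[[b]] <- pop[[paste0(b, "0")]]
      next
    }
    prev0 <- m[[binmap[[b]]]]
    prev_t <- pmin(1, prev0 * (1 + t_b)^year_index)
    p_inc <- pmin(1, pmax(0, (prev_t - prev0) / pmax(1 - prev0, 1e-12)))
    pop[[b]] <- pop[[paste0(b, "0")]] |
      (!pop[[paste0(b, "0")]] & pop[[umap[[b]]]] < p_inc)
  }
  pop
}

# Current-year reporting/mortality group: 10-year band from attained age
# (NA band for ages 80+, which keep the 70-79 rates but are not reported)
current_group <- function(pop) {
  band <- age_to_band(pop$age)
  over <- is.na(band) & pop$age >= 80
  lookup_band <- ifelse(over, "70-79", band)
  list(report_id = ifelse(is.na(band), NA_character_,
                          paste(band, pop$gender, pop$location,
                                sep = "_")),
       lookup_id = paste(lookup_band, pop$gender, pop$location,
                         sep = "_"),
       group_id = paste(ifelse(over, "80plus", band), pop$gender,
                        pop$location, sep = "_"))
}

#' Run one scenario
#'
#' @param ps a validated `parameter_set` (possibly a Monte Carlo
#'   parameter draw).
#' @param scenario a `scenario_spec` (use `scenario_preset("none")` for
#'   the no-intervention baseline).
#' @param n_per_cohort simulated individuals per cohort (>= 100; the
#'   reference configuration uses 10,000).
#' @param seed master seed; runs sharing it share all random streams.
#' @param add_entrants add 20-year-old entrants each year per the census
#'   projection (default TRUE).
#' @return a `simulation_result`: `deaths` array (cohort x year x cause,
#'   persons scaled to the projected census, ages 20-79),
#'   `person_years` (per year, scaled), `final_tobacco_prev` (category
#'   proportions among survivors), and `meta`.
#' @export
run_scenario <- function(ps, scenario = scenario_preset("none"),
                         n_per_cohort = 1000L, seed = 1L,
                         add_entrants = TRUE) {
  stopifnot(inherits(scenario, "scenario_spec"), n_per_cohort >= 100)
  stop_on_invalid(ps)
  ps$correlation <- nearest_psd(ps$correlation)$matrix

  pop <- build_roster(ps, n_per_cohort, seed, add_entrants)
  n_total <- nrow(pop)
  # one uniform per person-year per cause, so each cause's averted-death
  # count is itself a common-random-number contrast (a single stacked
  # uniform would reattribute averted MI deaths to the stroke interval)
  U <- with_stream(seed, "outcome",
                   array(stats::runif(n_total * SIM_YEARS * 3),
                         dim = c(n_total, SIM_YEARS, 3)))

  policy <- NULL
  if (!is.null(scenario$medications)) {
    # numeric parameters (possibly Monte Carlo draws) live in ps; the
    # scenario picks the coverage path
    policy <- ps$medications
    policy$coverage_start <- scenario$medications$coverage_start
    policy$coverage_end <- scenario$medications$coverage_end
    policy$coverage_years <- scenario$medications$coverage_years
    policy$preset <- scenario$medications$preset
  }

  cohort_ids <- sort(ps$cohorts$cohort_id)
  deaths <- array(0, dim = c(length(cohort_ids), SIM_YEARS,
                             length(CAUSES)),
                  dimnames = list(cohort_ids, BASE_YEAR + 0:9, CAUSES))
  person_years <- numeric(SIM_YEARS)
  mort <- ps$mortality
  mtr <- ps$trends$mortality

  for (y in 0:(SIM_YEARS - 1L)) {
    active <- pop$alive & pop$entry_year <= y
    for (cid in ps$cohorts$cohort_id) {
      if (!any(active & pop$cohort_id == cid)) {
        stop("cohort extinction: no survivors in cohort ", cid,
             " at year ", BASE_YEAR + y)
      }
    }
    pop[active, ] <- apply_trends(pop[active, ], ps, y)
    pop[active, ] <- apply_tobacco_scenario(pop[active, ], scenario, y,
                                            ps)

    grp <- current_group(pop)
    act <- which(active)
    a <- pop[act, ]
    agrp_lookup <- grp$lookup_id[act]
    agrp_group <- grp$group_id[act]
    areport <- grp$report_id[act]

    # mid-cycle quit clocks
    eval_months <- a$months_since_quit + 6
    a_eval <- a
    a_eval$months_since_quit <- eval_months
    a_eval$months_since_passive <- a$months_since_passive + 6

    # counterfactual (intervention-free) risk attributes on the same
    # trend-updated continuous/binary state
    ref <- a_eval
    ref$tobacco <- a$tobacco0
    ref$smoked_product <- a$smoked_product0
    ref$months_since_quit <- ifelse(is.na(a$months_since_quit0),
                                    NA_real_,
                                    a$months_since_quit0 +
                                      12 * (y - a$entry_year) + 6)
    ref$passive_removed <- FALSE

    tau <- ps$quit_lag_months
    rr_act <- list(mi = individual_rr_vec(a_eval, ps$relative_risks,
                                          "mi", tau),
                   stroke = individual_rr_vec(a_eval, ps$relative_risks,
                                              "stroke", tau))
    rr_ref <- list(mi = individual_rr_vec(ref, ps$relative_risks, "mi",
                                          tau),
                   stroke = individual_rr_vec(ref, ps$relative_risks,
                                              "stroke", tau))
    if (!is.null(policy)) {
      rr_act$mi <- rr_act$mi *
        medication_multiplier_vec(a, policy, y, "mi")
      rr_act$stroke <- rr_act$stroke *
        medication_multiplier_vec(a, policy, y, "stroke")
    }

    p <- matrix(0, nrow(a), 3, dimnames = list(NULL, CAUSES))
    for (g in unique(agrp_group)) {
      idx <- agrp_group == g
      lid <- agrp_lookup[idx][1]
      # reduced fixtures may lack the band a person has aged into; fall
      # back to the origin cohort's rates
      if (!lid %in% mort$cohort_id) lid <- a$cohort_id[idx][1]
      for (cs in c("mi", "stroke")) {
        m0 <- mort$rate[mort$cohort_id == lid & mort$cause == cs]
        p[idx, cs] <- normalized_cause_probs(
          rr_act[[cs]][idx], m0, mtr[[cs]], y,
          rr_reference = rr_ref[[cs]][idx])
      }
      m0 <- mort$rate[mort$cohort_id == lid & mort$cause == "other"]
      p[idx, "other"] <- m0 * (1 + mtr[["other"]])^y
    }

    died_mi <- U[act, y + 1L, 1] < p[, "mi"]
    died_stroke <- !died_mi & U[act, y + 1L, 2] < p[, "stroke"]
    died_other <- !died_mi & !died_stroke &
      U[act, y + 1L, 3] < p[, "other"]

    # population weights: projected census over simulated alive count,
    # per current reporting cohort
    reported <- !is.na(areport) & areport %in% ps$cohorts$cohort_id
    wt <- numeric(nrow(a))
    for (g in unique(areport[reported])) {
      idx <- which(areport == g)
      crow <- ps$cohorts[ps$cohorts$cohort_id == g, ]
      wt[idx] <- crow$census * (1 + crow$growth)^y / length(idx)
    }
    person_years[y + 1L] <- sum(wt)
    for (cs_i in seq_along(CAUSES)) {
      died <- switch(CAUSES[cs_i], mi = died_mi, stroke = died_stroke,
                     other = died_other)
      if (any(died & reported)) {
        tab <- tapply(wt[died & reported], areport[died & reported],
                      sum)
        deaths[names(tab), y + 1L, cs_i] <-
          deaths[names(tab), y + 1L, cs_i] + tab
      }
    }

    pop$alive[act[died_mi | died_stroke | died_other]] <- FALSE
    # advance clocks for everyone already in the population
    inpop <- pop$entry_year <= y
    pop$age[inpop] <- pop$age[inpop] + 1
    pop$months_since_quit[inpop] <- pop$months_since_quit[inpop] + 12
    pop$months_since_passive[inpop] <-
      pop$months_since_passive[inpop] + 12
  }

  surv <- pop$alive & pop$entry_year <= (SIM_YEARS - 1L)
  prev <- table(factor(pop$tobacco[surv], levels = TOBACCO_CATEGORIES))
  structure(list(
    deaths = deaths,
    person_years = person_years,
    final_tobacco_prev = prev / sum(prev),
    meta = list(seed = seed, n_per_cohort = n_per_cohort,
                scenario = scenario$name,
                params_digest = params_digest(ps),
                add_entrants = add_entrants)),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  tot <- apply(x$deaths, 3, sum)
  cat("<simulation_result>", x$meta$scenario, "\n")
  cat("  seed:", x$meta$seed, " n/cohort:", x$meta$n_per_cohort, "\n")
  cat(sprintf("  deaths 2013-2022 (ages 20-79): MI %.3g, stroke %.3g, other %.3g\n",
              tot["mi"], tot["stroke"], tot["other"]))
  invisible(x)
}

subgroup_shares <- function(delta) {
  keys <- cohort_keys()
  ids <- rownames(delta)
  k <- keys[match(ids, keys$cohort_id), ]
  by_year <- rowSums(delta)
  gl <- tapply(by_year, paste(k$gender, k$location, sep = "_"), sum)
  ab <- tapply(by_year, k$age_band, sum)
  tot <- sum(by_year)
  if (abs(tot) < .Machine$double.eps) {
    return(list(gender_location = gl * 0, age_band = ab * 0))
  }
  list(gender_location = gl / tot, age_band = ab / tot)
}

#' Deaths averted by a scenario
#'
#' Baseline-minus-scenario deaths per cause, summed over 2013-2022 and
#' ages 20-79, with percent reductions and subgroup shares. Both results
#' must come from the same seed and parameter draw (common random
#' numbers), which is checked.
#'
#' @param baseline `simulation_result` of the no-intervention run.
#' @param scenario `simulation_result` of the intervention run.
#' @return list of class `averted_summary`: per cause `averted`,
#'   `baseline`, `percent` (100 * averted/baseline), and subgroup shares
#'   of averted deaths by gender x location and age band.
#' @export
averted <- function(baseline, scenario) {
  if (!identical(baseline$meta$seed, scenario$meta$seed) ||
        !identical(baseline$meta$params_digest,
                   scenario$meta$params_digest) ||
        !identical(baseline$meta$n_per_cohort,
                   scenario$meta$n_per_cohort)) {
    stop("averted() requires runs with a shared seed, population size ",
         "and parameter draw (common random numbers)")
  }
  out <- list()
  for (cs in c("mi", "stroke")) {
    delta <- baseline$deaths[, , cs] - scenario$deaths[, , cs]
    base <- sum(baseline$deaths[, , cs])
    out[[cs]] <- list(averted = sum(delta), baseline = base,
                      percent = 100 * sum(delta) / base,
                      shares = subgroup_shares(delta))
  }
  structure(out, class = "averted_summary",
            scenario = scenario$meta$scenario)
}

#' @export
print.averted_summary <- function(x, ...) {
  cat("<averted_summary>", attr(x, "scenario"), "\n")
  for (cs in c("mi", "stroke")) {
    cat(sprintf("  %-7s averted %.4g of %.4g baseline deaths (%.2f%%)\n",
                cs, x[[cs]]$averted, x[[cs]]$baseline, x[[cs]]$percent))
  }
  invisible(x)
}
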