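#' Tobacco-control interventions
#'
#' Five FCTC measures act on three exposure channels (active cigarette
#' smoking, active bidi smoking, passive exposure): smoke-free laws,
#' brief cessation advice, mass media campaigns, an advertising ban, and
#' excise-tax increases whose dose-response runs mechanistically through
#' price elasticities. Channel effects combine under one of three modes
#' (largest-only, cumulative, or cumulative with 25% synergy), phase in
#' with legislative coverage, and confer cardiovascular benefit gradually
#' through the exponential quit lag.
#'
#' @name interventions
NULL

TC_INTERVENTIONS <- c("smokefree", "brief_advice", "mass_media", "ad_ban",
                      "tax")
EXPOSURE_CHANNELS <- c("active_cigarette", "active_bidi", "passive")

#' Smoking-prevalence reduction from a tax increase
#'
#' Mechanistic dose-response: `reduction = min(1, |elasticity| *
#' tax_share * tax_increase_pct / 100)`, assuming full pass-through of the
#' tax to retail prices. With the default shares (cigarettes 38%, bidis
#' 9%) and elasticities, the location-averaged reductions reproduce the
#' published 50/300/500% anchors for both products within 3 percentage
#' points.
#'
#' @param product "cigarette" or "bidi".
#' @param location "urban", "rural", or "average" (mean of the two).
#' @param tax_increase_pct percent increase over the current tax (>= 0).
#' @param tp tax parameters (see [default_tax_parameters()]).
#' @return reduction fraction in [0,1].
#' @export
tax_effect <- function(product, location, tax_increase_pct,
                       tp = default_tax_parameters()) {
  stopifnot(tax_increase_pct >= 0)
  el <- tp$elasticity
  if (identical(location, "average")) {
    return(mean(vapply(LOCATIONS, function(l)
      tax_effect(product, l, tax_increase_pct, tp), 0)))
  }
  row <- el[el$product == product & el$location == location, ]
  if (nrow(row) != 1L) stop("no elasticity for ", product, "/", location)
  pmin(1, abs(row$elasticity) * tp$share[[product]] *
         tax_increase_pct / 100)
}

#' Combine intervention effects on one exposure channel
#'
#' @param effects numeric vector of per-intervention reduction fractions
#'   in [0,1] (empty vector gives 0).
#' @param mode "max_only" (largest effect only), "cumulative"
#'   (`1 - prod(1 - e)`), or "synergy25" (cumulative with each individual
#'   effect amplified by 25%, capped at 1).
#' @return combined reduction fraction in [0,1].
#' @export
combine_effects <- function(effects,
                            mode = c("cumulative", "max_only",
                                     "synergy25")) {
  mode <- match.arg(mode)
  if (!length(effects)) return(0)
  stopifnot(all(effects >= 0 & effects <= 1))
  switch(mode,
         max_only = max(effects),
         cumulative = 1 - prod(1 - effects),
         synergy25 = 1 - prod(1 - pmin(1, 1.25 * effects)))
}

#' Legislative coverage ramp
#'
#' `baseline_10yr_linear`: interventions are enacted immediately at full
#' coverage and their smoking effects phase in linearly over the decade,
#' `(year_index + 1)/10`. `delayed_80pct_5yr`: legislation itself ramps
#' from 0% to 80% coverage over 5 years and then holds,
#' `0.8 * min(1, (year_index + 1)/5)`.
#'
#' @param ramp one of the two schedule names.
#' @param year_index 0-based year in 0..9.
#' @return fraction in [0,1].
#' @export
coverage_ramp <- function(ramp = c("baseline_10yr_linear",
                                   "delayed_80pct_5yr"),
                          year_index) {
  ramp <- match.arg(ramp)
  stopifnot(all(year_index >= 0 & year_index <= 9))
  switch(ramp,
         baseline_10yr_linear = (year_index + 1) / 10,
         delayed_80pct_5yr = 0.8 * pmin(1, (year_index + 1) / 5))
}

#' Realized effect trajectory of a ramp schedule
#'
#' The smoking effect of a covered tranche of the population phases in
#' linearly over 10 years; the realized population effect fraction in
#' year y is the convolution of annual legislative-coverage increments
#' with that phase-in. Under the baseline schedule (coverage steps to
#' 100% at enactment) this reduces exactly to `(y + 1)/10`; under the
#' delayed schedule each year's 16-point coverage increment starts its
#' own decade-long phase-in, so the realized effect stays strictly below
#' the baseline trajectory in every year.
#'
#' @param ramp schedule name as in [coverage_ramp()].
#' @param year_index 0-based year in 0..9.
#' @return fraction of the full steady-state effect realized that year.
#' @export
effect_trajectory <- function(ramp = c("baseline_10yr_linear",
                                       "delayed_80pct_5yr"),
                              year_index) {
  ramp <- match.arg(ramp)
  # legislative coverage path: baseline legislation is enacted at full
  # coverage immediately (step to 1); the delayed schedule ramps to 80%
  cov <- switch(ramp,
                baseline_10yr_linear = rep(1, 10),
                delayed_80pct_5yr = coverage_ramp(ramp, 0:9))
  inc <- diff(c(0, cov))
  traj <- vapply(0:9, function(y) {
    s <- 0:y
    sum(inc[s + 1] * pmin(1, (y - s + 1) / 10))
  }, 0)
  traj[year_index + 1]
}

#' Residual relative risk after quitting
#'
#' Excess risk decays exponentially with time constant `tau` (default
#' 19.1 months): `floor + (rr_current - floor) * exp(-months/tau)`,
#' hard-floored once 120 months have elapsed (benefit complete after
#' 10 years).
#'
#' @param rr_current RR while still exposed (>= floor).
#' @param months_since_quit months since cessation (>= 0).
#' @param tau time constant in months (> 0).
#' @param floor RR retained permanently (1 for full cessation; the
#'   chewing RR for dual users who quit only the smoked product).
#' @return residual multiplier.
#' @export
quit_benefit <- function(rr_current, months_since_quit, tau = 19.1,
                         floor = 1) {
  stopifnot(tau > 0, all(months_since_quit >= 0))
  out <- floor + (rr_current - floor) * exp(-months_since_quit / tau)
  ifelse(months_since_quit >= 120, floor, out)
}

#' Tobacco-control scenario specification
#'
#' @param interventions character subset of
#'   `c("smokefree", "brief_advice", "mass_media", "ad_ban", "tax")`.
#' @param tax_increase named numeric: percent tax increase per product,
#'   e.g. `c(cigarette = 300, bidi = 300)` (used when "tax" is active).
#' @param mode combination mode, see [combine_effects()].
#' @param ramp implementation schedule, see [coverage_ramp()].
#' @param medications NULL, or a `medication_policy` / preset name
#'   ("who_45pct", "who_80pct") activating the pharmacological package.
#' @param name optional label.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(interventions = character(),
                          tax_increase = c(cigarette = 0, bidi = 0),
                          mode = "cumulative",
                          ramp = "baseline_10yr_linear",
                          medications = NULL, name = NULL) {
  stopifnot(all(interventions %in% TC_INTERVENTIONS),
            all(tax_increase >= 0))
  mode <- match.arg(mode, c("cumulative", "max_only", "synergy25"))
  ramp <- match.arg(ramp, c("baseline_10yr_linear", "delayed_80pct_5yr"))
  if (is.character(medications)) {
    medications <- default_medication_policy(medications)
  }
  ti <- c(cigarette = 0, bidi = 0)
  ti[names(tax_increase)] <- tax_increase
  structure(list(interventions = interventions, tax_increase = ti,
                 mode = mode, ramp = ramp, medications = medications,
                 name = name %||% "scenario"),
            class = "scenario_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$name, "\n")
  cat("  tobacco-control:", if (length(x$interventions))
    paste(x$interventions, collapse = ", ") else "(none)", "\n")
  if ("tax" %in% x$interventions) {
    cat("  tax increase:   cigarette +", x$tax_increase[["cigarette"]],
        "%, bidi +", x$tax_increase[["bidi"]], "%\n", sep = "")
  }
  cat("  mode:", x$mode, " ramp:", x$ramp, "\n")
  cat("  medications:", if (is.null(x$medications)) "(none)" else
    x$medications$preset, "\n")
  invisible(x)
}

#' Named scenario presets
#'
#' The comparison-table rows: each single tobacco-control measure, the
#' 300% tax combinations, the full tobacco-control package under the
#' three combination modes, the medication packages, and tobacco control
#' plus medications.
#'
#' @param name preset name; call with no argument to list all names.
#' @return a `scenario_spec` (or character vector of names).
#' @export
scenario_preset <- function(name) {
  presets <- list(
    none = scenario_spec(name = "No intervention"),
    smokefree = scenario_spec("smokefree", name = "Smoke-free legislation"),
    brief_advice = scenario_spec("brief_advice",
                                 name = "Brief cessation advice"),
    mass_media = scenario_spec("mass_media", name = "Mass media"),
    ad_ban = scenario_spec("ad_ban", name = "Advertising ban"),
    tax300_bidi = scenario_spec("tax", tax_increase = c(bidi = 300),
                                name = "300% bidi tax"),
    tax300_cig = scenario_spec("tax", tax_increase = c(cigarette = 300),
                               name = "300% cigarette tax"),
    tax300_both = scenario_spec("tax",
                                tax_increase = c(cigarette = 300,
                                                 bidi = 300),
                                name = "300% bidi and cigarette tax"),
    all_meds = scenario_spec(medications = "who_45pct", name = "All meds"),
    all_meds_80 = scenario_spec(medications = "who_80pct",
                                name = "All meds (80% coverage)"),
    all_tc_max = scenario_spec(TC_INTERVENTIONS,
                               tax_increase = c(cigarette = 300,
                                                bidi = 300),
                               mode = "max_only",
                               name = "All TC (no additive effects)"),
    all_tc_cumulative = scenario_spec(TC_INTERVENTIONS,
                                      tax_increase = c(cigarette = 300,
                                                       bidi = 300),
                                      name = "All TC (cumulative effects)"),
    all_tc_synergy = scenario_spec(TC_INTERVENTIONS,
                                   tax_increase = c(cigarette = 300,
                                                    bidi = 300),
                                   mode = "synergy25",
                                   name = "All TC (25% synergy)"),
    all_tc_meds = scenario_spec(TC_INTERVENTIONS,
                                tax_increase = c(cigarette = 300,
                                                 bidi = 300),
                                medications = "who_45pct",
                                name = "All TC+all meds"))
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop("unknown scenario preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

# Combined steady-state reduction target for each exposure channel under a
# scenario, per location (tax effects are location-specific). Returns a
# named vector over EXPOSURE_CHANNELS.
channel_targets <- function(scenario, ps, location,
                            effects = ps$intervention_effects) {
  named <- scenario$interventions
  out <- numeric(0)
  for (ch in EXPOSURE_CHANNELS) {
    e <- effects$central[effects$name %in% named & effects$target == ch]
    if ("tax" %in% named && ch != "passive") {
      prod <- if (ch == "active_cigarette") "cigarette" else "bidi"
      inc <- scenario$tax_increase[[prod]]
      if (inc > 0) {
        e <- c(e, tax_effect(prod, location, inc, ps$tax))
      }
    }
    out[ch] <- combine_effects(e, scenario$mode)
  }
  out
}

#' Apply a tobacco-control scenario to a population for one year
#'
#' For each exposure channel the year's cumulative target reduction is
#' the combined steady-state effect times the realized ramp trajectory.
#' Individuals quit when their pre-drawn channel uniform falls below the
#' target, which selects quitters without replacement, keeps trajectories
#' monotone, and is identical across scenarios sharing a seed (common
#' random numbers). Active quitters become former users (dual users lose
#' the smoked component but keep chewing) with their quit clock at zero;
#' passive-exposed individuals lose the passive excess subject to the
#' same lag.
#'
#' @param pop population data.frame from [sample_profiles()].
#' @param scenario a `scenario_spec`.
#' @param year_index 0-based simulation year.
#' @param ps the `parameter_set`.
#' @param effects optionally a redrawn intervention-effect table (Monte
#'   Carlo replicates).
#' @return updated population data.frame.
#' @export
apply_tobacco_scenario <- function(pop, scenario, year_index, ps,
                                   effects = ps$intervention_effects) {
  if (!length(scenario$interventions)) return(pop)
  traj <- effect_trajectory(scenario$ramp, year_index)
  for (loc in unique(pop$location)) {
    tgt <- channel_targets(scenario, ps, loc, effects) * traj
    inloc <- pop$location == loc

    sel <- inloc & pop$u_quit_cig < tgt[["active_cigarette"]] &
      (pop$tobacco == "cigarette" |
         (pop$tobacco == "dual" & pop$smoked_product == "cigarette"))
    pop <- .quit_active(pop, sel, "cigarette")

    sel <- inloc & pop$u_quit_bidi < tgt[["active_bidi"]] &
      (pop$tobacco == "bidi" |
         (pop$tobacco == "dual" & pop$smoked_product == "bidi"))
    pop <- .quit_active(pop, sel, "bidi")

    sel <- inloc & pop$tobacco == "passive" & !pop$passive_removed &
      pop$u_quit_passive < tgt[["passive"]]
    if (any(sel)) {
      pop$passive_removed[sel] <- TRUE
      pop$months_since_passive[sel] <- 0
    }
  }
  pop
}

.quit_active <- function(pop, sel, product) {
  if (!any(sel)) return(pop)
  dual <- sel & pop$tobacco == "dual"
  mono <- sel & !dual
  pop$tobacco[mono] <- "former"
  pop$smoked_product[mono] <- product
  pop$tobacco[dual] <- "chewing"   # keeps chewing; smoked excess decays
  pop$months_since_quit[sel] <- 0
  pop
}
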