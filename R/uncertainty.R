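#' Monte Carlo uncertainty layer
#'
#' Each replicate draws the uncertain parameters from normal
#' distributions defined by their 95% CIs (truncated to each parameter's
#' legal domain), then runs the baseline and every scenario with shared
#' random streams and records deaths averted. Percentile 2.5/97.5
#' intervals are reported rather than normal approximations because the
#' averted-death distributions are skewed.
#'
#' @name uncertainty
NULL

#' Uncertainty run specification
#'
#' @param n_runs Monte Carlo replicates (the reference configuration uses
#'   10,000; tests use far fewer).
#' @param n_per_cohort simulated individuals per cohort per run.
#' @param master_seed master seed; all replicate seeds derive from it.
#' @param draw_params draw parameters from their CIs (FALSE freezes them
#'   at central values, leaving only outcome-sampling noise).
#' @param add_entrants passed to [run_scenario()].
#' @return list of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(n_runs = 200L, n_per_cohort = 1000L,
                             master_seed = 1L, draw_params = TRUE,
                             add_entrants = TRUE) {
  stopifnot(n_runs >= 1L)
  structure(list(n_runs = as.integer(n_runs),
                 n_per_cohort = as.integer(n_per_cohort),
                 master_seed = as.integer(master_seed),
                 draw_params = isTRUE(draw_params),
                 add_entrants = isTRUE(add_entrants)),
            class = "uncertainty_spec")
}

rnorm_ci <- function(n, central, lo, hi, lower, upper) {
  sd <- (hi - lo) / (2 * stats::qnorm(0.975))
  pmin(upper, pmax(lower, stats::rnorm(n, central, sd)))
}

#' Draw one parameter replicate
#'
#' Intervention effects, relative risks, price elasticities, medication
#' RRRs, adherence and the census growth rate are drawn from their
#' CI-defined normals, truncated (by clamping) to their legal domains.
#' One stream per parameter family, so adding a scenario never perturbs
#' another family's draws.
#'
#' @param ps central `parameter_set`.
#' @param master_seed master seed.
#' @param run replicate index (1-based).
#' @return a `parameter_set` with drawn values.
#' @export
draw_parameter_variant <- function(ps, master_seed, run) {
  with_stream(master_seed, "params", run = run, expr = {
    ie <- ps$intervention_effects
    ie$central <- rnorm_ci(nrow(ie), ie$central, ie$lo, ie$hi, 0, 1)
    # keep the stored interval an envelope of the draw so the variant
    # still validates (draws may land in the distribution's tails)
    ie$lo <- pmin(ie$lo, ie$central)
    ie$hi <- pmax(ie$hi, ie$central)
    ps$intervention_effects <- ie

    rr <- ps$relative_risks
    rr$rr <- rnorm_ci(nrow(rr), rr$rr, rr$rr_lo, rr$rr_hi, 0.05, Inf)
    ps$relative_risks <- rr

    el <- ps$tax$elasticity
    hw <- abs(el$elasticity) * el$rel_halfwidth
    el$elasticity <- rnorm_ci(nrow(el), el$elasticity,
                              el$elasticity - hw, el$elasticity + hw,
                              -1.999, -0.001)
    ps$tax$elasticity <- el

    pol <- ps$medications
    pol$rrr$rrr <- rnorm_ci(nrow(pol$rrr), pol$rrr$rrr, pol$rrr$lo,
                            pol$rrr$hi, 0, 1)
    pol$rrr$lo <- pmin(pol$rrr$lo, pol$rrr$rrr)
    pol$rrr$hi <- pmax(pol$rrr$hi, pol$rrr$rrr)
    for (s in names(pol$adherence)) {
      ci <- pol$adherence_ci[[s]]
      pol$adherence[[s]] <- rnorm_ci(1, pol$adherence[[s]], ci[1],
                                     ci[2], 0, 1)
    }
    ps$medications <- pol

    g <- ps$cohorts$growth
    ps$cohorts$growth <- pmax(0, stats::rnorm(length(g), g, 0.2 * g))
    ps
  })
}

#' Run the Monte Carlo uncertainty analysis
#'
#' @param ps central `parameter_set`.
#' @param scenarios named list of `scenario_spec`s (the no-intervention
#'   baseline is implicit).
#' @param spec an [uncertainty_spec()].
#' @return list of class `averted_deaths_table`: `table` (data.frame:
#'   scenario, cause, averted mean and 95% percentile CI, baseline mean,
#'   percent reduction), `shares` (mean subgroup shares of averted
#'   deaths), `runs` (per-run draws, long format), `failures`.
#' @export
run_uncertainty <- function(ps, scenarios, spec = uncertainty_spec()) {
  stopifnot(length(scenarios) >= 1)
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, function(s) s$name, "")
  }
  rows <- list()
  share_acc <- list()
  failures <- 0L
  for (r in seq_len(spec$n_runs)) {
    ps_r <- if (spec$draw_params) {
      draw_parameter_variant(ps, spec$master_seed, r)
    } else ps
    seed_r <- as.integer((as.double(spec$master_seed) + r * 9973) %%
                           2000000000)
    res <- tryCatch({
      base <- run_scenario(ps_r, scenario_preset("none"),
                           spec$n_per_cohort, seed_r,
                           spec$add_entrants)
      lapply(scenarios, function(sc) {
        averted(base, run_scenario(ps_r, sc, spec$n_per_cohort, seed_r,
                                   spec$add_entrants))
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > max(1, 0.01 * spec$n_runs)) {
        stop("more than 1% of Monte Carlo runs failed; last error: ",
             conditionMessage(res))
      }
      next
    }
    for (nm in names(res)) {
      for (cs in c("mi", "stroke")) {
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, scenario = nm, cause = cs,
          averted = res[[nm]][[cs]]$averted,
          baseline = res[[nm]][[cs]]$baseline)
      }
      key <- paste0(nm, ".mi")
      share_acc[[key]] <- c(share_acc[[key]],
                            list(res[[nm]]$mi$shares))
    }
  }
  if (!length(rows)) {
    stop("all ", spec$n_runs, " Monte Carlo run(s) failed")
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs,
                                     list(runs$scenario, runs$cause),
                                     drop = TRUE), function(d) {
    data.frame(scenario = d$scenario[1], cause = d$cause[1],
               averted = mean(d$averted),
               lo = unname(stats::quantile(d$averted, 0.025)),
               hi = unname(stats::quantile(d$averted, 0.975)),
               baseline = mean(d$baseline),
               percent = 100 * mean(d$averted) / mean(d$baseline))
  }))
  rownames(agg) <- NULL
  shares <- lapply(share_acc, function(lst) {
    list(gender_location = Reduce(`+`, lapply(lst,
                                              `[[`,
                                              "gender_location")) /
           length(lst),
         age_band = Reduce(`+`, lapply(lst, `[[`, "age_band")) /
           length(lst))
  })
  structure(list(table = agg, shares = shares, runs = runs,
                 failures = failures,
                 meta = list(spec = spec,
                             scenarios = names(scenarios))),
            class = "averted_deaths_table")
}

#' @export
print.averted_deaths_table <- function(x, ...) {
  cat("<averted_deaths_table>", length(x$meta$scenarios),
      "scenario(s),", x$meta$spec$n_runs, "runs\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (x$failures) cat("  failed runs:", x$failures, "\n")
  invisible(x)
}
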