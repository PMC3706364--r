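#' Result surfaces
#'
#' Assembles the scenario-comparison table (deaths averted with 95% CIs
#' and percent reductions, rows ordered tobacco control, pharmacological,
#' combinations), subgroup-share tables, optional per-year mortality
#' trend series, and run metadata.
#'
#' @name report_cli
NULL

.SCENARIO_ORDER <- c("smokefree", "brief_advice", "mass_media", "ad_ban",
                     "tax300_bidi", "tax300_cig", "tax300_both",
                     "aspirin", "antihypertensive", "statin",
                     "all_meds", "all_meds_80", "all_tc_max",
                     "all_tc_cumulative", "all_tc_synergy",
                     "all_tc_meds")

#' Per-year death series from a simulation result
#'
#' @param result a `simulation_result`.
#' @return data.frame: `year`, `cause`, `deaths` (census-scaled).
#' @export
mortality_trend <- function(result) {
  d <- apply(result$deaths, c(2, 3), sum)
  out <- expand.grid(year = as.integer(rownames(d)),
                     cause = colnames(d), stringsAsFactors = FALSE)
  out$deaths <- as.vector(d)
  out$scenario <- result$meta$scenario
  out
}

#' Build a report bundle
#'
#' @param adt an `averted_deaths_table` from [run_uncertainty()].
#' @param trend_results optional list of `simulation_result`s for the
#'   per-year trend series.
#' @return list of class `report_bundle`: `comparison`, `shares`,
#'   `trends`, `meta`.
#' @export
build_report <- function(adt, trend_results = NULL) {
  stopifnot(inherits(adt, "averted_deaths_table"))
  tab <- adt$table
  ord <- match(tab$scenario, .SCENARIO_ORDER)
  ord[is.na(ord)] <- length(.SCENARIO_ORDER) + 1L
  tab <- tab[order(ord, tab$scenario, tab$cause), ]
  rownames(tab) <- NULL
  # internal consistency: percent column against its numerator/denominator
  stopifnot(all(abs(tab$percent - 100 * tab$averted / tab$baseline) <
                  1e-9 * pmax(1, abs(tab$percent))))
  shares <- lapply(adt$shares, function(s) {
    lapply(s, function(v) if (sum(v) == 0) v else v / sum(v))
  })
  trends <- if (!is.null(trend_results)) {
    do.call(rbind, lapply(trend_results, mortality_trend))
  }
  structure(list(comparison = tab, shares = shares, trends = trends,
                 meta = c(adt$meta,
                          list(failures = adt$failures,
                               package_version =
                                 as.character(utils::packageVersion(
                                   "cvdmicrosim"))))),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `comparison.csv`, `shares.csv`, optionally `trends.csv`, and a
#' JSON summary with metadata.
#'
#' @param bundle a `report_bundle`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$comparison,
                   file.path(path, "comparison.csv"), row.names = FALSE)
  sh <- do.call(rbind, lapply(names(bundle$shares), function(nm) {
    s <- bundle$shares[[nm]]
    rbind(data.frame(scenario = nm, dimension = "gender_location",
                     group = names(s$gender_location),
                     share = as.numeric(s$gender_location)),
          data.frame(scenario = nm, dimension = "age_band",
                     group = names(s$age_band),
                     share = as.numeric(s$age_band)))
  }))
  if (!is.null(sh)) {
    utils::write.csv(sh, file.path(path, "shares.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$trends)) {
    utils::write.csv(bundle$trends, file.path(path, "trends.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(comparison = bundle$comparison,
         meta = bundle$meta[c("scenarios", "failures",
                              "package_version")]),
    file.path(path, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
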