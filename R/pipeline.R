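#' Analysis configuration
#'
#' Collects every knob of the end-to-end analysis. All Monte Carlo stages
#' derive their seeds from the single root `seed`, so a pipeline run is fully
#' reproducible.
#'
#' @param cases_path,population_path optional CSV input paths (alternatively
#'   pass objects straight to [run_pipeline()]).
#' @param grid a [lag_grid()].
#' @param B_knox,B_density,B_spectrum,B_mc Monte Carlo replicate counts
#'   (all >= 99; `B_density` >= 199).
#' @param seed mandatory root seed.
#' @param critical_lags optional `c(s, t)` override; `NULL` selects them from
#'   the Knox grid.
#' @param characteristics columns compared between clustered and nonclustered
#'   cases.
#' @param ref_levels named list of reference levels.
#' @param mc_for characteristics tested by Monte Carlo simulation (must be
#'   location-derived; see [mc_covariate_pvalue()]).
#' @param mc_funs named list of `function(x, y)` constructors for `mc_for`.
#' @param density_method `"mc"` or `"poisson"` (see [density_index()]).
#' @param alpha familywise error level.
#' @param out_dir optional output directory; when set, [run_pipeline()] writes
#'   CSV/JSON results and a run-metadata log there.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(cases_path = NULL, population_path = NULL,
                            grid = lag_grid(), B_knox = 999, B_density = 999,
                            B_spectrum = 999, B_mc = 999, seed,
                            critical_lags = NULL,
                            characteristics = c("marker_positive", "sex", "urban"),
                            ref_levels = list(marker_positive = "no"),
                            mc_for = character(0), mc_funs = list(),
                            density_method = "mc", alpha = 0.05,
                            out_dir = NULL) {
  if (missing(seed)) stop("'seed' is mandatory for any stochastic step", call. = FALSE)
  if (min(B_knox, B_spectrum, B_mc) < 99 || B_density < 199) {
    stop("replicate counts must be >= 99 (B_density >= 199)", call. = FALSE)
  }
  structure(list(cases_path = cases_path, population_path = population_path,
                 grid = grid, B_knox = B_knox, B_density = B_density,
                 B_spectrum = B_spectrum, B_mc = B_mc, seed = as.integer(seed),
                 critical_lags = critical_lags,
                 characteristics = characteristics, ref_levels = ref_levels,
                 mc_for = mc_for, mc_funs = mc_funs,
                 density_method = density_method, alpha = alpha,
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Flat YAML mirroring the arguments of [analysis_config()]; `spatial_lags_m`
#' and `temporal_lags_days` become the lag grid, dates are ISO-8601.
#'
#' @param path YAML file path.
#' @return Object of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- lag_grid(
    spatial_lags_m = if (!is.null(y$spatial_lags_m)) y$spatial_lags_m else c(500, 1000, 2000, 5000, 10000),
    temporal_lags_days = if (!is.null(y$temporal_lags_days)) y$temporal_lags_days else c(182, 365, 548, 730)
  )
  args <- y[intersect(names(y), setdiff(names(formals(analysis_config)),
                                        c("grid", "mc_funs")))]
  args$grid <- grid
  do.call(analysis_config, args)
}

#' Run the full space-time clustering pipeline
#'
#' The three analysis steps in order: (1) Knox tests over the lag grid with
#' the population-shift-adjusted Monte Carlo null and max-statistic
#' correction, selecting the critical lags; (2) classification of cases as
#' clustered/nonclustered at the critical lags, the child-population-density
#' index, and the clustered-vs-nonclustered comparison with Holm correction;
#' (3) graph linking of clustered cases into local clusters and the Monte
#' Carlo test of the cluster-size spectrum. Sibling cases are excluded first.
#'
#' @param config an [analysis_config()].
#' @param cases optional case table (otherwise read from `config$cases_path`).
#' @param population optional `population_model` (otherwise read from
#'   `config$population_path`).
#' @return Object of class `knox_pipeline` bundling `cases` (after sibling
#'   exclusion), `knox`, `labeling`, `density`, `comparison`, `spectrum`, and
#'   a `meta` record (seeds, critical lags, package version).
#' @export
run_pipeline <- function(config, cases = NULL, population = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(cases)) {
    if (is.null(config$cases_path)) stop("no cases given", call. = FALSE)
    cases <- run_stage("read_cases", read_case_table(config$cases_path))
  }
  if (is.null(population)) {
    if (is.null(config$population_path)) stop("no population given", call. = FALSE)
    population <- run_stage("read_population", read_population(config$population_path))
  }
  seeds <- stage_seeds(config$seed, c("knox", "density", "spectrum", "mc_cov"))

  if ("sibling_group" %in% names(cases)) {
    cases <- run_stage("exclude_siblings", exclude_siblings(cases))
  }

  knox <- run_stage("knox", knox_test(cases, population, config$grid,
                                      B = config$B_knox, seed = seeds["knox"]))
  crit <- if (!is.null(config$critical_lags)) {
    c(s = config$critical_lags[[1]], t = config$critical_lags[[2]])
  } else knox$critical_lags

  labeling <- run_stage("link_clusters", link_clusters(cases, crit["s"], crit["t"]))
  dens <- run_stage("density", density_index(cases, population, crit["s"], crit["t"],
                                             B = config$B_density,
                                             seed = seeds["density"],
                                             method = config$density_method))
  comparison <- run_stage("comparison", compare_characteristics(
    cases, labeling$clustered, config$characteristics,
    density = dens, ref_levels = config$ref_levels,
    mc_for = config$mc_for, mc_funs = config$mc_funs,
    population = population, s_star = crit["s"], t_star = crit["t"],
    B = config$B_mc, seed = seeds["mc_cov"], alpha = config$alpha))
  spectrum <- run_stage("size_spectrum", size_spectrum_test(
    cases, population, crit["s"], crit["t"],
    B = config$B_spectrum, seed = seeds["spectrum"]))

  meta <- list(seed = config$seed, stage_seeds = as.list(seeds),
               critical_lags = as.list(crit),
               critical_lags_overridden = !is.null(config$critical_lags),
               n_cases = nrow(cases),
               excluded_siblings = attr(cases, "excluded"),
               density_method = config$density_method,
               package_version = as.character(utils::packageVersion("knoxclust")),
               timestamp = format(Sys.time(), tz = "UTC"))

  result <- structure(list(cases = cases, knox = knox, labeling = labeling,
                           density = dens, comparison = comparison,
                           spectrum = spectrum, meta = meta),
                      class = "knox_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labeled <- result$cases
  labeled$clustered <- result$labeling$clustered
  labeled$cluster_id <- result$labeling$cluster_id
  write_case_table(labeled, file.path(out_dir, "clusters.csv"))
  utils::write.csv(as.data.frame(result$density),
                   file.path(out_dir, "density.csv"), row.names = FALSE)
  utils::write.csv(result$comparison$rows,
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(cells = result$knox$cells,
         adjusted_p_max = result$knox$adjusted_p_max,
         critical_lags = as.list(result$knox$critical_lags),
         n_replicates = result$knox$n_replicates),
    file.path(out_dir, "knox.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(result$spectrum$spectrum,
                       file.path(out_dir, "spectrum.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(result$meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.knox_pipeline <- function(x, ...) {
  cat("Space-time clustering pipeline\n")
  cat(sprintf("  %d cases (after sibling exclusion), seed %d\n",
              x$meta$n_cases, x$meta$seed))
  cat(sprintf("  critical lags: %.0f m, %.0f days%s\n",
              x$meta$critical_lags$s, x$meta$critical_lags$t,
              if (x$meta$critical_lags_overridden) " (overridden)" else ""))
  cat(sprintf("  Knox min p = %.4g, adjusted p = %.4g\n",
              x$knox$min_p, x$knox$adjusted_p_max))
  cat(sprintf("  clustered: %d (%.1f%%)\n", sum(x$labeling$clustered),
              100 * mean(x$labeling$clustered)))
  cat("\nUse print() on $knox, $labeling, $comparison, $spectrum for details.\n")
  invisible(x)
}
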