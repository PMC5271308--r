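#' Configuration for the synthetic registry generator
#'
#' Bundles and validates every parameter of the synthetic child population and
#' case generator. Defaults emulate a national childhood-leukemia registry:
#' roughly 1.2 million children spread over a 100 x 70 km region in a mixture
#' of population centers that drift between census-style snapshots, and 1,282
#' leukemia cases born 1985--2014 whose birth locations follow the population.
#' Under the null (`cluster_rate = 0`) cases carry no space-time interaction;
#' with `cluster_rate > 0` localized "mini-epidemic" excesses (default radius
#' 500 m, duration 365 days, one excess case each) are superimposed and a
#' binary cytogenetic-style marker is enriched inside them.
#'
#' @param region_extent numeric length 4, `c(xmin, xmax, ymin, ymax)` in meters.
#' @param snapshot_dates `Date` vector (>= 2) of population snapshot dates.
#' @param n_children total child population per snapshot.
#' @param cell_size_m side length of the square population grid cells, meters.
#' @param n_population_centers number of population centers (ignored when
#'   `centers` is supplied).
#' @param centers optional data frame with columns `x`, `y`, `sd_m`,
#'   `weight_start`, `weight_end`: per-center location, Gaussian spread and
#'   intensity share at the first and last snapshot (linear drift in between).
#'   `NULL` draws centers deterministically from `seed`.
#' @param n_cases number of cases in the output table (before added siblings).
#' @param study_window `Date` length 2, interval of birth dates.
#' @param cluster_rate expected number of induced space-time clusters.
#' @param cluster_radius_m spatial radius of an induced cluster, meters.
#' @param cluster_duration_days temporal extent of an induced cluster, days.
#' @param cluster_excess_cases integer vector; the number of excess cases per
#'   induced cluster is sampled uniformly from it (default: exactly 1).
#' @param marker_prevalence_background probability that a case outside induced
#'   clusters is marker positive.
#' @param marker_prevalence_in_cluster probability that a case inside an
#'   induced cluster is marker positive.
#' @param marker_untested_rate probability that the marker status is missing
#'   (missing completely at random; emulates testing introduced mid-study).
#' @param sibling_pair_rate per-case probability of adding a sibling case born
#'   within 50 m and 3 years, sharing a `sibling_group` id.
#' @param n_point_sources number of fixed point sources (e.g. industrial
#'   sites) used for the location-derived `dist_source_m` covariate.
#' @param urban_quantile children-weighted quantile of local cell counts above
#'   which a birth cell is labeled "urban".
#' @param seed integer; fully determines all generator output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_population()], [generate_cases()]
#' @export
sim_config <- function(region_extent = c(0, 100000, 0, 70000),
                       snapshot_dates = as.Date(c("1985-01-01", "1995-01-01",
                                                  "2005-01-01", "2015-01-01")),
                       n_children = 1200000,
                       cell_size_m = 1000,
                       n_population_centers = 15,
                       centers = NULL,
                       n_cases = 1282,
                       study_window = as.Date(c("1985-01-01", "2014-12-31")),
                       cluster_rate = 0,
                       cluster_radius_m = 500,
                       cluster_duration_days = 365,
                       cluster_excess_cases = 1L,
                       marker_prevalence_background = 0.25,
                       marker_prevalence_in_cluster = 0.75,
                       marker_untested_rate = 0.556,
                       sibling_pair_rate = 0.004,
                       n_point_sources = 2,
                       urban_quantile = 0.5,
                       seed) {
  if (missing(seed)) stop("'seed' is mandatory: it fully determines the output", call. = FALSE)
  cfg <- list(
    region_extent = as.numeric(region_extent),
    snapshot_dates = sort(as.Date(snapshot_dates)),
    n_children = as.integer(n_children),
    cell_size_m = as.numeric(cell_size_m),
    n_population_centers = as.integer(n_population_centers),
    centers = centers,
    n_cases = as.integer(n_cases),
    study_window = as.Date(study_window),
    cluster_rate = as.numeric(cluster_rate),
    cluster_radius_m = as.numeric(cluster_radius_m),
    cluster_duration_days = as.numeric(cluster_duration_days),
    cluster_excess_cases = as.integer(cluster_excess_cases),
    marker_prevalence_background = as.numeric(marker_prevalence_background),
    marker_prevalence_in_cluster = as.numeric(marker_prevalence_in_cluster),
    marker_untested_rate = as.numeric(marker_untested_rate),
    sibling_pair_rate = as.numeric(sibling_pair_rate),
    n_point_sources = as.integer(n_point_sources),
    urban_quantile = as.numeric(urban_quantile),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$region_extent) != 4 ||
      cfg$region_extent[2] <= cfg$region_extent[1] ||
      cfg$region_extent[4] <= cfg$region_extent[3]) {
    stop("'region_extent' must be c(xmin, xmax, ymin, ymax) with positive extent", call. = FALSE)
  }
  if (length(cfg$snapshot_dates) < 2) {
    stop("at least 2 snapshot dates are needed to represent population shifts", call. = FALSE)
  }
  if (is.null(cfg$centers) && cfg$n_population_centers < 1) {
    stop("at least one population center is required", call. = FALSE)
  }
  if (!is.null(cfg$centers)) {
    need <- c("x", "y", "sd_m", "weight_start", "weight_end")
    if (!all(need %in% names(cfg$centers)) || nrow(cfg$centers) < 1) {
      stop("'centers' must have >= 1 row and columns x, y, sd_m, weight_start, weight_end", call. = FALSE)
    }
  }
  probs <- c(cfg$marker_prevalence_background, cfg$marker_prevalence_in_cluster,
             cfg$marker_untested_rate, cfg$sibling_pair_rate, cfg$urban_quantile)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$cluster_rate > 0 &&
      (cfg$cluster_radius_m <= 0 || cfg$cluster_duration_days <= 0)) {
    stop("cluster radius and duration must be positive when cluster_rate > 0", call. = FALSE)
  }
  if (cfg$n_cases < 1) stop("'n_cases' must be >= 1", call. = FALSE)
  if (cfg$study_window[2] <= cfg$study_window[1]) {
    stop("'study_window' must be an increasing date interval", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic registry configuration\n")
  cat(sprintf("  region: %.0f x %.0f km, cells %.0f m, %d children\n",
              diff(x$region_extent[1:2]) / 1000, diff(x$region_extent[3:4]) / 1000,
              x$cell_size_m, x$n_children))
  cat(sprintf("  snapshots: %s\n", paste(format(x$snapshot_dates), collapse = ", ")))
  cat(sprintf("  cases: %d born %s to %s\n", x$n_cases,
              format(x$study_window[1]), format(x$study_window[2])))
  cat(sprintf("  induced clusters: rate %.2f, radius %.0f m, duration %.0f d\n",
              x$cluster_rate, x$cluster_radius_m, x$cluster_duration_days))
  cat(sprintf("  marker prevalence: %.2f background, %.2f in-cluster, %.2f untested\n",
              x$marker_prevalence_background, x$marker_prevalence_in_cluster,
              x$marker_untested_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
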