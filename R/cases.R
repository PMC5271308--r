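#' Generate a synthetic case table
#'
#' Draws case birth events from the time-interpolated population intensity:
#' birth dates uniform over the study window, birth locations proportional to
#' the local child population at each case's birth date (this is exactly the
#' null the Monte Carlo machinery resamples from). When `cluster_rate > 0`,
#' localized space-time excesses are superimposed: each induced cluster has a
#' seed case plus excess cases uniform within `cluster_radius_m` and within
#' `cluster_duration_days / 2` in time of the seed, all tagged with a
#' `truth_cluster_id`. A binary marker (emulating a cytogenetic subtype) is
#' enriched inside induced clusters; a configurable fraction of cases is left
#' untested. Sibling cases born within 50 m and 3 years are appended with a
#' shared `sibling_group`, so the sibling-exclusion rule can be exercised.
#'
#' @param config a [sim_config()] object.
#' @param population population snapshots from [generate_population()].
#' @return A data frame (the case table) with columns `case_id`, `x_birth`,
#'   `y_birth`, `birth_date`, `diagnosis_date`, `marker_positive`
#'   ("yes"/"no"/"untested"), `sex`, `urban`, `dist_source_m`,
#'   `sibling_group`, `truth_cluster_id`.
#' @export
generate_cases <- function(config, population) {
  stopifnot(inherits(config, "sim_config"), inherits(population, "population_model"))
  validate_sim_config(config)
  if (nrow(population$cells) < 1) stop("population is empty", call. = FALSE)
  if (config$cluster_rate > 0 &&
      (config$cluster_radius_m <= 0 || config$cluster_duration_days <= 0)) {
    stop("cluster radius and duration must be positive when cluster_rate > 0", call. = FALSE)
  }
  ext <- config$region_extent
  win <- as.numeric(config$study_window)

  with_seed(derive_seed(config$seed, 1L), {
    n_clusters <- if (config$cluster_rate > 0) stats::rpois(1, config$cluster_rate) else 0L
    excess <- if (n_clusters > 0) {
      config$cluster_excess_cases[sample.int(length(config$cluster_excess_cases),
                                             n_clusters, replace = TRUE)]
    } else integer(0)
    n_induced <- if (n_clusters > 0) sum(1L + excess) else 0L
    if (n_induced >= config$n_cases) {
      stop("induced cluster cases exceed n_cases; lower cluster_rate or raise n_cases",
           call. = FALSE)
    }
    n_bg <- config$n_cases - n_induced

    rand_dates <- function(n) win[1] + floor(stats::runif(n) * (win[2] - win[1] + 1))
    # background + cluster seeds: locations follow the population at birth date
    d_bg <- rand_dates(n_bg)
    d_seed <- rand_dates(n_clusters)
    d_null <- c(d_bg, d_seed)
    cells0 <- sample_cells(population, snapshot_weights(population, d_null))[, 1]
    xy0 <- jitter_in_cell(population, cells0)

    bdate <- d_null
    x <- xy0[, "x"]; y <- xy0[, "y"]
    truth <- c(rep(NA_integer_, n_bg),
               if (n_clusters > 0) seq_len(n_clusters) else integer(0))
    if (n_clusters > 0) {
      seed_idx <- n_bg + seq_len(n_clusters)
      for (k in seq_len(n_clusters)) {
        m <- excess[k]
        ang <- stats::runif(m, 0, 2 * pi)
        rad <- config$cluster_radius_m * sqrt(stats::runif(m))
        dx <- x[seed_idx[k]] + rad * cos(ang)
        dy <- y[seed_idx[k]] + rad * sin(ang)
        dd <- bdate[seed_idx[k]] +
          round(stats::runif(m, -config$cluster_duration_days / 2,
                             config$cluster_duration_days / 2))
        x <- c(x, pmin(pmax(dx, ext[1]), ext[2]))
        y <- c(y, pmin(pmax(dy, ext[3]), ext[4]))
        bdate <- c(bdate, pmin(pmax(dd, win[1]), win[2]))
        truth <- c(truth, rep(k, m))
      }
    }
    n <- length(x)

    age_days <- floor(stats::runif(n) * 16 * 365.25)
    diag_date <- bdate + age_days

    in_cluster <- !is.na(truth)
    p_marker <- ifelse(in_cluster, config$marker_prevalence_in_cluster,
                       config$marker_prevalence_background)
    marker <- ifelse(stats::rbinom(n, 1, p_marker) == 1, "yes", "no")
    marker[stats::rbinom(n, 1, config$marker_untested_rate) == 1] <- "untested"

    sex <- ifelse(stats::rbinom(n, 1, 0.51) == 1, "male", "female")

    # urban: local interpolated child count above the children-weighted quantile
    lam_mid <- intensity_at(population, mean(win))[, 1]
    thr <- weighted_quantile(lam_mid, lam_mid, config$urban_quantile)
    sw <- snapshot_weights(population, bdate)
    cell_idx <- nearest_cell(population, x, y)
    lam_i <- population$counts[cbind(cell_idx, sw$lo)] * (1 - sw$w) +
      population$counts[cbind(cell_idx, sw$hi)] * sw$w
    urban <- ifelse(lam_i > thr, "urban", "rural")

    sources <- cbind(stats::runif(config$n_point_sources, ext[1], ext[2]),
                     stats::runif(config$n_point_sources, ext[3], ext[4]))
    dist_source <- if (config$n_point_sources > 0) {
      apply(sources, 1, function(s) sqrt((x - s[1])^2 + (y - s[2])^2))
    } else matrix(Inf, n, 1)
    dist_source_m <- if (is.matrix(dist_source)) do.call(pmin, as.data.frame(dist_source)) else dist_source

    cases <- data.frame(
      case_id = sprintf("C%05d", seq_len(n)),
      x_birth = x, y_birth = y,
      birth_date = as.Date(bdate, origin = "1970-01-01"),
      diagnosis_date = as.Date(diag_date, origin = "1970-01-01"),
      marker_positive = marker, sex = sex, urban = urban,
      dist_source_m = dist_source_m,
      sibling_group = NA_character_,
      truth_cluster_id = truth,
      stringsAsFactors = FALSE
    )

    n_sib <- stats::rbinom(1, config$n_cases, config$sibling_pair_rate)
    if (n_sib > 0) {
      idx <- sample.int(n, min(n_sib, n))
      sib <- cases[idx, , drop = FALSE]
      grp <- sprintf("S%03d", seq_along(idx))
      cases$sibling_group[idx] <- grp
      ang <- stats::runif(length(idx), 0, 2 * pi)
      rad <- stats::runif(length(idx), 5, 49)
      sib$x_birth <- pmin(pmax(sib$x_birth + rad * cos(ang), ext[1]), ext[2])
      sib$y_birth <- pmin(pmax(sib$y_birth + rad * sin(ang), ext[3]), ext[4])
      shift <- sample(c(-(1:1095), 1:1095), length(idx), replace = TRUE)
      bd <- pmin(pmax(as.numeric(sib$birth_date) + shift, win[1]), win[2])
      sib$birth_date <- as.Date(bd, origin = "1970-01-01")
      sib$diagnosis_date <- sib$birth_date + floor(stats::runif(length(idx)) * 16 * 365.25)
      sib$sibling_group <- grp
      sib$case_id <- sprintf("C%05d", n + seq_along(idx))
      sib$truth_cluster_id <- NA_integer_
      cases <- rbind(cases, sib)
    }
    rownames(cases) <- NULL
    cases
  })
}

nearest_cell <- function(population, x, y) {
  h <- population$cell_size_m
  ux <- sort(unique(population$cells$x))
  uy <- sort(unique(population$cells$y))
  ix <- pmin(pmax(round((x - ux[1]) / h) + 1L, 1L), length(ux))
  iy <- pmin(pmax(round((y - uy[1]) / h) + 1L, 1L), length(uy))
  match(paste(ux[ix], uy[iy]), paste(population$cells$x, population$cells$y))
}

weighted_quantile <- function(values, weights, q) {
  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  values[o][which(cw >= q)[1]]
}
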