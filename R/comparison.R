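#' Odds ratio and Wald confidence interval from a 2x2 table
#'
#' `OR = (a d) / (b c)` with the Wald interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell triggers the
#' Haldane-Anscombe 0.5 continuity correction on all four cells, with a
#' warning.
#'
#' @param a exposed clustered count.
#' @param b unexposed clustered count.
#' @param c exposed nonclustered count.
#' @param d unexposed nonclustered count.
#' @param conf_level confidence level (default 0.95).
#' @return List with `or`, `ci` (length 2), `log_or`, `se`, `counts`,
#'   `continuity` (logical), of class `or_estimate`.
#' @export
or_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("all four counts must be finite and nonnegative", call. = FALSE)
  }
  continuity <- any(counts == 0)
  if (continuity) {
    warning("zero cell in 2x2 table: applying 0.5 continuity correction")
    counts <- counts + 0.5
  }
  log_or <- log(counts["a"]) + log(counts["d"]) - log(counts["b"]) - log(counts["c"])
  se <- sqrt(sum(1 / counts))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(or = unname(exp(log_or)),
         ci = unname(exp(log_or + c(-1, 1) * z * se)),
         log_or = unname(log_or), se = se,
         counts = c(a = a, b = b, c = c, d = d), continuity = continuity),
    class = "or_estimate"
  )
}

#' @export
print.or_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f)%s\n", x$or, x$ci[1], x$ci[2],
              if (x$continuity) " [0.5 continuity correction]" else ""))
  invisible(x)
}

#' Logistic regression of clustering status on a case characteristic
#'
#' Fits `clustered ~ characteristic` (categorical dummies against a
#' configurable reference level) by maximum likelihood, optionally adding the
#' child-population-density index as a linear adjustment term. Cases with a
#' missing characteristic are excluded listwise for this fit. Per-level odds
#' ratios carry Wald confidence intervals; the characteristic-level p-value is
#' the likelihood-ratio test against the nested model without the
#' characteristic.
#'
#' @param cases a case table.
#' @param clustered logical vector of clustered flags (from
#'   [classify_clustered()] or [link_clusters()]`$clustered`).
#' @param characteristic name of the case-table column to test.
#' @param density optional [density_index()] object (matched by `case_id`).
#' @param ref_level optional reference level; default is the first level.
#' @param conf_level confidence level for Wald intervals.
#' @return An object of class `clustering_model`: list with `characteristic`,
#'   `levels` data frame (`level`, `n_clustered`, `N_clustered`,
#'   `n_nonclustered`, `N_nonclustered`, `or`, `ci_low`, `ci_high`), `p_lrt`,
#'   `adjusted` (logical), `separation` (logical), and the `fit`.
#' @export
fit_clustering_model <- function(cases, clustered, characteristic,
                                 density = NULL, ref_level = NULL,
                                 conf_level = 0.95) {
  stopifnot(characteristic %in% names(cases), length(clustered) == nrow(cases))
  x <- cases[[characteristic]]
  miss <- is.na(x)
  if (is.character(x) || is.factor(x)) miss <- miss | x == "untested"
  dat <- data.frame(clustered = clustered[!miss],
                    x = factor(x[!miss]), stringsAsFactors = FALSE)
  if (nlevels(dat$x) < 2) {
    stop(sprintf("characteristic '%s' needs >= 2 observed levels", characteristic),
         call. = FALSE)
  }
  if (!is.null(ref_level)) dat$x <- stats::relevel(dat$x, ref = ref_level)
  adjusted <- !is.null(density)
  if (adjusted) {
    dat$dens <- density$index[match(cases$case_id[!miss], density$case_id)]
    if (any(is.na(dat$dens))) stop("density index missing for some cases", call. = FALSE)
    fit <- stats::glm(clustered ~ x + dens, family = stats::binomial(), data = dat)
    fit0 <- stats::glm(clustered ~ dens, family = stats::binomial(), data = dat)
  } else {
    fit <- stats::glm(clustered ~ x, family = stats::binomial(), data = dat)
    fit0 <- stats::glm(clustered ~ 1, family = stats::binomial(), data = dat)
  }
  separation <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) || !fit$converged
  if (separation) {
    warning(sprintf("possible separation fitting '%s'; consider the Monte Carlo p-value",
                    characteristic))
  }
  p_lrt <- stats::pchisq(fit0$deviance - fit$deviance,
                         df = fit0$df.residual - fit$df.residual,
                         lower.tail = FALSE)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lv <- levels(dat$x)
  co <- stats::coef(summary(fit))
  rows <- lapply(lv, function(l) {
    ncl <- sum(dat$clustered & dat$x == l)
    nnc <- sum(!dat$clustered & dat$x == l)
    if (l == lv[1]) {
      c(or = 1, lo = NA_real_, hi = NA_real_, ncl = ncl, nnc = nnc)
    } else {
      nm <- paste0("x", l)
      est <- co[nm, "Estimate"]; se <- co[nm, "Std. Error"]
      c(or = exp(est), lo = exp(est - z * se), hi = exp(est + z * se),
        ncl = ncl, nnc = nnc)
    }
  })
  rows <- do.call(rbind, rows)
  structure(
    list(characteristic = characteristic,
         levels = data.frame(
           level = lv,
           n_clustered = as.integer(rows[, "ncl"]),
           N_clustered = sum(dat$clustered),
           n_nonclustered = as.integer(rows[, "nnc"]),
           N_nonclustered = sum(!dat$clustered),
           or = rows[, "or"], ci_low = rows[, "lo"], ci_high = rows[, "hi"],
           row.names = NULL),
         p_lrt = p_lrt, adjusted = adjusted, separation = separation,
         fit = fit),
    class = "clustering_model"
  )
}

#' @export
print.clustering_model <- function(x, ...) {
  cat(sprintf("Clustered vs nonclustered: %s (%s, LRT p = %.4g)\n",
              x$characteristic, if (x$adjusted) "density adjusted" else "unadjusted",
              x$p_lrt))
  print(format(x$levels, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Monte Carlo p-value for a geographically determined covariate
#'
#' For covariates that are deterministic functions of birth location (distance
#' bands to a point source, urbanization of the birth cell, ...), the
#' likelihood-ratio test of the logistic fit is not valid because close cases
#' share the covariate. The p-value is instead calibrated by simulation: each
#' null replicate resamples locations from the population, re-classifies
#' clustered status at the critical lags, recomputes the covariate from the
#' new locations, and refits; `p = (1 + #\{stat_b >= stat_obs\}) / (B + 1)`
#' on the LRT statistic.
#'
#' @inheritParams classify_clustered
#' @param population a `population_model`.
#' @param covariate_fun `function(x, y)` returning the covariate (factor or
#'   character) from birth coordinates.
#' @param B replicates (>= 99).
#' @param seed integer seed.
#' @return List with `p`, `stat_obs`, `B`, class `mc_covariate_test`.
#' @export
mc_covariate_pvalue <- function(cases, population, s_star, t_star,
                                covariate_fun, B = 999, seed = 1) {
  if (!is.function(covariate_fun)) {
    stop("'covariate_fun' must be a function of birth coordinates (x, y)", call. = FALSE)
  }
  if (B < 99) stop("B must be >= 99", call. = FALSE)
  lrt_stat <- function(x, y) {
    flags <- classify_clustered(data.frame(x_birth = x, y_birth = y,
                                           birth_date = cases$birth_date),
                                s_star, t_star)
    cv <- factor(covariate_fun(x, y))
    if (nlevels(cv) < 2) return(0)
    # separation warnings are irrelevant here: the LRT statistic is
    # calibrated against its own Monte Carlo null, not a chi-square
    suppressWarnings({
      fit <- stats::glm(flags ~ cv, family = stats::binomial())
      fit0 <- stats::glm(flags ~ 1, family = stats::binomial())
    })
    fit0$deviance - fit$deviance
  }
  stat_obs <- lrt_stat(cases$x_birth, cases$y_birth)
  stats_b <- with_seed(seed, {
    rc <- replicate_coords(cases, population, B)
    vapply(seq_len(B), function(b) lrt_stat(rc$x[, b], rc$y[, b]), numeric(1))
  })
  structure(list(p = (1 + sum(stats_b >= stat_obs)) / (B + 1),
                 stat_obs = stat_obs, B = B),
            class = "mc_covariate_test")
}

#' @export
print.mc_covariate_test <- function(x, ...) {
  cat(sprintf("Monte Carlo covariate test: LRT stat %.3f, p = %.4g (B = %d)\n",
              x$stat_obs, x$p, x$B))
  invisible(x)
}

#' Holm step-down adjustment of labeled p-values
#'
#' Step-down: the i-th smallest p-value is multiplied by `m - i + 1`,
#' monotonicity is enforced by a running maximum, and results are capped at 1.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param labels optional labels (default `names(p)`).
#' @param alpha familywise error rate for the rejection flags.
#' @return An object of class `holm_result`: data frame with `label`, `p_raw`,
#'   `p_adjusted`, `reject`.
#' @export
holm_adjust <- function(p, labels = names(p), alpha = 0.05) {
  if (length(p) == 0) stop("empty p-value list", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("p", seq_along(p))
  adj <- stats::p.adjust(p, method = "holm")
  structure(data.frame(label = labels, p_raw = p, p_adjusted = adj,
                       reject = adj <= alpha, row.names = NULL),
            class = c("holm_result", "data.frame"), alpha = alpha)
}

#' Clustered vs nonclustered comparison table
#'
#' Runs [fit_clustering_model()] for a set of characteristics, unadjusted and
#' (when a density index is supplied) density-adjusted, and Holm-adjusts the
#' characteristic-level p-values. For characteristics named in `mc_for` the
#' row p-value is replaced by the Monte Carlo calibration of
#' [mc_covariate_pvalue()] (those characteristics must be derivable from birth
#' location via `mc_funs`).
#'
#' @param cases a case table.
#' @param clustered logical clustered flags.
#' @param characteristics character vector of case-table columns to compare.
#' @param density optional [density_index()].
#' @param ref_levels named list of reference levels per characteristic.
#' @param mc_for characteristics whose p-value comes from Monte Carlo
#'   simulation; requires `population`, `s_star`, `t_star` and entries in
#'   `mc_funs`.
#' @param mc_funs named list of `function(x, y)` covariate constructors.
#' @param population,s_star,t_star,B,seed Monte Carlo machinery for `mc_for`.
#' @param alpha familywise level for Holm rejection flags.
#' @return Object of class `comparison_table`: list with `rows` (one data
#'   frame row per characteristic level, Table-style), `tests` (one row per
#'   characteristic: `p`, `p_source`, `p_holm`), `alpha`.
#' @export
compare_characteristics <- function(cases, clustered, characteristics,
                                    density = NULL, ref_levels = list(),
                                    mc_for = character(0), mc_funs = list(),
                                    population = NULL, s_star = NULL,
                                    t_star = NULL, B = 999, seed = 1,
                                    alpha = 0.05) {
  rows <- list(); pvals <- c(); src <- c()
  for (ch in characteristics) {
    ref <- if (ch %in% names(ref_levels)) ref_levels[[ch]] else NULL
    unadj <- fit_clustering_model(cases, clustered, ch, ref_level = ref)
    adj <- if (!is.null(density)) {
      fit_clustering_model(cases, clustered, ch, density = density, ref_level = ref)
    } else NULL
    if (ch %in% mc_for) {
      if (is.null(population) || is.null(mc_funs[[ch]])) {
        stop(sprintf("Monte Carlo p for '%s' needs 'population' and an entry in 'mc_funs'", ch),
             call. = FALSE)
      }
      mc <- mc_covariate_pvalue(cases, population, s_star, t_star,
                                mc_funs[[ch]], B = B,
                                seed = derive_seed(seed, match(ch, characteristics)))
      p_ch <- mc$p; p_src <- "mc"
    } else {
      p_ch <- if (!is.null(adj)) adj$p_lrt else unadj$p_lrt
      p_src <- "lrt"
    }
    lv <- unadj$levels
    lv$characteristic <- ch
    lv$or_adj <- if (!is.null(adj)) adj$levels$or else NA_real_
    lv$ci_adj_low <- if (!is.null(adj)) adj$levels$ci_low else NA_real_
    lv$ci_adj_high <- if (!is.null(adj)) adj$levels$ci_high else NA_real_
    lv$p <- p_ch
    lv$p_source <- p_src
    rows[[ch]] <- lv
    pvals <- c(pvals, p_ch); src <- c(src, p_src)
  }
  holm <- holm_adjust(pvals, labels = characteristics, alpha = alpha)
  tests <- data.frame(characteristic = characteristics, p = pvals,
                      p_source = src, p_holm = holm$p_adjusted,
                      reject = holm$reject, row.names = NULL)
  structure(list(rows = do.call(rbind, c(rows, make.row.names = FALSE)),
                 tests = tests, alpha = alpha),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Clustered vs nonclustered case comparison\n")
  df <- x$rows
  df$or <- sprintf("%.2f", df$or)
  show <- df[, c("characteristic", "level", "n_clustered", "N_clustered",
                 "n_nonclustered", "N_nonclustered", "or")]
  if (!all(is.na(x$rows$or_adj))) show$or_adj <- sprintf("%.2f", x$rows$or_adj)
  print(show, row.names = FALSE)
  cat("\nCharacteristic-level tests (Holm-adjusted):\n")
  print(format(x$tests, digits = 3), row.names = FALSE)
  invisible(x)
}
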