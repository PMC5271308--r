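#' Per-case child-population-density index
#'
#' For each case, estimates the probability `p_chance` that at least one other
#' case would fall within the critical lags of it *by chance alone* -- i.e.
#' under the population-shift-adjusted null -- and returns its log odds
#' `log(p_chance / (1 - p_chance))`. Cases in densely populated areas are more
#' likely to be clustered by chance; adding this index to a logistic model of
#' clustered status adjusts the case-case comparison for that artifact.
#'
#' Two estimators are provided. `"mc"` (default) holds case i at its observed
#' location and date, resamples all other cases from the null `B` times, and
#' takes the share of replicates in which some other case lands within the
#' lags. `"poisson"` computes the expected number `lambda_i` of other cases in
#' the space-time cylinder around case i from the population intensity (sum
#' over temporally close cases of their probability of falling in the spatial
#' disc) and sets `p_chance = 1 - exp(-lambda_i)`.
#'
#' Estimates are clamped to `[1/(2B), 1 - 1/(2B)]` before the logit so the
#' index is always finite; a warning is issued when clamping occurs.
#'
#' @inheritParams classify_clustered
#' @param population a `population_model`.
#' @param B Monte Carlo replicates for method `"mc"` (>= 199).
#' @param seed integer seed (method `"mc"`).
#' @param method `"mc"` or `"poisson"`.
#' @return An object of class `density_index`: data frame with `case_id`,
#'   `p_chance`, `index`, plus attributes `method`, `B`, `s_star`, `t_star`.
#' @export
density_index <- function(cases, population, s_star, t_star, B = 999,
                          seed = 1, method = c("mc", "poisson")) {
  method <- match.arg(method)
  assert_positive(s_star, "s_star"); assert_positive(t_star, "t_star")
  stopifnot(inherits(population, "population_model"))
  n <- nrow(cases)
  d <- days_num(cases$birth_date)

  if (method == "mc") {
    if (B < 199) stop("B must be >= 199 for method 'mc'", call. = FALSE)
    tp <- temporal_pairs(d, t_star)
    # ordered pairs: observed case i vs replicate location of case j
    oi <- c(tp$i, tp$j)
    oj <- c(tp$j, tp$i)
    hits <- integer(n)
    with_seed(seed, {
      rc <- replicate_coords(cases, population, B)
      for (b in seq_len(B)) {
        close <- (cases$x_birth[oi] - rc$x[oj, b])^2 +
          (cases$y_birth[oi] - rc$y[oj, b])^2 < s_star^2
        if (any(close)) {
          hit_cases <- unique(oi[close])
          hits[hit_cases] <- hits[hit_cases] + 1L
        }
      }
    })
    p <- hits / B
  } else {
    # expected number of other cases in the cylinder, from the intensity:
    # lambda_i = sum over temporally close cases j of Pr(j lands within s_star
    # of case i), where j's location is cell-multinomial + uniform in cell.
    tp <- temporal_pairs(d, t_star)
    neighbors <- split(c(tp$j, tp$i), factor(c(tp$i, tp$j), levels = seq_len(n)))
    probs <- intensity_at(population, d)              # cells x n
    probs <- sweep(probs, 2, colSums(probs), "/")
    h <- population$cell_size_m
    m_sub <- 6L                                       # 6 x 6 sub-grid per cell
    off <- as.matrix(expand.grid(
      dx = ((seq_len(m_sub) - 0.5) / m_sub - 0.5) * h,
      dy = ((seq_len(m_sub) - 0.5) / m_sub - 0.5) * h))
    reach <- s_star + h * sqrt(2) / 2
    lam <- numeric(n)
    for (i in seq_len(n)) {
      js <- neighbors[[i]]
      if (!length(js)) next
      cand <- which(abs(population$cells$x - cases$x_birth[i]) <= reach &
                      abs(population$cells$y - cases$y_birth[i]) <= reach)
      if (!length(cand)) next
      # fraction of each candidate cell's area inside the disc
      dx <- outer(population$cells$x[cand] - cases$x_birth[i], off[, "dx"], "+")
      dy <- outer(population$cells$y[cand] - cases$y_birth[i], off[, "dy"], "+")
      frac <- rowMeans(dx^2 + dy^2 < s_star^2)
      lam[i] <- sum(frac * rowSums(probs[cand, js, drop = FALSE]))
    }
    p <- 1 - exp(-lam)
  }

  lo <- 1 / (2 * B); hi <- 1 - lo
  if (any(p < lo | p > hi)) {
    warning(sprintf("%d p_chance estimates clamped to [%.2g, %.2g] before logit",
                    sum(p < lo | p > hi), lo, hi))
  }
  p <- pmin(pmax(p, lo), hi)
  out <- data.frame(case_id = cases$case_id, p_chance = p,
                    index = stats::qlogis(p))
  structure(out, class = c("density_index", "data.frame"),
            method = method, B = B, s_star = s_star, t_star = t_star)
}

#' @export
print.density_index <- function(x, ...) {
  cat(sprintf("Child-population-density index (%s, B = %d, lags %.0f m / %.0f d)\n",
              attr(x, "method"), attr(x, "B"), attr(x, "s_star"), attr(x, "t_star")))
  cat(sprintf("  index: median %.2f, IQR [%.2f, %.2f]\n",
              stats::median(x$index),
              stats::quantile(x$index, 0.25), stats::quantile(x$index, 0.75)))
  invisible(x)
}
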