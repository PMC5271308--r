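#' Flag cases as clustered at the critical lags
#'
#' A case is clustered if it was born within the critical spatial and temporal
#' lags (strict inequalities) of at least one other case, and nonclustered
#' otherwise. The relation is symmetric by construction.
#'
#' @param cases a case table.
#' @param s_star critical spatial lag, meters.
#' @param t_star critical temporal lag, days.
#' @return Logical vector, one flag per case.
#' @export
classify_clustered <- function(cases, s_star, t_star) {
  assert_positive(s_star, "s_star"); assert_positive(t_star, "t_star")
  cp <- close_pair_count(cases, s_star, t_star)
  flags <- rep(FALSE, nrow(cases))
  flags[unique(as.vector(cp$pairs))] <- TRUE
  flags
}

# Connected component membership of the close-pair graph; n nodes, edges a
# 2-column index matrix. Components of size 1 are singletons.
component_membership <- function(n, edges) {
  if (nrow(edges) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Link clustered cases into local clusters
#'
#' Builds the graph whose vertices are cases and whose edges are close pairs
#' at the critical lags, and takes connected components as local clusters:
#' each member of a cluster is within the lags of at least one other member,
#' and chains merge transitively. Components of size 1 are the nonclustered
#' cases.
#'
#' @inheritParams classify_clustered
#' @return An object of class `cluster_labeling`: list with `clustered`
#'   (logical per case), `cluster_id` (integer per case, `NA` for
#'   nonclustered; ids numbered 1.. in order of first case), `size_spectrum`
#'   (named integer vector: number of clusters of exactly k cases, with k = 1
#'   counting nonclustered singletons), `s_star`, `t_star`.
#' @export
link_clusters <- function(cases, s_star, t_star) {
  assert_positive(s_star, "s_star"); assert_positive(t_star, "t_star")
  n <- nrow(cases)
  cp <- close_pair_count(cases, s_star, t_star)
  memb <- component_membership(n, cp$pairs)
  sizes <- tabulate(memb)
  clustered <- sizes[memb] >= 2L
  cluster_id <- rep(NA_integer_, n)
  if (any(clustered)) {
    comp_ids <- memb[clustered]
    cluster_id[clustered] <- match(comp_ids, unique(comp_ids))
  }
  spec <- table(factor(sizes, levels = seq_len(max(sizes))))
  size_spectrum <- as.integer(spec)
  names(size_spectrum) <- seq_along(size_spectrum)
  structure(
    list(clustered = clustered, cluster_id = cluster_id,
         size_spectrum = size_spectrum, s_star = s_star, t_star = t_star,
         n_cases = n),
    class = "cluster_labeling"
  )
}

#' @export
print.cluster_labeling <- function(x, ...) {
  n_cl <- sum(x$clustered)
  cat(sprintf("Cluster labeling at critical lags %.0f m, %.0f days\n",
              x$s_star, x$t_star))
  cat(sprintf("  %d of %d cases clustered (%.1f%%) in %d local clusters\n",
              n_cl, x$n_cases, 100 * n_cl / x$n_cases,
              sum(x$size_spectrum[-1])))
  occ <- x$size_spectrum[x$size_spectrum > 0]
  cat("  size spectrum (size: clusters): ",
      paste(sprintf("%s: %d", names(occ), occ), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Exact cluster-size counts for one configuration of coordinates.
spectrum_of <- function(x, y, dates_num, s_star, t_star, tp = NULL) {
  if (is.null(tp)) tp <- temporal_pairs(dates_num, t_star)
  keep <- (x[tp$i] - x[tp$j])^2 + (y[tp$i] - y[tp$j])^2 < s_star^2
  memb <- component_membership(length(x), cbind(tp$i[keep], tp$j[keep]))
  tabulate(tabulate(memb))
}

#' Monte Carlo test of the cluster-size spectrum
#'
#' Tabulates local clusters by size on the observed data and on `B` null
#' replicates (same population-shift-adjusted null as [knox_test()]), and for
#' every size k reports the Monte Carlo probability of observing at least as
#' many clusters of size k *or bigger* as in the data:
#' `p(k) = (1 + #\{cum_b >= cum_obs\}) / (B + 1)`. Per exact size it also
#' reports the replicate mean, minimum and maximum counts. Size 1 counts the
#' nonclustered singletons.
#'
#' @inheritParams classify_clustered
#' @param population a `population_model`.
#' @param B number of replicates (>= 99).
#' @param seed integer seed.
#' @return An object of class `size_spectrum_test`: data frame `spectrum` with
#'   columns `size`, `observed`, `mc_mean`, `mc_min`, `mc_max`,
#'   `observed_cum`, `p_mc`, plus `n_replicates`, `s_star`, `t_star`, `seed`.
#' @export
size_spectrum_test <- function(cases, population, s_star, t_star, B = 999, seed = 1) {
  assert_positive(s_star, "s_star"); assert_positive(t_star, "t_star")
  stopifnot(inherits(population, "population_model"))
  if (B < 99) stop("B must be >= 99 for usable p-value resolution", call. = FALSE)
  n <- nrow(cases)
  d <- days_num(cases$birth_date)
  tp <- temporal_pairs(d, t_star)
  obs_spec <- spectrum_of(cases$x_birth, cases$y_birth, d, s_star, t_star, tp)

  rep_specs <- with_seed(seed, {
    rc <- replicate_coords(cases, population, B)
    lapply(seq_len(B), function(b) {
      spectrum_of(rc$x[, b], rc$y[, b], d, s_star, t_star, tp)
    })
  })

  kmax <- max(length(obs_spec), vapply(rep_specs, length, 1L))
  pad <- function(v) c(v, rep(0L, kmax - length(v)))
  Mrep <- do.call(rbind, lapply(rep_specs, pad))   # B x kmax exact counts
  obs <- pad(obs_spec)
  # cumulative "size or bigger" counts
  revcum <- function(v) rev(cumsum(rev(v)))
  obs_cum <- revcum(obs)
  cum_rep <- if (kmax == 1L) Mrep else t(apply(Mrep, 1, revcum))
  p <- vapply(seq_len(kmax), function(k) {
    (1 + sum(cum_rep[, k] >= obs_cum[k])) / (B + 1)
  }, numeric(1))

  structure(
    list(spectrum = data.frame(
           size = seq_len(kmax), observed = obs,
           mc_mean = colMeans(Mrep), mc_min = apply(Mrep, 2, min),
           mc_max = apply(Mrep, 2, max),
           observed_cum = obs_cum, p_mc = p),
         n_replicates = B, s_star = s_star, t_star = t_star,
         n_cases = n, seed = seed),
    class = "size_spectrum_test"
  )
}

#' @export
print.size_spectrum_test <- function(x, ...) {
  cat(sprintf("Cluster-size spectrum vs %d Monte Carlo null replicates (lags %.0f m, %.0f d)\n",
              x$n_replicates, x$s_star, x$t_star))
  print(format(x$spectrum, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.size_spectrum_test <- function(x, ...) {
  sp <- x$spectrum
  graphics::plot(sp$size, sp$mc_mean, type = "n",
                 ylim = range(0, sp$mc_max, sp$observed), log = "",
                 xlab = "cluster size", ylab = "number of clusters",
                 main = "Observed vs Monte Carlo cluster-size spectrum", ...)
  graphics::segments(sp$size, sp$mc_min, sp$size, sp$mc_max, col = "grey60")
  graphics::points(sp$size, sp$mc_mean, pch = 3, col = "grey30")
  graphics::points(sp$size, sp$observed, pch = 18, col = "red", cex = 1.3)
  graphics::legend("topright", pch = c(18, 3), col = c("red", "grey30"),
                   legend = c("observed", "MC mean (min-max)"), bty = "n")
  invisible(x)
}
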