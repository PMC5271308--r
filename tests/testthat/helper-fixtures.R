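# Small synthetic study used throughout the tests: 30 x 30 km, 120k children
# in 5 drifting centers, 3 snapshots. Kept small so Monte Carlo loops stay fast.
small_config <- function(seed, n_cases = 200, cluster_rate = 0, ...) {
  sim_config(region_extent = c(0, 30000, 0, 30000), n_children = 120000,
             cell_size_m = 1500, n_population_centers = 5,
             snapshot_dates = as.Date(c("1985-01-01", "2000-01-01", "2015-01-01")),
             n_cases = n_cases, cluster_rate = cluster_rate, seed = seed, ...)
}

make_study <- function(seed, ...) {
  cfg <- small_config(seed, ...)
  pop <- generate_population(cfg)
  list(cfg = cfg, pop = pop, cases = generate_cases(cfg, pop))
}

# Plain random case table (no population structure) for oracle comparisons.
rand_cases <- function(n, seed, span_m = 5000, span_d = 2000) {
  set.seed(seed)
  data.frame(
    case_id = sprintf("R%04d", seq_len(n)),
    x_birth = runif(n, 0, span_m),
    y_birth = runif(n, 0, span_m),
    birth_date = as.Date("1990-01-01") + sample.int(span_d, n, replace = TRUE)
  )
}

# Independent O(n^2) double-loop oracle for close pairs (strict inequalities).
brute_pairs <- function(cases, s, t) {
  n <- nrow(cases)
  d <- as.numeric(cases$birth_date)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dist <- sqrt((cases$x_birth[i] - cases$x_birth[j])^2 +
                     (cases$y_birth[i] - cases$y_birth[j])^2)
      if (dist < s && abs(d[i] - d[j]) < t) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

# Independent iterative depth-first-search connected components.
dfs_components <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# canonical sorted representation of a pair set for comparisons
pair_key <- function(p) {
  if (nrow(p) == 0) return(character(0))
  sort(paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
}
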