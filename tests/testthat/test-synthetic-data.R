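test_that("generator is fully determined by the seed", {
  s1 <- make_study(7)
  s2 <- make_study(7)
  expect_identical(s1$pop$counts, s2$pop$counts)
  expect_identical(s1$cases, s2$cases)
  s3 <- make_study(8)
  expect_false(identical(s1$cases, s3$cases))
})

test_that("a static population gives snapshots identical up to sampling noise", {
  centers <- data.frame(x = 10000, y = 10000, sd_m = 4000,
                        weight_start = 1, weight_end = 1)
  n_ok <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(region_extent = c(0, 20000, 0, 20000), n_children = 20000,
                      cell_size_m = 2000, centers = centers,
                      snapshot_dates = as.Date(c("1990-01-01", "2010-01-01")),
                      n_cases = 10, seed = seed)
    pop <- generate_population(cfg)
    tot <- rowSums(pop$counts)
    keep <- tot >= 10            # chi-square validity
    p <- suppressWarnings(stats::chisq.test(t(pop$counts[keep, ]))$p.value)
    if (p > 0.01) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 95)
})

test_that("drifting center weights move the population centroid", {
  centers <- data.frame(x = c(5000, 25000), y = c(15000, 15000),
                        sd_m = c(2000, 2000),
                        weight_start = c(1, 0), weight_end = c(0, 1))
  cfg <- sim_config(region_extent = c(0, 30000, 0, 30000), n_children = 50000,
                    cell_size_m = 1500, centers = centers,
                    snapshot_dates = as.Date(c("1990-01-01", "2010-01-01")),
                    n_cases = 10, seed = 3)
  pop <- generate_population(cfg)
  cx <- apply(pop$counts, 2, function(w) weighted.mean(pop$cells$x, w))
  expect_lt(abs(cx[1] - 5000), 1000)
  expect_lt(abs(cx[2] - 25000), 1000)
})

test_that("snapshot totals match the configured child count", {
  s <- make_study(5)
  expect_true(all(abs(colSums(s$pop$counts) - s$cfg$n_children)
                  <= 0.1 * s$cfg$n_children))
})

test_that("null configuration produces no truth ids and background marker prevalence", {
  s <- make_study(11, n_cases = 800, marker_untested_rate = 0)
  expect_true(all(is.na(s$cases$truth_cluster_id)))
  prev <- mean(s$cases$marker_positive == "yes")
  p0 <- s$cfg$marker_prevalence_background
  expect_lt(abs(prev - p0), 4 * sqrt(p0 * (1 - p0) / nrow(s$cases)))
})

test_that("fully enriched marker appears only inside induced clusters", {
  s <- make_study(13, n_cases = 300, cluster_rate = 15,
                  marker_prevalence_in_cluster = 1,
                  marker_prevalence_background = 0,
                  marker_untested_rate = 0)
  expect_gt(sum(s$cases$marker_positive == "yes"), 0)
  expect_true(all(!is.na(s$cases$truth_cluster_id[s$cases$marker_positive == "yes"])))
})

test_that("registry-scale tested counts match the configured untested rate", {
  cfg <- sim_config(seed = 21, n_cases = 1282, marker_untested_rate = 1 - 569 / 1282,
                    cell_size_m = 2000)
  pop <- generate_population(cfg)
  cases <- generate_cases(cfg, pop)
  tested <- sum(cases$marker_positive != "untested")
  # binomial check around the 569 target at n = 1282 (+ a few sibling rows)
  expect_lt(abs(tested - (1 - cfg$marker_untested_rate) * nrow(cases)),
            4 * sqrt(nrow(cases) * 0.25))
  expect_lt(abs(tested - 569), 80)
})

test_that("case records satisfy the table invariants", {
  s <- make_study(17, n_cases = 400, cluster_rate = 10, sibling_pair_rate = 0.02)
  cs <- s$cases
  ext <- s$cfg$region_extent
  expect_true(all(cs$x_birth >= ext[1] & cs$x_birth <= ext[2]))
  expect_true(all(cs$y_birth >= ext[3] & cs$y_birth <= ext[4]))
  expect_true(all(cs$diagnosis_date >= cs$birth_date))
  expect_true(all(as.numeric(cs$diagnosis_date - cs$birth_date) / 365.25 < 16))
  expect_true(all(cs$birth_date >= s$cfg$study_window[1] &
                    cs$birth_date <= s$cfg$study_window[2]))
})

test_that("induced clusters are geometrically tight and sibling pairs are close", {
  s <- make_study(19, n_cases = 300, cluster_rate = 12, sibling_pair_rate = 0.03)
  cs <- s$cases
  for (k in unique(stats::na.omit(cs$truth_cluster_id))) {
    idx <- which(cs$truth_cluster_id == k)
    if (length(idx) < 2) next
    seed_i <- idx[1]
    d <- sqrt((cs$x_birth[idx] - cs$x_birth[seed_i])^2 +
                (cs$y_birth[idx] - cs$y_birth[seed_i])^2)
    expect_true(all(d <= s$cfg$cluster_radius_m + 1e-9))
    dt <- abs(as.numeric(cs$birth_date[idx] - cs$birth_date[seed_i]))
    expect_true(all(dt <= s$cfg$cluster_duration_days))
  }
  sibs <- cs$sibling_group[!is.na(cs$sibling_group)]
  expect_gt(length(sibs), 0)
  for (g in unique(sibs)) {
    idx <- which(cs$sibling_group == g)
    expect_length(idx, 2)
    d <- sqrt(diff(cs$x_birth[idx])^2 + diff(cs$y_birth[idx])^2)
    expect_lt(d, 50)
    expect_lte(abs(as.numeric(diff(cs$birth_date[idx]))), 3 * 365.25)
  }
})

test_that("marker enrichment raises the downstream clustered-vs-nonclustered OR", {
  log_or <- function(prev_in, seeds) {
    vapply(seeds, function(sd) {
      s <- make_study(sd, n_cases = 300, cluster_rate = 20,
                      marker_prevalence_in_cluster = prev_in,
                      marker_untested_rate = 0)
      fl <- classify_clustered(s$cases, 1000, 730)
      m <- s$cases$marker_positive == "yes"
      tab <- or_2x2(sum(fl & m) + 0.5, sum(fl & !m) + 0.5,
                    sum(!fl & m) + 0.5, sum(!fl & !m) + 0.5)
      tab$log_or
    }, numeric(1))
  }
  seeds <- 101:130
  expect_gt(mean(log_or(0.75, seeds)), mean(log_or(0.25, seeds)) + 0.2)
})

test_that("generator rejects invalid configurations", {
  expect_error(sim_config(seed = 1, n_population_centers = 0), "center")
  expect_error(sim_config(seed = 1, cluster_rate = 2, cluster_radius_m = 0), "radius")
  expect_error(sim_config(seed = 1, marker_untested_rate = 1.2), "probabilities")
  expect_error(sim_config(n_cases = 10), "seed")
  expect_error(sim_config(seed = 1, snapshot_dates = as.Date("1990-01-01")),
               "snapshot")
})
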