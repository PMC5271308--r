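test_that("close_pair_count handles the textbook configurations", {
  one <- rand_cases(1, 1)
  expect_equal(close_pair_count(one, 1000, 730)$count, 0L)

  collinear <- data.frame(case_id = c("a", "b", "c"),
                          x_birth = c(0, 600, 1200), y_birth = 0,
                          birth_date = as.Date("1990-06-15"))
  cp <- close_pair_count(collinear, 1000, 730)
  expect_equal(cp$count, 2L)
  expect_setequal(pair_key(cp$pairs), c("1 2", "2 3"))
})

test_that("lags are strict: a pair exactly at the threshold is not close", {
  cases <- data.frame(case_id = c("a", "b"),
                      x_birth = c(0, 1000), y_birth = 0,
                      birth_date = as.Date(c("1990-01-01", "1990-01-01")))
  expect_equal(close_pair_count(cases, 1000, 730)$count, 0L)
  expect_equal(close_pair_count(cases, 1000.001, 730)$count, 1L)
  cases2 <- data.frame(case_id = c("a", "b"), x_birth = 0, y_birth = 0,
                       birth_date = as.Date(c("1990-01-01", "1992-01-01")))
  expect_equal(close_pair_count(cases2, 100, 730)$count, 0L)   # exactly 730 d
  expect_equal(close_pair_count(cases2, 100, 731)$count, 1L)
})

test_that("close_pair_count matches the brute-force oracle", {
  for (seed in 1:20) {
    n <- sample(5:120, 1)
    cases <- rand_cases(n, seed)
    s <- runif(1, 200, 3000); t <- runif(1, 50, 1500)
    cp <- close_pair_count(cases, s, t)
    bp <- brute_pairs(cases, s, t)
    expect_equal(cp$count, nrow(bp))
    expect_identical(pair_key(cp$pairs), pair_key(bp))
  }
})

test_that("close_pair_count validates its arguments", {
  cases <- rand_cases(5, 1)
  expect_error(close_pair_count(cases, -1, 730), "positive")
  expect_error(close_pair_count(cases, 1000, 0), "positive")
})

test_that("mc_null_replicate keeps dates and covariates, resamples locations", {
  s <- make_study(23, n_cases = 150)
  rep1 <- mc_null_replicate(s$cases, s$pop, seed = 5)
  expect_identical(rep1$birth_date, s$cases$birth_date)
  expect_identical(rep1$marker_positive, s$cases$marker_positive)
  expect_false(identical(rep1$x_birth, s$cases$x_birth))
  expect_identical(rep1, mc_null_replicate(s$cases, s$pop, seed = 5))
})

test_that("a degenerate population concentrates all replicate locations", {
  s <- make_study(29, n_cases = 50)
  pop <- s$pop
  pop$counts[] <- 0L
  target <- 137L
  pop$counts[target, ] <- 1000L
  rep1 <- mc_null_replicate(s$cases, pop, seed = 2)
  h <- pop$cell_size_m
  expect_true(all(abs(rep1$x_birth - pop$cells$x[target]) <= h / 2))
  expect_true(all(abs(rep1$y_birth - pop$cells$y[target]) <= h / 2))
})

test_that("uniform static population yields uniform replicate coordinates", {
  s <- make_study(31, n_cases = 200)
  pop <- s$pop
  pop$counts[] <- 10L
  reps <- lapply(1:5, function(k) mc_null_replicate(s$cases, pop, seed = k))
  xs <- unlist(lapply(reps, `[[`, "x_birth"))
  ks <- stats::ks.test(xs, "punif", pop$region[1], pop$region[2])
  expect_gt(ks$p.value, 0.001)
})

test_that("zero population intensity at a birth date is a data error", {
  s <- make_study(37, n_cases = 30)
  pop <- s$pop
  pop$counts[, 1] <- 0L   # zero intensity at the first snapshot
  early <- s$cases
  early$birth_date <- as.Date("1985-01-01")
  expect_error(mc_null_replicate(early, pop), "intensity")
})

test_that("knox_test output satisfies the structural invariants", {
  s <- make_study(41, n_cases = 250)
  grid <- lag_grid(c(500, 1000, 2000, 5000), c(182, 365, 730))
  kt <- knox_test(s$cases, s$pop, grid, B = 99, seed = 9)
  B <- kt$n_replicates
  expect_true(all(kt$cells$p_mc >= 1 / (B + 1) & kt$cells$p_mc <= 1))
  expect_true(all(abs(kt$cells$p_mc * (B + 1) - round(kt$cells$p_mc * (B + 1))) < 1e-9))
  expect_gte(kt$adjusted_p_max, kt$min_p)
  # observed and expected counts nondecreasing in both lags
  O <- matrix(kt$cells$observed, 4, 3)
  E <- matrix(kt$cells$expected, 4, 3)
  expect_true(all(diff(O) >= 0) && all(diff(t(O)) >= 0))
  expect_true(all(diff(E) >= 0) && all(diff(t(E)) >= 0))
  # ratio is plain observed/expected arithmetic
  expect_equal(kt$cells$ratio, kt$cells$observed / kt$cells$expected)
  # critical lags are a grid point with the minimal p
  crit <- kt$cells[kt$cells$spatial_lag_m == kt$critical_lags["s"] &
                     kt$cells$temporal_lag_days == kt$critical_lags["t"], ]
  expect_equal(crit$p_mc, min(kt$cells$p_mc))
  # observed close-pair column agrees with the single-cell counter
  expect_equal(crit$observed, close_pair_count(s$cases, crit$spatial_lag_m,
                                               crit$temporal_lag_days)$count)
})

test_that("knox_test is deterministic and rejects too few replicates", {
  s <- make_study(43, n_cases = 120)
  k1 <- knox_test(s$cases, s$pop, B = 99, seed = 4)
  k2 <- knox_test(s$cases, s$pop, B = 99, seed = 4)
  expect_identical(k1$cells, k2$cells)
  expect_identical(k1$adjusted_p_max, k2$adjusted_p_max)
  expect_error(knox_test(s$cases, s$pop, B = 50, seed = 1), "99")
})

test_that("critical-lag ties break toward larger ratio then smaller lags", {
  s <- make_study(47, n_cases = 150)
  kt <- knox_test(s$cases, s$pop, B = 99, seed = 8)
  tied <- kt$cells[kt$cells$p_mc == kt$min_p, ]
  best_ratio <- max(tied$ratio)
  cand <- tied[tied$ratio == best_ratio, ]
  cand <- cand[order(cand$spatial_lag_m, cand$temporal_lag_days), ][1, ]
  expect_equal(unname(kt$critical_lags["s"]), cand$spatial_lag_m)
  expect_equal(unname(kt$critical_lags["t"]), cand$temporal_lag_days)
})
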