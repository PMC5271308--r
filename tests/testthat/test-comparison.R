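test_that("or_2x2 reproduces published registry summary statistics", {
  # cytogenetic marker: 37/93 clustered vs 118/476 nonclustered carriers
  o <- or_2x2(37, 93 - 37, 118, 476 - 118)
  expect_equal(round(o$or, 2), 2.00)
  expect_equal(round(o$ci, 2), c(1.26, 3.19))
  expect_equal(round(100 * 37 / 93, 1), 39.8)
  expect_equal(round(100 * (37 + 118) / (93 + 476), 1), 27.2)
  # high hyperdiploidy 34/109 vs 183/538; trisomies 15/79 vs 103/407
  expect_equal(round(or_2x2(34, 109 - 34, 183, 538 - 183)$or, 2), 0.88)
  expect_equal(round(or_2x2(15, 79 - 15, 103, 407 - 103)$or, 2), 0.69)
})

test_that("or_2x2 is symmetric at equal counts and handles zero cells", {
  o <- or_2x2(20, 20, 20, 20)
  expect_equal(o$or, 1)
  expect_equal(o$ci[1] * o$ci[2], 1, tolerance = 1e-12)
  expect_warning(oz <- or_2x2(0, 10, 5, 20), "continuity")
  expect_true(oz$continuity && is.finite(oz$or))
  expect_error(or_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("or_2x2 equals the logistic regression coefficient", {
  set.seed(42)
  for (k in 1:10) {
    tab <- matrix(sample(5:80, 4), 2)
    o <- or_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    y <- rep(c(1, 1, 0, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    x <- rep(c(1, 0, 1, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    fit <- stats::glm(y ~ x, family = stats::binomial())
    expect_equal(o$or, unname(exp(stats::coef(fit)["x"])), tolerance = 1e-6)
  }
})

test_that("a binary characteristic fit matches the 2x2 table", {
  st <- make_study(91, n_cases = 400, cluster_rate = 15, marker_untested_rate = 0.3)
  fl <- classify_clustered(st$cases, 1000, 730)
  fit <- fit_clustering_model(st$cases, fl, "marker_positive", ref_level = "no")
  m <- st$cases$marker_positive
  tested <- m != "untested"
  o <- or_2x2(sum(fl & tested & m == "yes"), sum(fl & tested & m == "no"),
              sum(!fl & tested & m == "yes"), sum(!fl & tested & m == "no"))
  row <- fit$levels[fit$levels$level == "yes", ]
  expect_equal(row$or, o$or, tolerance = 1e-6)
  expect_equal(c(row$ci_low, row$ci_high), o$ci, tolerance = 1e-6)
  # untested cases are excluded listwise
  expect_equal(row$N_clustered + row$N_nonclustered, sum(tested))
})

test_that("a constant density index reduces the adjusted model to the unadjusted one", {
  st <- make_study(93, n_cases = 300, cluster_rate = 10, marker_untested_rate = 0)
  fl <- classify_clustered(st$cases, 1000, 730)
  const <- structure(data.frame(case_id = st$cases$case_id,
                                p_chance = 0.2, index = stats::qlogis(0.2)),
                     class = c("density_index", "data.frame"))
  un <- fit_clustering_model(st$cases, fl, "marker_positive", ref_level = "no")
  ad <- fit_clustering_model(st$cases, fl, "marker_positive",
                             density = const, ref_level = "no")
  expect_equal(ad$levels$or, un$levels$or, tolerance = 1e-8)
})

test_that("a real density index changes the marker estimate but keeps it positive", {
  st <- make_study(95, n_cases = 500, cluster_rate = 30, marker_untested_rate = 0)
  fl <- classify_clustered(st$cases, 1000, 730)
  di <- suppressWarnings(density_index(st$cases, st$pop, 1000, 730, B = 199,
                                       seed = 4))
  ad <- fit_clustering_model(st$cases, fl, "marker_positive",
                             density = di, ref_level = "no")
  expect_gt(ad$levels$or[ad$levels$level == "yes"], 1)
  expect_lt(ad$p_lrt, 0.05)
})

test_that("holm_adjust follows the step-down formula", {
  single <- holm_adjust(0.031)
  expect_equal(single$p_adjusted, 0.031)
  hand <- holm_adjust(c(a = 0.001, b = 0.02, c = 0.04))
  expect_equal(hand$p_adjusted, c(0.003, 0.04, 0.04))
  ones <- holm_adjust(rep(1, 4))
  expect_true(all(ones$p_adjusted == 1))
  set.seed(7)
  p <- runif(12)
  h <- holm_adjust(p)
  expect_true(all(h$p_adjusted >= h$p_raw))
  expect_true(all(diff(h$p_adjusted[order(h$p_raw)]) >= -1e-12))
  expect_true(all(h$p_adjusted <= 1))
  # rejections are a subset of the unadjusted ones
  expect_true(all(!h$reject | h$p_raw <= attr(h, "alpha")))
  expect_error(holm_adjust(numeric(0)), "empty")
  expect_error(holm_adjust(c(0.5, 0)), "0, 1")
})

test_that("mc_covariate_pvalue is deterministic and uses the add-one formula", {
  st <- make_study(97, n_cases = 120)
  # plant a strong artificial signal: all cases in one tight clump are both
  # clustered and share the location-derived covariate, so the observed LRT
  # statistic dwarfs every null replicate
  cases <- st$cases
  clump <- 1:30
  cases$x_birth[clump] <- 15000 + runif(30, 0, 200)
  cases$y_birth[clump] <- 15000 + runif(30, 0, 200)
  cases$birth_date[clump] <- as.Date("1995-01-01") + sample.int(300, 30, TRUE)
  inside <- function(x, y) ifelse((x - 15000)^2 + (y - 15000)^2 < 500^2,
                                  "near", "far")
  mc <- mc_covariate_pvalue(cases, st$pop, 1000, 730, inside, B = 99, seed = 3)
  expect_equal(mc$p, 1 / 100)
  mc2 <- mc_covariate_pvalue(cases, st$pop, 1000, 730, inside, B = 99, seed = 3)
  expect_identical(mc$p, mc2$p)
  expect_error(mc_covariate_pvalue(cases, st$pop, 1000, 730, "urban", B = 99),
               "function")
})

test_that("mc covariate p-values are calibrated under the null", {
  rejections <- 0L
  bands <- function(x, y) paste0("b", floor(x / 4000) %% 2)
  for (seed in 201:230) {
    st <- make_study(seed, n_cases = 120)
    mc <- mc_covariate_pvalue(st$cases, st$pop, 1000, 730, bands,
                              B = 99, seed = seed)
    if (mc$p <= 0.05) rejections <- rejections + 1L
  }
  # binomial(30, 0.05): >= 7 rejections has probability < 0.001
  expect_lte(rejections, 6)
})

test_that("compare_characteristics assembles rows and Holm-corrects", {
  st <- make_study(99, n_cases = 400, cluster_rate = 20, marker_untested_rate = 0.3)
  fl <- classify_clustered(st$cases, 1000, 730)
  di <- suppressWarnings(density_index(st$cases, st$pop, 1000, 730, B = 199, seed = 5))
  cmp <- compare_characteristics(st$cases, fl,
                                 c("marker_positive", "sex", "urban"),
                                 density = di,
                                 ref_levels = list(marker_positive = "no"))
  expect_setequal(unique(cmp$rows$characteristic),
                  c("marker_positive", "sex", "urban"))
  expect_equal(cmp$tests$p_holm,
               holm_adjust(cmp$tests$p)$p_adjusted)
  expect_true(all(cmp$tests$p_holm >= cmp$tests$p))
  expect_true(all(cmp$rows$n_clustered <= cmp$rows$N_clustered))
})
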