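test_that("percent variation closed forms and invariances", {
  expect_equal(percent_variation(c(2, 2, 2)), 0)
  expect_equal(percent_variation(c(0.5, 0.7, 1.0)), 50)
  set.seed(1)
  v <- runif(50, 0.5, 2)
  expect_equal(percent_variation(v), percent_variation(17.3 * v))
  expect_gte(percent_variation(v), 0); expect_lt(percent_variation(v), 100)
  expect_error(percent_variation(1), "at least 2")
})

test_that("Pearson matches the hand-computed 4-point case and the textbook formula", {
  r <- pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$value, 0.6, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(pearson(1:5, 1:5)$value, 1)
  expect_equal(pearson(1:5, -(1:5))$value, -1)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
    rr <- pearson(x, y)$value
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(rr, oracle, tolerance = 1e-12)
  }
  expect_error(pearson(c(1, 1, 1), 1:3), "constant")
})

test_that("allometric slope recovers exact power laws and flags isometry", {
  tot <- c(0.4, 0.5, 0.6, 0.7, 0.8)
  iso <- suppressWarnings(allometric_slope(tot, 0.3 * tot))
  expect_equal(iso$slope, 1, tolerance = 1e-12)
  expect_true(iso$isometric)
  sq <- suppressWarnings(allometric_slope(tot, tot^2))
  expect_equal(sq$slope, 2, tolerance = 1e-12)
  expect_error(allometric_slope(c(-1, 1, 2), c(1, 1, 1)), "positive")
})

test_that("isometric generator draws contain slope 1 in the 95% CI in most seeds", {
  # isometric conditions: variation dominated by the shared size factor
  cv <- c(AL = 0.085, MB = 0.085, CX = 0.085, ME = 0.085, LO = 0.085,
          OTH = 0.085)
  pp <- phantom_params(neuropil_cv = cv, size_cv = 0.08, hive_sigma = 0,
                       seed = 1)
  hits <- sapply(1:10, function(s) {
    tab <- cohort_to_table(sample_cohort(pp, hive_plan = c(H1 = 500), seed = s))
    allometric_slope(tab$total, tab$MB)$isometric
  })
  expect_gte(mean(hits), 0.9)
})

test_that("colony F-test reproduces the containment degrees of freedom of the study design", {
  pp <- phantom_params(seed = 3)
  tab <- cohort_to_table(sample_cohort(pp, hive_plan = honeybee_hive_plan()))
  expect_equal(nrow(tab), 110)
  res <- colony_effect_test(tab, "total")
  expect_equal(res$df, c(8, 101))
  expect_equal(res$n, 110)
  # single population reduces to one-way ANOVA with the same df convention
  tb <- cohort_to_table(sample_cohort(pp, hive_plan = bumblebee_hive_plan()))
  resb <- colony_effect_test(tb, "total")
  expect_equal(resb$df, c(3, 73))
  expect_error(colony_effect_test(tab[tab$hive == "H1", ], "total"), "2 hives")
})

test_that("colony F-test behaves under null and strong-effect cohorts", {
  null_p <- sapply(1:8, function(s) {
    pp <- phantom_params(hive_sigma = 0, seed = s)
    tab <- cohort_to_table(sample_cohort(pp, hive_plan = honeybee_hive_plan(),
                                         seed = 100 + s))
    colony_effect_test(tab, "total")$p
  })
  expect_gt(mean(null_p), 0.2)     # F ~ 1 in expectation under the null
  pp <- phantom_params(hive_sigma = 0.3, seed = 4)
  tab <- cohort_to_table(sample_cohort(pp, hive_plan = honeybee_hive_plan()))
  expect_lt(colony_effect_test(tab, "total")$p, 0.001)
})

test_that("lateralization test covers ties, pure deficits and exclusions", {
  t0 <- data.frame(OL_left = rep(1, 10), OL_right = rep(1, 10))
  r0 <- lateralization_test(t0, "OL")
  expect_equal(r0$value, 0); expect_equal(r0$p, 1)
  expect_equal(r0$pct_smaller_left, 0); expect_equal(r0$n_ties, 10)
  t1 <- data.frame(OL_left = 0.95 * (1:10), OL_right = as.numeric(1:10))
  r1 <- lateralization_test(t1, "OL")
  expect_lt(r1$p, 0.001)
  expect_equal(r1$pct_smaller_left, 100)
  t2 <- t1; t2$OL_left[1:3] <- NA
  r2 <- lateralization_test(t2, "OL")
  expect_equal(r2$n_used, 7); expect_equal(r2$n_excluded, 3)
  expect_error(lateralization_test(data.frame(OL_left = 1:2, OL_right = 2:3)),
               "3 usable")
})

test_that("asymmetry quadrants classify strictly, report ties and sum to 100%", {
  t_sym <- data.frame(AL_left = rep(1, 5), AL_right = rep(1, 5),
                      OL_left = rep(2, 5), OL_right = rep(2, 5))
  expect_warning(q0 <- asymmetry_quadrants(t_sym), "no classifiable")
  expect_equal(q0$n_ties, 5); expect_equal(q0$n_classified, 0)
  t_rr <- data.frame(AL_left = rep(1, 4), AL_right = rep(1.1, 4),
                     OL_left = rep(2, 4), OL_right = rep(2.2, 4))
  q1 <- asymmetry_quadrants(t_rr)
  expect_equal(unname(q1$percent[1]), 100)
  set.seed(8)
  n <- 4000
  tr <- data.frame(AL_left = rnorm(n, 1, 0.1), AL_right = rnorm(n, 1, 0.1),
                   OL_left = rnorm(n, 2, 0.1), OL_right = rnorm(n, 2, 0.1))
  q2 <- asymmetry_quadrants(tr)
  expect_equal(sum(q2$percent), 100)
  expect_true(all(abs(q2$percent - 25) < 4))   # ~4 binomial se
})

test_that("operating-characteristic simulation validates its inputs", {
  pp <- phantom_params(seed = 1)
  expect_error(simulate_operating_characteristics(pp, n_reps = 1), ">= 50")
  expect_error(simulate_operating_characteristics(pp, n_reps = 50, alpha = 1.5),
               "alpha")
})
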