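# Nonparametric statistics layer and the cohort-level analysis.

test_that("Anderson-Darling screen distinguishes normal from skewed data", {
  set.seed(101)
  keep <- replicate(100, !anderson_darling_normality(rnorm(500))$reject)
  expect_gte(mean(keep), 0.9)
  set.seed(102)
  rej <- replicate(100, anderson_darling_normality(rexp(500))$reject)
  expect_gte(mean(rej), 0.95)

  expect_error(anderson_darling_normality(c(1, 2, 3)), "n >= 5")
  expect_error(anderson_darling_normality(rep(1, 10)), "degenerate")
})

test_that("Kruskal-Wallis handles identical groups, ties, and rank formula", {
  kt <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kt$H, 0)
  expect_equal(kt$p_value, 1)
  expect_false(kt$significant)

  # fully separated groups of 3: H equals the two-group maximum
  # 12/(n(n+1)) * (R1^2/3 + R2^2/3) - 3(n+1) with ranks {1,2,3},{4,5,6}
  kt2 <- kruskal_wallis(list(c(1, 2, 3), c(101, 102, 103)), exact = "never")
  Hmax <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(kt2$H, Hmax, tolerance = 1e-12)

  # rank-based: invariant under strictly monotone transforms
  g <- list(c(0.3, 2.5, 1.1, 4), c(0.9, 3.3, 5.5, 1.8))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(x) exp(x)))$H,
               tolerance = 1e-12)
})

test_that("exact permutation p agrees with brute-force enumeration", {
  perms <- fetalmorph:::.group_assignments(c(4, 4))
  expect_equal(length(perms), choose(8, 4))

  g1 <- c(1.2, 3.4, 2.2, 5.1); g2 <- c(2.0, 6.3, 4.4, 7.7)
  kt <- kruskal_wallis(list(g1, g2), exact = "always")
  # independent oracle: enumerate assignments directly
  pool <- c(g1, g2)
  Hobs <- fetalmorph:::.kw_h(pool, rep(1:2, each = 4))
  Hs <- vapply(perms, function(a) fetalmorph:::.kw_h(pool, a), numeric(1))
  expect_equal(kt$p_exact, mean(Hs >= Hobs - 1e-12))
  expect_true(kt$p_exact >= 0 && kt$p_exact <= 1)

  # far tail: chi-squared approximation close to exact
  sep <- kruskal_wallis(list(1:4, 101:104), exact = "always")
  expect_equal(sep$p_exact, 2 / 70, tolerance = 1e-12)
  expect_lt(abs(sep$p_value - sep$p_exact), 0.02)
})

test_that("median/IQR use type-7 quantiles", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)), c(median = 3, q25 = 2, q75 = 4))
  expect_equal(median_iqr(5), c(median = 5, q25 = 5, q75 = 5))
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, q25 = 1.75, q75 = 3.25))
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("correlation strengths follow the bins with upward boundaries", {
  pw <- pearson_with_strength(1:10, 2 * (1:10) + 1)
  expect_equal(pw$r, 1)
  expect_equal(pw$strength, "strong")
  expect_equal(correlation_strength(0.56), "moderate")
  expect_equal(correlation_strength(0.64), "moderate")
  expect_equal(correlation_strength(0.3), "weak")
  expect_equal(correlation_strength(0.5), "moderate")
  expect_equal(correlation_strength(0.7), "strong")
  expect_equal(correlation_strength(0.29), "none_or_very_weak")

  # sign flip: r negates, strength label unchanged
  x <- c(1, 3, 2, 5, 4, 6); y <- c(2, 4, 2.5, 5.5, 5, 7)
  a <- pearson_with_strength(x, y); b <- pearson_with_strength(x, -y)
  expect_equal(b$r, -a$r)
  expect_equal(b$strength, a$strength)
  expect_error(pearson_with_strength(1:5, rep(2, 5)), "constant")
})

test_that("cohort rates pair MMC scans and GA-ranked controls", {
  co <- generate_cohort(6, 6, 6, seed = 13)
  rates <- cohort_paired_rates(co$table)
  expect_setequal(unique(rates$group), c("mmc", "control"))
  expect_equal(sum(rates$group == "mmc" & rates$metric == "mean_si"), 6L)
  expect_equal(sum(rates$group == "control" & rates$metric == "mean_si"), 6L)
  expect_true(all(rates$ga_post > rates$ga_pre))
  expect_equal(rates$rate,
               (rates$post - rates$pre) / (rates$ga_post - rates$ga_pre))

  # a subject missing its post scan is excluded with a warning
  broken <- co$table[!(co$table$subject_id == "mmc01" &
                       co$table$timepoint == "post"), ]
  expect_warning(r2 <- cohort_paired_rates(broken), "mmc01")
  expect_false("mmc01" %in% r2$pair_id)
})

test_that("the group analysis flags the built-in effects and correlations", {
  co <- generate_cohort(12, 12, 12, seed = 3)
  ga <- run_group_analysis(co$table)
  expect_equal(nrow(ga$tests), 6L * 3L)  # metrics x contrasts
  expect_true(all(ga$tests$p_value >= 0 & ga$tests$p_value <= 1))
  expect_identical(ga$tests$significant, ga$tests$p_value < 0.05)

  vent <- ga$tests[ga$tests$metric == "ventricles_volume_mm3" &
                   ga$tests$contrast == "rate_mmc_vs_control", ]
  expect_true(vent$significant)
  expect_gt(vent$median_1, vent$median_2)  # affected ventricular rate higher
  expect_true(vent$q25_1 <= vent$median_1 && vent$median_1 <= vent$q75_1)

  cors <- ga$correlations
  vv <- cors[cors$biometric == "vw_mm" &
             cors$metric == "ventricles_volume_mm3", ]
  expect_true(vv$strength %in% c("moderate", "strong"))
  expect_equal(vv$sign, "positive")

  out <- withr::local_tempdir()
  write_group_analysis(ga, out)
  expect_true(all(file.exists(file.path(out, c("tests.csv", "rates.csv",
                                               "correlations.csv",
                                               "run_log.json")))))
})

test_that("zero-effect cohorts keep the false-positive rate near alpha", {
  rej <- vapply(1:60, function(i) {
    co <- generate_cohort(12, 12, 12,
                          effect_config = cohort_effects(zero_effect = TRUE),
                          seed = 5000 + i)
    r <- cohort_paired_rates(co$table)
    r <- r[r$metric == "ventricles_volume_mm3", ]
    kruskal_wallis(list(r$rate[r$group == "mmc"],
                        r$rate[r$group == "control"]))$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.15)
})
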