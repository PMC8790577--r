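test_that("KS statistic matches the exhaustive ECDF-scan oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$statistic, 1)

  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20, 0.4)
    got <- ks_two_sample(x, y)
    expect_equal(got$statistic, ks_oracle_D(x, y), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(c(1, 2), rnorm(10)), "n_x = 2")
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(15)
  x <- rnorm(25); y <- rnorm(30, 0.5)
  d0 <- ks_two_sample(x, y)$statistic
  expect_equal(ks_two_sample(exp(x), exp(y))$statistic, d0)
  expect_equal(ks_two_sample(x^3, y^3)$statistic, d0)
})

test_that("one-way ANOVA F matches the textbook between/within ratio", {
  # identical group means -> F = 0, p = 1
  g0 <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  got0 <- anova_one_way(g0)
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p_value, 1)

  # hand-computable example
  g1 <- list(c(0, 1), c(0, 1), c(10, 11))
  got1 <- anova_one_way(g1)
  expect_equal(got1$statistic, anova_oracle_F(g1), tolerance = 1e-12)
  expect_identical(got1$df1, 2)
  expect_identical(got1$df2, 3)

  # random draws also agree with the oracle
  set.seed(33)
  for (i in 1:5) {
    g <- list(rnorm(8), rnorm(9, 0.5), rnorm(7, 1))
    expect_equal(anova_one_way(g)$statistic, anova_oracle_F(g),
                 tolerance = 1e-10)
  }

  expect_error(anova_one_way(list(1, c(1, 2), c(3, 4))), ">= 2 values")
  expect_error(anova_one_way(list(c(1, 1), c(2, 2), c(3, 3))),
               "zero within-group variance")
})

test_that("ANOVA F is invariant to shifting and scaling all values", {
  set.seed(5)
  g <- list(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  f0 <- anova_one_way(g)$statistic
  expect_equal(anova_one_way(lapply(g, `+`, 7))$statistic, f0,
               tolerance = 1e-10)
  expect_equal(anova_one_way(lapply(g, `*`, -3.5))$statistic, f0,
               tolerance = 1e-10)
})

test_that("EMT correlation is rank-based and matches rank-then-Pearson", {
  set.seed(22)
  s <- rnorm(15); names(s) <- paste0("s", 1:15)
  expect_equal(correlate_with_emt(s, s)$rho, 1)
  expect_equal(correlate_with_emt(s, -s)$rho, -1)

  m <- rnorm(15); names(m) <- names(s)
  got <- correlate_with_emt(s, m)
  expect_equal(got$rho, cor(rank(s), rank(m)), tolerance = 1e-12)

  expect_error(correlate_with_emt(s, setNames(rep(1, 15), names(s))),
               "degenerate marker")
  expect_error(correlate_with_emt(s[1:3], m[1:3]), ">= 4")
})

test_that("p-value banding follows the published thresholds", {
  expect_identical(p_to_band(c(0.0005, 0.005, 0.03, 0.5)),
                   c("***", "**", "*", "NS"))
  # boundary conventions: bands are half-open at the thresholds
  expect_identical(p_to_band(c(0.001, 0.01, 0.05)), c("**", "*", "NS"))
  expect_identical(p_to_band(NA), NA_character_)
  expect_error(p_to_band(1.2), "outside")
})

test_that("landscape contrasts recover a planted positive marker", {
  cfg <- slim_sim_config(seed = 55, n_samples = 400)
  co <- generate_cohort(cfg)
  sc <- compute_emt_score(co$expression)
  gr <- stratify_by_emt(sc)
  specs <- data.frame(name = c("PLANTED", "NULLM"), category = "checkpoint",
                      stringsAsFactors = FALSE)
  tt <- structure(list(values = co$expression$values[c("PLANTED", "NULLM"), ],
                       category = c("checkpoint", "checkpoint")),
                  class = "time_marker_table")
  ls <- build_landscape(tt, gr, sc)
  planted <- ls[ls$marker == "PLANTED", ]
  expect_gt(planted$delta_median, 0)
  expect_lt(planted$ks_p, 0.001)
  expect_identical(planted$ks_band, "***")
  expect_identical(c(planted$n_high, planted$n_low), c(100L, 100L))

  # constant marker: delta 0, correlation recorded as missing, not dropped
  tt$values["NULLM", ] <- 1
  ls2 <- build_landscape(tt, gr, sc)
  row2 <- ls2[ls2$marker == "NULLM", ]
  expect_equal(row2$delta_median, 0)
  expect_true(is.na(row2$corr_rho))
  expect_identical(nrow(ls2), 2L)
})
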