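test_that("EMT score is mean mesenchymal z minus mean epithelial z", {
  p <- markers <- marker_panel()
  # all z = 0 -> score 0
  expect_equal(compute_emt_score(panel_expr(2, fill = 0))$score, c(0, 0))

  # mesenchymal all 1, epithelial all 0 -> score exactly 1
  em <- panel_expr(3, fill = 0)
  em$values[p$mesenchymal, ] <- 1
  expect_equal(compute_emt_score(em)$score, rep(1, 3))

  # random 16 x 5 matrix matches an independent per-column arithmetic oracle
  set.seed(101)
  em2 <- panel_expr(5)
  em2$values[] <- rnorm(length(em2$values))
  got <- compute_emt_score(em2)
  oracle <- vapply(seq_len(5), function(j)
    mean(em2$values[p$mesenchymal, j]) - mean(em2$values[p$epithelial, j]),
    numeric(1))
  expect_equal(got$score, oracle, tolerance = 1e-12)
  expect_identical(got$n_epi_used, rep(3L, 5))
  expect_identical(got$n_mes_used, rep(13L, 5))
})

test_that("missing panel genes are excluded pairwise; empty sides handled", {
  p <- marker_panel()
  em <- panel_expr(2)
  em$values[] <- 1
  em$values["CDH1", 1] <- NA             # pairwise exclusion
  got <- compute_emt_score(em)
  expect_equal(got$score, c(0, 0))
  expect_identical(got$n_epi_used, c(2L, 3L))

  # a sample with no usable epithelial gene gets NA with a warning
  em2 <- panel_expr(2)
  em2$values[p$epithelial, 1] <- NA
  expect_warning(got2 <- compute_emt_score(em2), "no usable panel gene")
  expect_true(is.na(got2$score[1]) && !is.na(got2$score[2]))

  # no mesenchymal gene at all in the matrix -> ineligible error
  m <- matrix(0, 3, 9, dimnames = list(p$epithelial, paste0("s", 1:9)))
  expect_error(compute_emt_score(make_expr(m)), "ineligible")
})

test_that("cohort eligibility enforces n > 100 and required epithelial markers", {
  big <- panel_expr(150)
  expect_true(check_cohort_eligibility(big)$eligible)

  small <- panel_expr(80)
  v <- check_cohort_eligibility(small)
  expect_false(v$eligible)
  expect_match(v$reasons, "n = 80 <= 100", all = FALSE)

  # matrix without CDH1 (the THCA-style exclusion)
  p <- marker_panel()
  genes <- setdiff(c(p$epithelial, p$mesenchymal), "CDH1")
  m <- matrix(0, length(genes), 150,
              dimnames = list(genes, paste0("s", 1:150)))
  v2 <- check_cohort_eligibility(make_expr(m))
  expect_false(v2$eligible)
  expect_match(v2$reasons, "required epithelial marker absent: CDH1",
               all = FALSE)
})

test_that("quartile stratification gives forced group sizes and handles ties", {
  sc <- data.frame(sample = letters[1:8], score = 1:8)
  gr <- stratify_by_emt(sc)
  expect_identical(as.character(gr$group[gr$score %in% c(7, 8)]),
                   rep("high", 2))
  expect_identical(as.character(gr$group[gr$score %in% c(1, 2)]),
                   rep("low", 2))
  expect_identical(as.integer(table(gr$group)["intermediate"]), 4L)

  # 1000 distinct scores -> exactly 250 high
  set.seed(9)
  sc2 <- data.frame(sample = paste0("s", 1:1000), score = sample(rnorm(1000)))
  gr2 <- stratify_by_emt(sc2)
  expect_identical(as.integer(table(gr2$group)), c(250L, 500L, 250L))

  # 12 scores with a 4-way tie spanning the upper boundary: sizes match the
  # brute-force rank-and-cut oracle under the stable tie rule
  tied <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.9, 0.9, 0.9, 0.9, 1.2)
  sc3 <- data.frame(sample = paste0("s", 1:12), score = tied)
  gr3 <- stratify_by_emt(sc3)
  expect_identical(as.character(gr3$group), stratify_oracle(tied))
  expect_identical(as.integer(table(gr3$group)), c(3L, 6L, 3L))

  expect_error(stratify_by_emt(data.frame(sample = letters[1:5], score = 1:5)),
               ">= 8")
})

test_that("stratification is monotone and scoring is translation-equivariant", {
  set.seed(77)
  p <- marker_panel()
  for (rep in 1:5) {
    em <- panel_expr(40)
    em$values[] <- rnorm(length(em$values))
    sc <- compute_emt_score(em)
    gr <- stratify_by_emt(sc)
    expect_true(min(gr$score[gr$group == "high"]) >=
                max(gr$score[gr$group == "low"]))

    # +c on mesenchymal rows raises every score by c; on epithelial lowers it
    cshift <- rnorm(1)
    em_up <- em; em_up$values[p$mesenchymal, ] <-
      em_up$values[p$mesenchymal, ] + cshift
    expect_equal(compute_emt_score(em_up)$score, sc$score + cshift,
                 tolerance = 1e-12)
    em_dn <- em; em_dn$values[p$epithelial, ] <-
      em_dn$values[p$epithelial, ] + cshift
    expect_equal(compute_emt_score(em_dn)$score, sc$score - cshift,
                 tolerance = 1e-12)

    # permutation invariance over genes and samples
    em_perm <- em
    em_perm$values <- em_perm$values[sample(nrow(em$values)),
                                     sample(ncol(em$values))]
    sc_perm <- compute_emt_score(em_perm)
    expect_equal(sc_perm$score[match(sc$sample, sc_perm$sample)], sc$score,
                 tolerance = 1e-12)
  }
})

test_that("distribution summary uses type-7 quantiles", {
  sc <- data.frame(sample = 1:3, score = c(-1, 0, 1))
  expect_equal(summarize_distribution(sc)$median, 0)

  # {0,1,2,3}: hand enumeration of linear-interpolation quartiles
  # h = 1 + p (n - 1): q1 at h = 1.75 -> 0.75; q3 at h = 3.25 -> 2.25
  sm <- summarize_distribution(data.frame(sample = 1:4, score = 0:3))
  expect_equal(sm$quartile1, 0.75)
  expect_equal(sm$quartile3, 2.25)
  expect_equal(sm$iqr, 1.5)

  expect_equal(summarize_distribution(
    data.frame(sample = 1:5, score = rep(2, 5)))$iqr, 0)
  expect_error(summarize_distribution(data.frame(sample = 1, score = 1)),
               ">= 2")
})

test_that("computed score tracks the planted EMT axis at moderate noise", {
  cfg <- slim_sim_config(seed = 31, n_samples = 300, noise_sd = 0.5)
  co <- generate_cohort(cfg)
  sc <- compute_emt_score(co$expression)
  rho <- cor(co$truth$axis[sc$sample], sc$score, method = "spearman")
  expect_gt(rho, 0.9)
})
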