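test_that("median profiles have one row per cohort-group with exact medians", {
  set.seed(40)
  mk_cohort <- function(seed) {
    co <- generate_cohort(simulation_config(n_samples = 40, seed = seed))
    tt <- assemble_time_table(co$enrichment, co$expression,
                              sig_scores = score_signatures(co$expression))
    gr <- stratify_by_emt(compute_emt_score(co$expression))
    list(tt = tt, gr = gr)
  }
  c1 <- mk_cohort(1); c2 <- mk_cohort(2)
  med <- build_median_profiles(list(A = c1$tt, B = c2$tt),
                               list(A = c1$gr, B = c2$gr))
  expect_identical(dim(med), c(6L, 59L))
  expect_setequal(rownames(med),
                  c(outer(c("A", "B"), c("low", "intermediate", "high"),
                          paste, sep = ".")))

  # independent sort-and-middle median oracle for one cell
  hi <- c1$gr$sample[c1$gr$group == "high"]
  v <- sort(c1$tt$values["Macrophages", hi])
  mid <- if (length(v) %% 2 == 1) v[(length(v) + 1) / 2]
         else mean(v[length(v) / 2 + 0:1])
  expect_equal(med["A.high", "Macrophages"], unname(mid), tolerance = 1e-12)

  # empty group errors with cohort and group named
  gr_bad <- c2$gr[c2$gr$group != "low", ]
  attr(gr_bad, "cohort_id") <- "B"
  expect_error(build_median_profiles(list(A = c1$tt, B = c2$tt),
                                     list(A = c1$gr, B = gr_bad)),
               "B has an empty 'low'")
})

test_that("PCA explains variance correctly and reconstructs its input", {
  # identical columns -> one component carries 100% of the variance
  set.seed(50)
  base <- rnorm(10)
  m <- cbind(a = base, b = base, c = base)
  pc <- run_pca(m, standardize = FALSE)
  expect_equal(pc$explained_variance_pct[1L], 100, tolerance = 1e-9)

  # 2x2: component variances match closed-form covariance eigenvalues
  m2 <- matrix(c(1, 3, 2, 8), 2, 2, dimnames = list(c("r1", "r2"),
                                                    c("x", "y")))
  pc2 <- run_pca(m2, standardize = FALSE)
  S <- stats::cov(m2)
  tr <- S[1, 1] + S[2, 2]; det_ <- S[1, 1] * S[2, 2] - S[1, 2]^2
  eig <- c((tr + sqrt(tr^2 - 4 * det_)) / 2, (tr - sqrt(tr^2 - 4 * det_)) / 2)
  expect_equal(pc2$explained_variance_pct,
               100 * eig / sum(eig), tolerance = 1e-9)

  # SVD identity: scores %*% t(loadings) reproduces the processed matrix
  m3 <- matrix(rnorm(60), 10, 6,
               dimnames = list(paste0("r", 1:10), paste0("m", 1:6)))
  pc3 <- run_pca(m3, standardize = TRUE)
  recon <- pc3$scores %*% t(pc3$loadings)
  expect_equal(recon, scale(m3), tolerance = 1e-10, ignore_attr = TRUE)

  # invariants: explained variance non-increasing, sums to 100;
  # contributions sum to 100 per component
  expect_true(all(diff(pc3$explained_variance_pct) <= 1e-12))
  expect_equal(sum(pc3$explained_variance_pct), 100, tolerance = 1e-9)
  expect_equal(unname(colSums(pc3$contributions_pct)),
               rep(100, ncol(pc3$contributions_pct)), tolerance = 1e-9)

  expect_error(run_pca(matrix(1, 5, 3,
                              dimnames = list(NULL, c("a", "b", "c"))),
                       standardize = FALSE), "rank 0")
})

test_that("top contributors rank markers by squared-loading share on PC1", {
  # one dominant marker, others (nearly) constant
  set.seed(60)
  m <- cbind(dom = rnorm(12, sd = 5), flat1 = rnorm(12, sd = 1e-3),
             flat2 = rnorm(12, sd = 1e-3))
  pc <- run_pca(m, standardize = FALSE)
  expect_identical(top_contributors(pc, 1), "dom")

  m2 <- matrix(rnorm(72), 12, 6, dimnames = list(NULL, paste0("m", 1:6)))
  pc2 <- run_pca(m2)
  all6 <- top_contributors(pc2, 6)
  share <- 100 * pc2$loadings[, 1]^2 / sum(pc2$loadings[, 1]^2)
  expect_identical(all6, names(sort(share, decreasing = TRUE)))
  expect_equal(sum(pc2$contributions_pct[, 1]), 100, tolerance = 1e-9)
  expect_error(top_contributors(pc2, 0), "positive")
})

test_that("conditional probabilities are exact count ratios obeying total probability", {
  co <- generate_cohort(simulation_config(n_samples = 120, seed = 7))
  sc <- compute_emt_score(co$expression)
  gr <- stratify_by_emt(sc)

  # marker == EMT score with median threshold: P(high|high-group) = 1,
  # P(high|low-group) = 0
  v <- setNames(sc$score, sc$sample)
  cp <- conditional_prob_high(v, gr)
  expect_equal(cp$p_high[cp$group == "high"], 1)
  expect_equal(cp$p_high[cp$group == "low"], 0)

  # all values above threshold -> P = 1 everywhere
  cp1 <- conditional_prob_high(v, gr, threshold = min(v) - 1)
  expect_equal(cp1$p_high, rep(1, 3))

  # random marker matches exhaustive counting, and satisfies the law of
  # total probability exactly
  set.seed(71)
  m <- setNames(rnorm(length(v)), names(v))
  cp2 <- conditional_prob_high(m, gr)
  thr <- median(m)
  for (g in c("low", "intermediate", "high")) {
    in_g <- gr$sample[gr$group == g]
    expect_equal(cp2$p_high[cp2$group == g],
                 sum(m[in_g] >= thr) / length(in_g))
  }
  overall <- sum(cp2$p_high * cp2$n) / sum(cp2$n)
  expect_equal(overall, mean(m >= thr), tolerance = 1e-12)
})

test_that("silhouette-selected K-means recovers planted archetype structure", {
  # two well-separated blobs of cohort profiles
  set.seed(80)
  blob <- function(center, n, label) {
    m <- matrix(rnorm(n * 6, sd = 1), n, 6, byrow = TRUE) +
      matrix(center, n, 6, byrow = TRUE)
    rownames(m) <- paste0(label, seq_len(n))
    m
  }
  x <- rbind(blob(rep(0, 6), 11, "a"), blob(rep(10, 6), 11, "b"))
  colnames(x) <- paste0("m", 1:6)
  cl <- kmeans_with_silhouette(x, k_range = 2:6, restarts = 20, seed = 17)
  expect_identical(cl$k_optimal, 2L)
  lab <- cl$assignments
  expect_identical(length(unique(lab[1:11])), 1L)
  expect_identical(length(unique(lab[12:22])), 1L)
  expect_false(lab[1] == lab[12])

  # three planted blobs -> K = 3
  x3 <- rbind(blob(rep(0, 6), 8, "a"), blob(rep(10, 6), 8, "b"),
              blob(rep(-10, 6), 8, "c"))
  colnames(x3) <- paste0("m", 1:6)
  cl3 <- kmeans_with_silhouette(x3, k_range = 2:6, restarts = 20, seed = 17)
  expect_identical(cl3$k_optimal, 3L)

  # degenerate single cloud: silhouette low at every K, stable across seeds
  x1 <- blob(rep(0, 6), 20, "z"); colnames(x1) <- paste0("m", 1:6)
  cl1a <- kmeans_with_silhouette(x1, k_range = 2:4, restarts = 20, seed = 1)
  expect_true(all(cl1a$silhouette_by_k < 0.3))

  expect_error(kmeans_with_silhouette(x, k_range = 1:3), ">= 2")
})

test_that("K-means assignments are invariant to cohort row order", {
  set.seed(81)
  x <- rbind(matrix(rnorm(36), 6, 6), matrix(rnorm(36, 8), 6, 6))
  rownames(x) <- paste0("c", 1:12); colnames(x) <- paste0("m", 1:6)
  cl <- kmeans_with_silhouette(x, k_range = 2:3, restarts = 25, seed = 17)
  perm <- sample(nrow(x))
  clp <- kmeans_with_silhouette(x[perm, ], k_range = 2:3, restarts = 25,
                                seed = 17)
  # same partition up to label swap
  a <- cl$assignments[rownames(x)]
  b <- clp$assignments[rownames(x)]
  expect_identical(a == a[1], b == b[1])
  expect_identical(cl$k_optimal, clp$k_optimal)
})
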