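#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over t of the absolute difference between the two
#' empirical CDFs. The two-sided p-value is exact when \code{n*m <= 10000}
#' and neither vector has ties, and asymptotic (Kolmogorov distribution)
#' otherwise.
#'
#' @param x,y Numeric vectors; each needs >= 3 non-missing values.
#' @return List with \code{statistic} (D), \code{p_value}, \code{n_x},
#'   \code{n_y} and \code{exact} (logical).
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop(sprintf("KS test needs >= 3 values per group, got n_x = %d, n_y = %d",
                 length(x), length(y)))
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 10000) && !has_ties
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       n_x = length(x), n_y = length(y), exact = exact)
}

#' One-way fixed-effects ANOVA
#'
#' Classic equal-variance F test comparing k group means, with degrees of
#' freedom (k - 1, N - k).
#'
#' @param groups List of numeric vectors, one per group; each needs >= 2
#'   non-missing values.
#' @return List with \code{statistic} (F), \code{p_value}, \code{df1},
#'   \code{df2}.
#' @export
anova_one_way <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (length(groups) < 2L) stop("ANOVA needs >= 2 groups")
  if (any(sizes < 2L))
    stop("every group needs >= 2 values; sizes: ",
         paste(sizes, collapse = ", "))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0)
    stop("zero within-group variance everywhere; F undefined")
  value <- unlist(groups, use.names = FALSE)
  gfac <- factor(rep(seq_along(groups), sizes))
  ft <- stats::oneway.test(value ~ gfac, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = unname(ft$p.value),
       df1 = unname(ft$parameter[1L]), df2 = unname(ft$parameter[2L]))
}

#' Correlate a marker with the EMT score
#'
#' Spearman rank correlation (default) between per-sample marker values and
#' EMT scores, with the asymptotic t-approximation p-value. Pearson is
#' available via \code{method}. Pairs are matched by sample name when both
#' inputs are named, otherwise by position.
#'
#' @param scores An \code{"emt_scores"} object, or a numeric vector of
#'   scores (named by sample or positional).
#' @param marker_values Numeric vector of marker values (named by sample or
#'   positional).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return List with \code{rho}, \code{p_value}, \code{n}, \code{method}.
#' @export
correlate_with_emt <- function(scores, marker_values,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.data.frame(scores)) {
    s <- scores$score
    names(s) <- scores$sample
  } else s <- scores
  if (!is.null(names(s)) && !is.null(names(marker_values))) {
    shared <- intersect(names(s), names(marker_values))
    s <- s[shared]; marker_values <- marker_values[shared]
  } else if (length(s) != length(marker_values))
    stop("unnamed inputs of different lengths")
  keep <- !is.na(s) & !is.na(marker_values)
  s <- s[keep]; m <- marker_values[keep]
  if (length(s) < 4L)
    stop("correlation needs >= 4 paired non-missing observations, got ",
         length(s))
  if (length(unique(m)) == 1L) stop("degenerate marker: constant values")
  ct <- suppressWarnings(stats::cor.test(s, m, method = method, exact = FALSE))
  list(rho = unname(ct$estimate), p_value = unname(ct$p.value),
       n = length(s), method = method)
}

#' Convert a p-value to a significance band
#'
#' \code{***} for p < 0.001, \code{**} for 0.001 <= p < 0.01, \code{*} for
#' 0.01 <= p < 0.05, \code{NS} otherwise. Vectorized; \code{NA} maps to
#' \code{NA}.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Character vector of bands.
#' @export
p_to_band <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-value outside [0, 1]: ", p[bad][1L])
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01, "**",
             ifelse(p[ok] < 0.05, "*", "NS")))
  out
}

#' Contrast every TIME marker between EMT groups
#'
#' Builds one cohort's median-difference landscape: for each marker, the
#' difference of medians between EMT-high and EMT-low samples, a two-sample
#' KS test (high vs low), a one-way ANOVA across the three groups, and the
#' Spearman correlation of the marker with the EMT score. Markers with
#' insufficient or degenerate data carry \code{NA} statistics (never
#' silently dropped).
#'
#' @param time A \code{"time_marker_table"}.
#' @param groups An \code{"emt_groups"} assignment.
#' @param scores An \code{"emt_scores"} object (for the correlation); may be
#'   \code{NULL} to skip correlations.
#' @return A data.frame of class \code{"emt_landscape"}, one row per marker:
#'   marker, category, delta_median, ks_stat, ks_p, ks_band, anova_f,
#'   anova_p, anova_band, corr_rho, corr_p, n_high, n_int, n_low.
#' @export
build_landscape <- function(time, groups, scores = NULL) {
  stopifnot(inherits(time, "time_marker_table"), is.data.frame(groups))
  shared <- intersect(colnames(time$values), groups$sample)
  if (length(shared) == 0L)
    stop("no sample shared between marker table and group assignment")
  grp <- groups$group[match(shared, groups$sample)]
  vals <- time$values[, shared, drop = FALSE]
  if (!is.null(scores)) {
    sv <- scores$score[match(shared, scores$sample)]
    names(sv) <- shared
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  rows <- lapply(seq_len(nrow(vals)), function(i) {
    v <- vals[i, ]
    hi <- v[grp == "high"]; lo <- v[grp == "low"]; md <- v[grp == "intermediate"]
    dm <- if (any(!is.na(hi)) && any(!is.na(lo)))
      stats::median(hi, na.rm = TRUE) - stats::median(lo, na.rm = TRUE)
    else NA_real_
    ks <- safe(ks_two_sample(hi, lo))
    av <- safe(anova_one_way(list(hi, md, lo)))
    co <- if (!is.null(scores)) safe(correlate_with_emt(sv, v)) else NULL
    data.frame(marker = rownames(vals)[i], category = time$category[i],
               delta_median = dm,
               ks_stat = if (is.null(ks)) NA_real_ else ks$statistic,
               ks_p = if (is.null(ks)) NA_real_ else ks$p_value,
               anova_f = if (is.null(av)) NA_real_ else av$statistic,
               anova_p = if (is.null(av)) NA_real_ else av$p_value,
               corr_rho = if (is.null(co)) NA_real_ else co$rho,
               corr_p = if (is.null(co)) NA_real_ else co$p_value,
               n_high = sum(!is.na(hi)), n_int = sum(!is.na(md)),
               n_low = sum(!is.na(lo)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ks_band <- p_to_band(out$ks_p)
  out$anova_band <- p_to_band(out$anova_p)
  attr(out, "cohort_id") <- attr(groups, "cohort_id")
  class(out) <- c("emt_landscape", "data.frame")
  out
}

#' Write a landscape table to TSV
#' @param x An \code{"emt_landscape"} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(x, path) {
  utils::write.table(format(x, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
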