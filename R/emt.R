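#' Compute per-sample EMT scores
#'
#' For every sample, the EMT score is the mean z-score over the available
#' mesenchymal panel genes minus the mean z-score over the available
#' epithelial panel genes. Missing values are excluded pairwise: each
#' sample's means run over its non-missing panel genes. A sample with no
#' usable gene on either side receives a missing score (with a warning).
#'
#' @param expr An \code{\link{expression_matrix}} of per-gene z-scores.
#' @param panel A \code{\link{marker_panel}}.
#' @return An object of class \code{"emt_scores"}: a data.frame with columns
#'   \code{sample}, \code{score}, \code{n_epi_used}, \code{n_mes_used} and
#'   attribute \code{cohort_id}.
#' @examples
#' m <- matrix(0, 16, 2, dimnames = list(
#'   c(marker_panel()$epithelial, marker_panel()$mesenchymal),
#'   c("s1", "s2")))
#' compute_emt_score(expression_matrix(m, "EX"), marker_panel())$score  # 0 0
#' @export
compute_emt_score <- function(expr, panel = marker_panel()) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(panel, "marker_panel"))
  genes <- rownames(expr$values)
  epi <- intersect(panel$epithelial, genes)
  mes <- intersect(panel$mesenchymal, genes)
  absent <- setdiff(c(panel$epithelial, panel$mesenchymal), genes)
  if (length(absent) > 0L)
    message("cohort ", expr$cohort_id, ": panel gene(s) absent from matrix: ",
            paste(absent, collapse = ", "))
  if (length(epi) == 0L || length(mes) == 0L)
    stop("cohort ", expr$cohort_id, " is ineligible for EMT scoring: no usable ",
         if (length(epi) == 0L) "epithelial" else "mesenchymal",
         " panel gene in the matrix")
  epi_mat <- expr$values[epi, , drop = FALSE]
  mes_mat <- expr$values[mes, , drop = FALSE]
  n_epi <- colSums(!is.na(epi_mat))
  n_mes <- colSums(!is.na(mes_mat))
  epi_mean <- colMeans(epi_mat, na.rm = TRUE)
  mes_mean <- colMeans(mes_mat, na.rm = TRUE)
  score <- mes_mean - epi_mean
  score[n_epi == 0L | n_mes == 0L] <- NA_real_
  if (anyNA(score))
    warning(sum(is.na(score)), " sample(s) with no usable panel gene on one ",
            "side; score set to NA")
  out <- data.frame(sample = colnames(expr$values), score = unname(score),
                    n_epi_used = as.integer(n_epi),
                    n_mes_used = as.integer(n_mes),
                    stringsAsFactors = FALSE)
  attr(out, "cohort_id") <- expr$cohort_id
  class(out) <- c("emt_scores", "data.frame")
  out
}

#' Check whether a cohort is eligible for EMT analysis
#'
#' A cohort is ineligible when its sample count is at or below
#' \code{min_samples} (the analysis requires n > 100 by default), or when any
#' required panel gene is entirely absent from its expression matrix. By
#' default all epithelial markers are required, mirroring the exclusion of a
#' cohort whose matrix lacked CDH1.
#'
#' @param expr An \code{\link{expression_matrix}}.
#' @param panel A \code{\link{marker_panel}}.
#' @param min_samples Minimum sample count (exclusive bound); default 100.
#' @param required_genes Genes that must be present; default the panel's
#'   epithelial list.
#' @return List with \code{eligible} (logical) and \code{reasons}
#'   (character vector, empty when eligible).
#' @export
check_cohort_eligibility <- function(expr, panel = marker_panel(),
                                     min_samples = 100,
                                     required_genes = panel$epithelial) {
  stopifnot(inherits(expr, "expression_matrix"))
  reasons <- character(0)
  n <- ncol(expr$values)
  if (n <= min_samples)
    reasons <- c(reasons, sprintf("insufficient samples: n = %d <= %d",
                                  n, min_samples))
  absent <- setdiff(required_genes, rownames(expr$values))
  for (g in absent) {
    side <- if (g %in% panel$epithelial) "epithelial"
            else if (g %in% panel$mesenchymal) "mesenchymal" else "required"
    reasons <- c(reasons, sprintf("required %s marker absent: %s", side, g))
  }
  list(eligible = length(reasons) == 0L, reasons = reasons,
       cohort_id = expr$cohort_id, n_samples = n)
}

#' Stratify a cohort into EMT-high / intermediate / low groups
#'
#' Samples are assigned by within-cohort quartile of EMT score: the top
#' quartile is EMT-high ("mesenchymal"), the bottom quartile EMT-low
#' ("epithelial"), the middle half EMT-intermediate. Assignment uses a
#' deterministic rank rule: samples are ranked by (score, stable input
#' order); the lowest \code{floor(n * lower)} ranks are low and the ranks
#' above \code{ceiling(n * upper)} are high, so group sizes are always
#' exactly n/4, n/2, n/4 up to rounding even in the presence of ties.
#' Reported boundaries are the type-7 (linear interpolation) quantiles.
#'
#' @param scores An \code{"emt_scores"} object (see
#'   \code{\link{compute_emt_score}}), or a data.frame with \code{sample} and
#'   \code{score} columns.
#' @param lower,upper Quartile bounds in (0,1); defaults 0.25 and 0.75.
#' @return An object of class \code{"emt_groups"}: data.frame with columns
#'   \code{sample}, \code{score}, \code{group} (factor low < intermediate <
#'   high), plus attributes \code{boundaries} (the two score cut points) and
#'   \code{cohort_id}.
#' @examples
#' sc <- data.frame(sample = letters[1:8], score = 1:8)
#' table(stratify_by_emt(sc)$group)  # 2 low, 4 intermediate, 2 high
#' @export
stratify_by_emt <- function(scores, lower = 0.25, upper = 0.75) {
  stopifnot(is.data.frame(scores), all(c("sample", "score") %in% names(scores)))
  if (!(lower > 0 && lower < upper && upper < 1))
    stop("quartile bounds must satisfy 0 < lower < upper < 1")
  keep <- !is.na(scores$score)
  if (any(!keep))
    warning(sum(!keep), " sample(s) without a score excluded from stratification")
  sc <- scores[keep, , drop = FALSE]
  n <- nrow(sc)
  if (n < 8L)
    stop("stratification requires >= 8 scored samples, got ", n)
  # stable rank: order() breaks score ties by original input position
  rk <- integer(n)
  rk[order(sc$score)] <- seq_len(n)
  n_low <- floor(n * lower)
  cut_high <- ceiling(n * upper)
  group <- rep("intermediate", n)
  group[rk <= n_low] <- "low"
  group[rk > cut_high] <- "high"
  out <- data.frame(sample = sc$sample, score = sc$score,
                    group = factor(group, levels = c("low", "intermediate", "high")),
                    stringsAsFactors = FALSE)
  attr(out, "boundaries") <- stats::quantile(sc$score, c(lower, upper),
                                             type = 7, names = TRUE)
  attr(out, "cohort_id") <- attr(scores, "cohort_id")
  class(out) <- c("emt_groups", "data.frame")
  out
}

#' Summarize a cohort's EMT score distribution
#'
#' Median, quartiles and interquartile range (IQR) of the EMT score, using
#' the same type-7 linear-interpolation quantile convention as
#' \code{\link{stratify_by_emt}}.
#'
#' @param scores An \code{"emt_scores"} object or data.frame with a
#'   \code{score} column.
#' @return One-row data.frame: cohort_id, n, median, quartile1, quartile3, iqr.
#' @export
summarize_distribution <- function(scores) {
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  s <- scores$score[!is.na(scores$score)]
  if (length(s) < 2L)
    stop("distribution summary requires >= 2 scores, got ", length(s))
  q <- stats::quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(cohort_id = attr(scores, "cohort_id") %||% NA_character_,
             n = length(s), median = q[2L], quartile1 = q[1L],
             quartile3 = q[3L], iqr = q[3L] - q[1L],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
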