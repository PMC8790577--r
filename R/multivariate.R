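#' Per-group median marker profiles across cohorts
#'
#' Builds the (cohort, EMT group) x marker matrix of per-group medians of
#' every TIME marker — the input for the joint PCA of all cohorts and
#' groups. Rows are named \code{"<cohort>.<group>"}.
#'
#' @param time_tables Named list (by cohort) of \code{"time_marker_table"}s.
#' @param group_tables Named list (by cohort) of \code{"emt_groups"}.
#' @return Numeric matrix with attribute \code{row_info}, a data.frame of
#'   (cohort_id, group) per row.
#' @export
build_median_profiles <- function(time_tables, group_tables) {
  stopifnot(length(time_tables) > 0L,
            identical(names(time_tables), names(group_tables)))
  markers <- rownames(time_tables[[1L]]$values)
  lev <- c("low", "intermediate", "high")
  rows <- list(); info <- list()
  for (cid in names(time_tables)) {
    tt <- time_tables[[cid]]; gg <- group_tables[[cid]]
    shared <- intersect(colnames(tt$values), gg$sample)
    grp <- gg$group[match(shared, gg$sample)]
    for (g in lev) {
      idx <- shared[grp == g]
      if (length(idx) == 0L)
        stop("cohort ", cid, " has an empty '", g, "' group")
      rows[[paste(cid, g, sep = ".")]] <-
        apply(tt$values[markers, idx, drop = FALSE], 1L, stats::median,
              na.rm = TRUE)
      info[[paste(cid, g, sep = ".")]] <-
        data.frame(cohort_id = cid, group = g, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "row_info") <- do.call(rbind, info)
  out
}

#' Per-cohort high-minus-low delta profiles
#'
#' One row per cohort, one column per marker, holding
#' median(EMT-high) - median(EMT-low) — the values already computed in the
#' cohort's landscape.
#'
#' @param landscapes Named list (by cohort) of \code{"emt_landscape"}
#'   data.frames sharing the same marker set.
#' @return Numeric matrix, cohorts x markers.
#' @export
build_delta_profiles <- function(landscapes) {
  stopifnot(length(landscapes) > 0L)
  markers <- landscapes[[1L]]$marker
  rows <- lapply(landscapes, function(l) {
    if (!identical(l$marker, markers))
      stop("landscapes do not share a common marker set")
    l$delta_median
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(landscapes), markers)
  out
}

#' Principal component analysis of marker profiles
#'
#' Column-centered (and by default unit-variance-scaled, since markers live
#' on incommensurate scales) PCA via singular value decomposition. Zero
#' variance columns are dropped with a warning when standardizing; rows with
#' missing cells are dropped with a warning.
#'
#' @param x Numeric matrix (profiles x markers).
#' @param standardize Scale columns to unit variance (default \code{TRUE}).
#' @return Object of class \code{"emt_pca"}: list with \code{scores}
#'   (rows x components), \code{loadings} (markers x components),
#'   \code{explained_variance_pct} (per component, sums to 100) and
#'   \code{contributions_pct} (markers x components; each column sums
#'   to 100).
#' @export
run_pca <- function(x, standardize = TRUE) {
  stopifnot(is.matrix(x), is.numeric(x))
  drop_rows <- apply(x, 1L, anyNA)
  if (any(drop_rows)) {
    warning("dropping ", sum(drop_rows), " row(s) with missing cells: ",
            paste(utils::head(rownames(x)[drop_rows], 5), collapse = ", "))
    x <- x[!drop_rows, , drop = FALSE]
  }
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs >= 2 complete rows and >= 2 columns")
  sds <- apply(x, 2L, stats::sd)
  if (standardize && any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance column(s) before ",
            "standardized PCA")
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 non-constant columns")
  }
  if (all(apply(x, 2L, stats::sd) == 0)) stop("matrix has rank 0 after centering")
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2
  contrib <- 100 * pc$rotation^2 / rep(colSums(pc$rotation^2),
                                       each = nrow(pc$rotation))
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance_pct = 100 * ev / sum(ev),
                 contributions_pct = contrib,
                 center = pc$center, scale = pc$scale),
            class = "emt_pca")
}

#' @export
print.emt_pca <- function(x, ...) {
  cat(sprintf("PCA: %d rows, %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), ncol(x$scores),
              x$explained_variance_pct[1L],
              if (length(x$explained_variance_pct) > 1L)
                x$explained_variance_pct[2L] else 0))
  invisible(x)
}

#' Top-contributing markers of the first principal component
#'
#' Markers ranked by their percentage contribution (squared loading share)
#' to PC1, ties broken alphabetically.
#'
#' @param pca An \code{"emt_pca"} object.
#' @param n Number of markers to return.
#' @return Character vector of marker names, most contributing first.
#' @export
top_contributors <- function(pca, n = 4L) {
  stopifnot(inherits(pca, "emt_pca"))
  if (n <= 0L) stop("n must be positive")
  if (n > nrow(pca$contributions_pct))
    stop("n exceeds the number of markers (", nrow(pca$contributions_pct), ")")
  contrib <- pca$contributions_pct[, 1L]
  ord <- order(-contrib, names(contrib))
  names(contrib)[ord][seq_len(n)]
}

#' Conditional probability of high marker expression given EMT group
#'
#' "High" means marker value at or above a threshold — by default the pooled
#' median across all the cohort's samples; alternatively any pooled
#' quantile. P(high | group) is the exact count ratio within each group, so
#' the probabilities obey the law of total probability by construction.
#'
#' @param marker_values Named numeric vector (sample -> value).
#' @param groups An \code{"emt_groups"} assignment.
#' @param threshold Explicit threshold (marker units), or \code{NULL} to use
#'   the pooled quantile.
#' @param quantile_rule Pooled quantile defining "high" when
#'   \code{threshold} is \code{NULL}; default 0.5 (the median).
#' @return data.frame: group, n, n_high, p_high, threshold.
#' @export
conditional_prob_high <- function(marker_values, groups, threshold = NULL,
                                  quantile_rule = 0.5) {
  stopifnot(is.data.frame(groups))
  shared <- intersect(names(marker_values), groups$sample)
  if (length(shared) == 0L) stop("no sample shared with group assignment")
  v <- marker_values[shared]
  g <- groups$group[match(shared, groups$sample)]
  keep <- !is.na(v)
  v <- v[keep]; g <- g[keep]
  if (is.null(threshold))
    threshold <- stats::quantile(v, quantile_rule, type = 7, names = FALSE)
  lev <- c("low", "intermediate", "high")
  cnt <- table(factor(g, levels = lev))
  if (any(cnt == 0L))
    stop("empty EMT group(s): ", paste(lev[cnt == 0L], collapse = ", "))
  high <- v >= threshold
  data.frame(group = lev,
             n = as.integer(cnt[lev]),
             n_high = as.integer(tapply(high, factor(g, levels = lev), sum)[lev]),
             p_high = as.numeric(tapply(high, factor(g, levels = lev), mean)[lev]),
             threshold = threshold, stringsAsFactors = FALSE)
}

#' K-means classification of cohorts with silhouette-selected K
#'
#' Lloyd's K-means (best of \code{restarts} random starts, Euclidean
#' distance) on the delta-profile matrix for each K in \code{k_range};
#' the optimal K maximizes the mean silhouette width. Deterministic given
#' \code{seed}.
#'
#' @param x Numeric matrix (cohorts x markers), no missing cells.
#' @param k_range Integer candidates for K; minimum must be >= 2.
#' @param restarts Random restarts per K (default 50).
#' @param seed RNG seed (default 17).
#' @param standardize Scale columns to unit variance first (default
#'   \code{TRUE}, matching the PCA convention).
#' @return Object of class \code{"emt_clusters"}: list with
#'   \code{k_optimal}, \code{assignments} (named integer vector),
#'   \code{silhouette_by_k} (named numeric), \code{totss_by_k} and the
#'   \code{kmeans} fit at the optimum.
#' @export
kmeans_with_silhouette <- function(x, k_range = 2:8, restarts = 50L,
                                   seed = 17L, standardize = TRUE) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("delta-profile matrix contains missing cells")
  if (min(k_range) < 2L) stop("k_range minimum must be >= 2")
  k_range <- k_range[k_range <= nrow(x) - 1L]
  if (length(k_range) == 0L)
    stop("need at least max(k_range) + 1 rows for clustering")
  z <- if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    scale(x[, sds > 0, drop = FALSE])
  } else x
  d <- stats::dist(z)
  sil <- numeric(length(k_range)); names(sil) <- as.character(k_range)
  wss <- sil
  fits <- vector("list", length(k_range))
  set.seed(seed)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    # best-of-restarts Lloyd; a random start occasionally yields an empty
    # cluster (an error in stats::kmeans), so failed starts are redrawn
    fit <- NULL; tries <- 0L; done <- 0L
    while (done < restarts && tries < 20L * restarts) {
      tries <- tries + 1L
      cand <- tryCatch(
        suppressWarnings(stats::kmeans(z, centers = k, iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(cand)) next
      done <- done + 1L
      if (is.null(fit) || cand$tot.withinss < fit$tot.withinss) fit <- cand
    }
    if (is.null(fit)) stop("K-means failed for K = ", k)
    fits[[i]] <- fit
    wss[i] <- fit$tot.withinss
    sil[i] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
  }
  best <- which.max(sil)     # ties resolve to the smallest K
  assignments <- fits[[best]]$cluster
  names(assignments) <- rownames(x)
  structure(list(k_optimal = k_range[best], assignments = assignments,
                 silhouette_by_k = sil, tot_withinss_by_k = wss,
                 fit = fits[[best]]),
            class = "emt_clusters")
}

#' @export
print.emt_clusters <- function(x, ...) {
  cat(sprintf("K-means classification: optimal K = %d (mean silhouette %.3f)\n",
              x$k_optimal, x$silhouette_by_k[as.character(x$k_optimal)]))
  print(table(x$assignments))
  invisible(x)
}
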