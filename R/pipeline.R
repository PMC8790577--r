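#' Pipeline run configuration
#'
#' Bundles everything a full pipeline run needs: either a simulation recipe
#' or per-cohort input paths, the marker panel and signature definitions,
#' stratification thresholds, the clustering policy and the root seed.
#' All referenced paths are checked at validation time.
#'
#' @param output_dir Directory the run writes into (created if needed).
#' @param seed Root seed; all randomness in the run flows from it.
#' @param simulate List of arguments for
#'   \code{\link{generate_multicohort}} (used when \code{inputs} is
#'   \code{NULL}); e.g. \code{list(n_cohorts = 6, n_samples = 200)}.
#' @param inputs \code{NULL}, or a named list (by cohort) of lists with
#'   paths \code{expression}, \code{enrichment}, \code{clinical}.
#' @param gmt Optional path to a GMT file overriding the default signatures.
#' @param panel A \code{\link{marker_panel}}.
#' @param min_samples Cohort eligibility bound (n must exceed it; default 100).
#' @param quartiles Lower/upper stratification bounds (default 0.25, 0.75).
#' @param k_range,kmeans_restarts,kmeans_seed K-means policy
#'   (defaults 2:8, 50, 17).
#' @return Object of class \code{"run_config"}.
#' @export
run_config <- function(output_dir, seed = 1L,
                       simulate = list(n_cohorts = 6L, n_samples = 200L),
                       inputs = NULL, gmt = NULL,
                       panel = marker_panel(),
                       min_samples = 100L,
                       quartiles = c(0.25, 0.75),
                       k_range = 2:8, kmeans_restarts = 50L,
                       kmeans_seed = 17L) {
  if (!(quartiles[1L] > 0 && quartiles[1L] < quartiles[2L] && quartiles[2L] < 1))
    stop("quartile bounds must be ordered within (0, 1)")
  if (!is.null(gmt) && !file.exists(gmt))
    stop("GMT file does not exist: ", gmt)
  if (!is.null(inputs)) {
    if (is.null(names(inputs))) stop("inputs must be a named list (by cohort)")
    for (cid in names(inputs)) {
      need <- c("expression", "enrichment", "clinical")
      miss <- setdiff(need, names(inputs[[cid]]))
      if (length(miss) > 0L)
        stop("cohort ", cid, " inputs missing: ", paste(miss, collapse = ", "))
      for (p in unlist(inputs[[cid]][need]))
        if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, gmt = gmt,
                 panel = panel, min_samples = min_samples,
                 quartiles = quartiles, k_range = k_range,
                 kmeans_restarts = as.integer(kmeans_restarts),
                 kmeans_seed = as.integer(kmeans_seed)),
            class = "run_config")
}

# canonical hash of the config (output_dir excluded so the same analysis
# into two directories hashes identically)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  cfg$panel <- unclass(cfg$panel)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.15g", x)
    out[is.na(x)] <- "NA"
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a simulated multi-cohort bundle to disk
#'
#' Writes, per cohort, \code{expression_<id>.tsv},
#' \code{enrichment_<id>.tsv} and \code{clinical_<id>.tsv} in the formats
#' the readers accept, plus \code{ground_truth.json}.
#'
#' @param bundle Output of \code{\link{generate_multicohort}}.
#' @param dir Target directory (created if needed).
#' @return Named list of per-cohort input paths, suitable as the
#'   \code{inputs} argument of \code{\link{run_config}}.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  for (cid in names(bundle$cohorts)) {
    co <- bundle$cohorts[[cid]]
    paths <- list(
      expression = file.path(dir, paste0("expression_", cid, ".tsv")),
      enrichment = file.path(dir, paste0("enrichment_", cid, ".tsv")),
      clinical = file.path(dir, paste0("clinical_", cid, ".tsv")))
    write_expression_matrix(co$expression, paths$expression)
    write_enrichment_table(co$enrichment, paths$enrichment)
    write_clinical(co$clinical, paths$clinical)
    inputs[[cid]] <- paths
  }
  truth <- list(archetype = as.list(bundle$truth$archetype))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(inputs)
}

# load or simulate the per-cohort raw inputs
.load_bundle <- function(config) {
  if (!is.null(config$inputs)) {
    cohorts <- lapply(names(config$inputs), function(cid) {
      p <- config$inputs[[cid]]
      list(expression = read_expression_matrix(p$expression, cid),
           enrichment = read_enrichment_table(p$enrichment),
           clinical = read_clinical(p$clinical))
    })
    names(cohorts) <- names(config$inputs)
    list(cohorts = cohorts, truth = NULL)
  } else {
    do.call(generate_multicohort, c(config$simulate, list(seed = config$seed)))
  }
}

#' Run the full EMT/TIME pipeline
#'
#' Executes the pipeline stages in order — \code{score} (EMT scores, group
#' assignment, distribution summaries), \code{contrast} (signature scores,
#' TIME table, median-difference landscape per cohort), \code{cluster}
#' (median-profile PCA, top contributors, conditional probabilities,
#' delta-profile PCA + silhouette-selected K-means) and \code{survive}
#' (Kaplan-Meier curves and log-rank tests per cohort and endpoint) — and
#' writes each stage's tables under \code{config$output_dir}. Earlier
#' stages' results are always computed in memory (later stages need them),
#' but only the files of the stages listed in \code{stages} are written.
#'
#' @param config A \code{\link{run_config}}.
#' @param stages Character subset of
#'   \code{c("score", "contrast", "cluster", "survive")} to write.
#' @return The run manifest (also written as \code{manifest.json}):
#'   package version, seed, config hash, cohorts, stage file list with MD5
#'   checksums. Invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("score", "contrast", "cluster", "survive")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- .load_bundle(config)
  sigs <- if (!is.null(config$gmt)) read_gmt(config$gmt) else default_signatures()

  keep <- names(bundle$cohorts)[vapply(names(bundle$cohorts), function(cid) {
    elig <- check_cohort_eligibility(bundle$cohorts[[cid]]$expression,
                                     config$panel,
                                     min_samples = config$min_samples)
    if (!elig$eligible)
      message("excluding cohort ", cid, ": ",
              paste(elig$reasons, collapse = "; "))
    elig$eligible
  }, logical(1))]
  if (length(keep) == 0L) stop("no eligible cohort")
  cohorts <- bundle$cohorts[keep]

  files <- character(0)
  emit <- function(stage, writer, path) {
    if (stage %in% stages) {
      writer(path)
      files <<- c(files, path)
    }
  }

  ## stage: score
  scores <- list(); groups <- list(); summaries <- list()
  for (cid in names(cohorts)) {
    sc <- suppressMessages(compute_emt_score(cohorts[[cid]]$expression,
                                             config$panel))
    gr <- stratify_by_emt(sc, config$quartiles[1L], config$quartiles[2L])
    scores[[cid]] <- sc; groups[[cid]] <- gr
    summaries[[cid]] <- summarize_distribution(sc)
    tab <- as.data.frame(sc)
    tab$group <- as.character(gr$group[match(sc$sample, gr$sample)])
    emit("score", function(p) .write_tsv(tab, p),
         file.path(out_dir, paste0("emt_scores_", cid, ".tsv")))
  }
  emit("score", function(p) .write_tsv(do.call(rbind, summaries), p),
       file.path(out_dir, "score_summary.tsv"))

  ## stage: contrast
  time_tables <- list(); landscapes <- list()
  for (cid in names(cohorts)) {
    co <- cohorts[[cid]]
    sig_scores <- score_signatures(co$expression, sigs, on_missing = "drop")
    tt <- assemble_time_table(co$enrichment, co$expression,
                              sig_scores = sig_scores)
    time_tables[[cid]] <- tt
    landscapes[[cid]] <- build_landscape(tt, groups[[cid]], scores[[cid]])
    emit("contrast", function(p) write_time_table(tt, p),
         file.path(out_dir, paste0("time_markers_", cid, ".tsv")))
    emit("contrast", function(p) write_landscape(landscapes[[cid]], p),
         file.path(out_dir, paste0("landscape_", cid, ".tsv")))
  }

  ## stage: cluster
  med <- build_median_profiles(time_tables, groups)
  pca_med <- run_pca(med, standardize = TRUE)
  info <- attr(med, "row_info")
  top4 <- top_contributors(pca_med, min(4L, nrow(pca_med$contributions_pct)))
  cond <- list()
  for (cid in names(cohorts)) {
    for (mk in top4) {
      v <- time_tables[[cid]]$values[mk, ]
      cp <- conditional_prob_high(v, groups[[cid]])
      cp <- cbind(cohort_id = cid, marker = mk, cp)
      cond[[paste(cid, mk)]] <- cp
    }
  }
  delta <- build_delta_profiles(landscapes)
  cl <- kmeans_with_silhouette(delta, k_range = config$k_range,
                               restarts = config$kmeans_restarts,
                               seed = config$kmeans_seed)
  pca_delta <- run_pca(delta, standardize = TRUE)
  emit("cluster", function(p) .write_tsv(
    data.frame(row = rownames(pca_med$scores), cohort_id = info$cohort_id,
               group = info$group,
               pca_med$scores[, seq_len(min(4L, ncol(pca_med$scores)))],
               stringsAsFactors = FALSE), p),
    file.path(out_dir, "pca_scores.tsv"))
  emit("cluster", function(p) .write_tsv(
    data.frame(marker = rownames(pca_med$contributions_pct),
               pca_med$contributions_pct[, seq_len(min(4L, ncol(pca_med$contributions_pct)))],
               stringsAsFactors = FALSE), p),
    file.path(out_dir, "pca_contributions.tsv"))
  emit("cluster", function(p) .write_tsv(do.call(rbind, cond), p),
       file.path(out_dir, "conditional_probs.tsv"))
  emit("cluster", function(p) .write_tsv(
    data.frame(cohort_id = names(cl$assignments),
               cluster = unname(cl$assignments),
               pc1_delta = pca_delta$scores[names(cl$assignments), 1L],
               stringsAsFactors = FALSE), p),
    file.path(out_dir, "clusters.tsv"))
  emit("cluster", function(p) .write_tsv(
    data.frame(k = as.integer(names(cl$silhouette_by_k)),
               mean_silhouette = unname(cl$silhouette_by_k),
               tot_withinss = unname(cl$tot_withinss_by_k),
               stringsAsFactors = FALSE), p),
    file.path(out_dir, "silhouette_by_k.tsv"))

  ## stage: survive
  logrank_rows <- list()
  for (cid in names(cohorts)) {
    for (ep in c("os", "pfi")) {
      sv <- survival_by_emt_group(cohorts[[cid]]$clinical, groups[[cid]], ep)
      km_tab <- do.call(rbind, lapply(names(sv$km), function(g)
        cbind(group = g, as.data.frame(sv$km[[g]]))))
      emit("survive", function(p) .write_tsv(km_tab, p),
           file.path(out_dir, paste0("km_", cid, "_", ep, ".tsv")))
      logrank_rows[[paste(cid, ep)]] <- data.frame(
        cohort_id = cid, endpoint = ep,
        chi2_3group = sv$logrank_3group$chi2 %||% NA_real_,
        p_3group = sv$logrank_3group$p_value %||% NA_real_,
        chi2_high_vs_low = sv$logrank_high_vs_low$chi2 %||% NA_real_,
        p_high_vs_low = sv$logrank_high_vs_low$p_value %||% NA_real_,
        n_used = sv$n_used, stringsAsFactors = FALSE)
    }
  }
  emit("survive", function(p) .write_tsv(do.call(rbind, logrank_rows), p),
       file.path(out_dir, "logrank.tsv"))

  manifest <- list(package = "emtime",
                   version = as.character(utils::packageVersion("emtime")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   cohorts = names(cohorts),
                   stages = stages,
                   top_contributors = top4,
                   k_optimal = cl$k_optimal,
                   files = as.list(structure(unname(tools::md5sum(files)),
                                             names = basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
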