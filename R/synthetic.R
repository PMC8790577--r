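#' Default TIME marker couplings for simulation
#'
#' One row per simulated TIME marker: its category, its linear coupling
#' (beta) to the latent EMT axis, and its baseline level. The defaults plant
#' the qualitative structure the pipeline is designed to detect — strong
#' positive couplings for macrophage/TAM markers, most checkpoints,
#' immunosuppressive cytokines (TGFB1, IL10) and the inflammatory/exhaustion
#' signatures; a few negative couplings; and null markers for calibration.
#'
#' @return data.frame with columns name, category, coupling, baseline.
#' @export
default_marker_specs <- function() {
  cells <- default_immune_cells()
  cell_beta <- c("B cells" = -0.3, "CD4+ T cells" = 0.2, "CD8+ T cells" = 0.3,
                 "Tregs" = 0.8, "NK cells" = -0.5, "NKT cells" = 0,
                 "Monocytes" = 0.5, "Macrophages" = 1, "Macrophages M1" = 0.4,
                 "Macrophages M2" = 1, "Dendritic cells" = 0.3, "pDC" = 0,
                 "Neutrophils" = 0.2, "Eosinophils" = 0, "Mast cells" = 0.3,
                 "Th1 cells" = 0.2, "Th2 cells" = 0.4)
  cyto_beta <- c("IFNA1" = 0, "IFNB1" = 0, "IFNG" = 0.3, "TNFA" = 0.4,
                 "TGFB1" = 1, "IL1A" = 0.4, "IL1B" = 0.4, "IL2" = 0,
                 "IL3" = 0, "IL4" = -0.3, "IL5" = 0, "IL6" = 0.6,
                 "CXCL8" = 0.6, "IL10" = 1, "IL12A" = 0.3, "IL12B" = 0,
                 "STAT6" = 0)
  rbind(
    data.frame(name = cells, category = "immune_cell",
               coupling = unname(cell_beta[cells]), baseline = 1,
               stringsAsFactors = FALSE),
    data.frame(name = default_checkpoint_markers(), category = "checkpoint",
               coupling = 0.8, baseline = 0, stringsAsFactors = FALSE),
    data.frame(name = default_cytokine_markers(), category = "cytokine",
               coupling = unname(cyto_beta[default_cytokine_markers()]),
               baseline = 0, stringsAsFactors = FALSE))
}

#' Default signature-gene couplings for simulation
#'
#' @return Named numeric vector: coupling of each default signature's member
#'   genes to the latent EMT axis.
#' @export
default_signature_couplings <- function() {
  c(ifng_6gene = 0.5, inflammatory_13gene = 1, exhausted_cd8_9gene = 0.8,
    exhausted_cd8_3gene = 0.8, activated_stroma = 1, hypoxia = 0.5,
    cytolytic_activity = 0, tam = 1)
}

#' Simulation configuration
#'
#' Parameters of the synthetic TCGA-like cohort generator. Each sample
#' carries a latent EMT-axis position a ~ N(0, emt_axis_sd); mesenchymal
#' panel genes load +a, epithelial genes -a, and every TIME marker loads
#' beta * a, all with independent Gaussian noise. Survival hazard depends on
#' the stratified EMT group.
#'
#' @param n_samples Samples per cohort (default 400).
#' @param seed Integer RNG seed.
#' @param emt_axis_sd SD of the latent EMT axis (score units; default 1).
#' @param noise_sd SD of per-gene/per-marker Gaussian noise (z units;
#'   default 1).
#' @param marker_specs data.frame(name, category, coupling, baseline); see
#'   \code{\link{default_marker_specs}}.
#' @param signature_couplings Named numeric vector of per-signature gene
#'   couplings; see \code{\link{default_signature_couplings}}.
#' @param signatures Named list of \code{\link{gene_set}}s the couplings
#'   refer to.
#' @param hazard_ratio_high_vs_low Hazard ratio of the EMT-high vs EMT-low
#'   group (default 2).
#' @param censoring_rate Probability a subject is censored (default 0.3).
#' @param baseline_hazard Event hazard per day in the EMT-low group
#'   (default 1/1000).
#' @param panel \code{\link{marker_panel}} used for the planted EMT axis.
#' @param cohort_id Cohort identifier.
#' @return Object of class \code{"sim_config"}.
#' @export
simulation_config <- function(n_samples = 400L, seed = 1L, emt_axis_sd = 1,
                              noise_sd = 1,
                              marker_specs = default_marker_specs(),
                              signature_couplings = default_signature_couplings(),
                              signatures = default_signatures(),
                              hazard_ratio_high_vs_low = 2,
                              censoring_rate = 0.3,
                              baseline_hazard = 1 / 1000,
                              panel = marker_panel(),
                              cohort_id = "SIM1") {
  if (n_samples < 8L) stop("n_samples must be >= 8")
  if (emt_axis_sd <= 0) stop("emt_axis_sd must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (hazard_ratio_high_vs_low <= 0) stop("hazard ratio must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (!is.data.frame(marker_specs) ||
      !all(c("name", "category", "coupling", "baseline") %in% names(marker_specs)))
    stop("marker_specs needs columns name, category, coupling, baseline")
  if (anyDuplicated(marker_specs$name)) stop("duplicate marker spec names")
  bad_sig <- setdiff(names(signature_couplings), names(signatures))
  if (length(bad_sig) > 0L)
    stop("signature coupling(s) without a gene set: ",
         paste(bad_sig, collapse = ", "))
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 emt_axis_sd = emt_axis_sd, noise_sd = noise_sd,
                 marker_specs = marker_specs,
                 signature_couplings = signature_couplings,
                 signatures = signatures,
                 hazard_ratio_high_vs_low = hazard_ratio_high_vs_low,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 panel = panel, cohort_id = as.character(cohort_id)),
            class = "sim_config")
}

# softplus keeps simulated enrichment scores non-negative
.softplus <- function(x) log1p(exp(x))

#' Generate one synthetic cohort with known ground truth
#'
#' Draws a latent EMT axis per sample, builds a per-gene z-scored expression
#' matrix (panel genes, checkpoint/cytokine genes, signature genes), an
#' xCell-style non-negative enrichment table, and a clinical table whose OS
#' and PFI hazards depend on the stratified EMT group
#' (hazard = baseline * HR^g with g = 0, 0.5, 1 for low/intermediate/high;
#' PFI uses a 1.5x baseline hazard). Gene rows are re-standardized to mean
#' 0, SD 1 after generation. Fully reproducible from the config seed.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{expression} (\code{\link{expression_matrix}}),
#'   \code{enrichment} (\code{\link{enrichment_table}}), \code{clinical}
#'   (\code{\link{clinical_table}}) and \code{truth} (latent axis, specs,
#'   group assignment, hazard parameters).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("%s-%04d", config$cohort_id, seq_len(n))
  axis <- stats::rnorm(n, 0, config$emt_axis_sd)
  names(axis) <- samples
  noise <- function() stats::rnorm(n, 0, config$noise_sd)

  rows <- list()
  for (g in config$panel$mesenchymal) rows[[g]] <- axis + noise()
  for (g in config$panel$epithelial) rows[[g]] <- -axis + noise()
  specs <- config$marker_specs
  expr_specs <- specs[specs$category %in% c("checkpoint", "cytokine"), ]
  genes <- resolve_marker_genes(expr_specs$name)
  for (i in seq_len(nrow(expr_specs))) {
    g <- genes[[i]]
    if (!g %in% names(rows))
      rows[[g]] <- expr_specs$baseline[i] + expr_specs$coupling[i] * axis + noise()
  }
  for (sig in names(config$signature_couplings)) {
    beta <- config$signature_couplings[[sig]]
    for (g in config$signatures[[sig]]$genes)
      if (!g %in% names(rows)) rows[[g]] <- beta * axis + noise()
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- samples
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  vals <- (vals - mu) / sdv
  expr <- expression_matrix(vals, config$cohort_id)

  cell_specs <- specs[specs$category == "immune_cell", ]
  if (nrow(cell_specs) > 0L) {
    en <- t(vapply(seq_len(nrow(cell_specs)), function(i)
      .softplus(cell_specs$baseline[i] + cell_specs$coupling[i] * axis + noise()),
      numeric(n)))
    dimnames(en) <- list(cell_specs$name, samples)
    enrich <- enrichment_table(en)
  } else enrich <- NULL   # config simulates no immune-cell markers

  scores <- suppressMessages(compute_emt_score(expr, config$panel))
  groups <- stratify_by_emt(scores)
  gcode <- c(low = 0, intermediate = 0.5, high = 1)[as.character(groups$group)]
  gcode <- gcode[match(samples, groups$sample)]
  hr <- config$hazard_ratio_high_vs_low
  draw_endpoint <- function(base_hazard) {
    tt <- stats::rexp(n, rate = base_hazard * hr^gcode)
    ev <- stats::rbinom(n, 1L, 1 - config$censoring_rate)
    obs <- ifelse(ev == 1L, tt, stats::runif(n, 0, tt))
    list(time = obs, event = ev)
  }
  os <- draw_endpoint(config$baseline_hazard)
  pfi <- draw_endpoint(1.5 * config$baseline_hazard)
  clinical <- clinical_table(data.frame(
    sample = samples, os_time = os$time, os_event = os$event,
    pfi_time = pfi$time, pfi_event = pfi$event, stringsAsFactors = FALSE))

  truth <- list(axis = axis, marker_specs = specs,
                signature_couplings = config$signature_couplings,
                groups = groups,
                hazard = list(baseline = config$baseline_hazard,
                              hazard_ratio = hr,
                              group_code = gcode))
  list(expression = expr, enrichment = enrich, clinical = clinical,
       truth = truth)
}

#' Two (or more) cohort archetypes for planted clustering
#'
#' Builds archetype marker-spec tables by scaling the default TIME marker
#' couplings: an "inhibitory" archetype keeps the positive couplings, a
#' contrasting archetype flips (or nulls) them, so cohort delta profiles
#' separate into recoverable clusters.
#'
#' @param scales Numeric vector, one per archetype; each archetype's
#'   couplings are the defaults multiplied by its scale. Default
#'   \code{c(1, -1)}: an inhibitory and an anti-coupled archetype.
#' @return Named list of marker-spec data.frames.
#' @export
two_archetype_specs <- function(scales = c(inhibitory = 1, permissive = -1)) {
  if (is.null(names(scales)))
    names(scales) <- paste0("archetype", seq_along(scales))
  lapply(scales, function(s) {
    sp <- default_marker_specs()
    sp$coupling <- sp$coupling * s
    sp
  })
}

#' Generate a multi-cohort bundle with planted cluster structure
#'
#' Draws \code{n_cohorts} cohorts alternating over the supplied archetypes
#' (each archetype is a distinct marker-coupling vector), recording true
#' archetype membership as clustering ground truth. Cohort seeds are
#' derived deterministically from \code{seed}.
#'
#' @param n_cohorts Number of cohorts (default 22).
#' @param archetypes Named list of marker-spec data.frames
#'   (\code{\link{two_archetype_specs}}).
#' @param n_samples Samples per cohort (default 400).
#' @param seed Root seed.
#' @param ... Further arguments passed to \code{\link{simulation_config}}.
#' @return List with \code{cohorts} (named list of
#'   \code{\link{generate_cohort}} outputs) and \code{truth}
#'   (archetype membership per cohort).
#' @export
generate_multicohort <- function(n_cohorts = 22L,
                                 archetypes = two_archetype_specs(),
                                 n_samples = 400L, seed = 1L, ...) {
  if (length(archetypes) < 1L) stop("need >= 1 archetype")
  if (is.null(names(archetypes)))
    names(archetypes) <- paste0("archetype", seq_along(archetypes))
  assignment <- rep_len(names(archetypes), n_cohorts)
  ids <- sprintf("SIM%02d", seq_len(n_cohorts))
  cohorts <- vector("list", n_cohorts)
  names(cohorts) <- ids
  for (i in seq_len(n_cohorts)) {
    cfg <- simulation_config(n_samples = n_samples,
                             seed = seed + i * 1009L,
                             marker_specs = archetypes[[assignment[i]]],
                             cohort_id = ids[i], ...)
    cohorts[[i]] <- generate_cohort(cfg)
  }
  names(assignment) <- ids
  list(cohorts = cohorts, truth = list(archetype = assignment))
}
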