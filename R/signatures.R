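#' Score a gene signature per sample
#'
#' The signature score of a sample is the unweighted mean z-score over the
#' signature genes present in the matrix, with missing values excluded
#' pairwise. A 1-gene signature therefore equals that gene's z-score row.
#'
#' @param expr An \code{\link{expression_matrix}}.
#' @param set A \code{\link{gene_set}}.
#' @return List with \code{score} (named numeric vector, one per sample),
#'   \code{n_genes_used} and \code{genes_used}.
#' @export
score_signature <- function(expr, set) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(set, "gene_set"))
  present <- intersect(set$genes, rownames(expr$values))
  if (length(present) == 0L)
    stop("no gene of signature '", set$name, "' is present in cohort ",
         expr$cohort_id)
  sub <- expr$values[present, , drop = FALSE]
  score <- colMeans(sub, na.rm = TRUE)
  score[colSums(!is.na(sub)) == 0L] <- NA_real_
  list(score = score, n_genes_used = length(present), genes_used = present)
}

#' Score several signatures into a signatures-by-samples matrix
#'
#' @param expr An \code{\link{expression_matrix}}.
#' @param sets Named list of \code{\link{gene_set}} objects.
#' @param on_missing What to do for a signature with no gene in the matrix:
#'   \code{"error"} (default) or \code{"drop"} with a warning.
#' @return Numeric matrix, signatures x samples.
#' @export
score_signatures <- function(expr, sets = default_signatures(),
                             on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  rows <- list()
  for (nm in names(sets)) {
    res <- tryCatch(score_signature(expr, sets[[nm]]), error = function(e) e)
    if (inherits(res, "error")) {
      if (on_missing == "error") stop(res)
      warning("dropping signature '", nm, "': ", conditionMessage(res))
    } else rows[[nm]] <- res$score
  }
  if (length(rows) == 0L) stop("no scoreable signature")
  do.call(rbind, rows)
}

#' Assemble the unified TIME marker table
#'
#' Joins the four marker categories into one markers-by-samples matrix over
#' the samples shared by all sources: immune-cell enrichment scores (one row
#' per cell type), checkpoint and cytokine gene z-score rows (marker names
#' resolved to gene symbols via the alias table), and signature scores.
#' A checkpoint/cytokine marker whose gene is absent from the expression
#' matrix is kept as an all-missing row with a warning, never dropped
#' silently.
#'
#' @param enrich An \code{\link{enrichment_table}}.
#' @param expr An \code{\link{expression_matrix}}.
#' @param checkpoint_markers,cytokine_markers Marker names (defaults: the
#'   17-gene checkpoint and cytokine panels).
#' @param sig_scores Signatures-by-samples matrix from
#'   \code{\link{score_signatures}}, or \code{NULL} to skip signatures.
#' @param aliases Marker-name to gene-symbol map
#'   (\code{\link{default_marker_aliases}}).
#' @return Object of class \code{"time_marker_table"}: list with
#'   \code{values} (markers x samples matrix) and \code{category}
#'   (one of immune_cell, checkpoint, cytokine, signature per marker).
#' @export
assemble_time_table <- function(enrich, expr,
                                checkpoint_markers = default_checkpoint_markers(),
                                cytokine_markers = default_cytokine_markers(),
                                sig_scores = NULL,
                                aliases = default_marker_aliases()) {
  stopifnot(inherits(enrich, "enrichment_table"),
            inherits(expr, "expression_matrix"))
  samples <- intersect(colnames(enrich$values), colnames(expr$values))
  if (!is.null(sig_scores)) samples <- intersect(samples, colnames(sig_scores))
  if (length(samples) == 0L)
    stop("no sample shared between enrichment, expression",
         if (!is.null(sig_scores)) " and signature" else "", " tables")

  gene_rows <- function(markers) {
    syms <- resolve_marker_genes(markers, aliases)
    out <- matrix(NA_real_, nrow = length(markers), ncol = length(samples),
                  dimnames = list(markers, samples))
    hit <- syms %in% rownames(expr$values)
    if (any(!hit))
      warning("marker gene(s) absent from expression matrix, kept as NA rows: ",
              paste(markers[!hit], collapse = ", "))
    if (any(hit))
      out[markers[hit], ] <- expr$values[syms[hit], samples, drop = FALSE]
    out
  }

  blocks <- list(immune_cell = enrich$values[, samples, drop = FALSE],
                 checkpoint = gene_rows(checkpoint_markers),
                 cytokine = gene_rows(cytokine_markers))
  if (!is.null(sig_scores))
    blocks$signature <- sig_scores[, samples, drop = FALSE]
  values <- do.call(rbind, blocks)
  category <- rep(names(blocks), vapply(blocks, nrow, integer(1)))
  if (anyDuplicated(rownames(values)))
    stop("marker names must be unique across categories; duplicated: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  structure(list(values = values, category = category),
            class = "time_marker_table")
}

#' @export
print.time_marker_table <- function(x, ...) {
  cat(sprintf("time_marker_table: %d markers x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$category)),
                            table(x$category)), collapse = ", ")))
  invisible(x)
}

#' Write a TIME marker table to TSV
#'
#' Columns: marker, category, then one column per sample.
#' @param x A \code{"time_marker_table"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_time_table <- function(x, path) {
  stopifnot(inherits(x, "time_marker_table"))
  vals <- x$values
  cells <- matrix(sprintf("%.15g", vals), nrow = nrow(vals))
  cells[is.na(vals)] <- "NA"
  lines <- c(paste(c("marker", "category", colnames(vals)), collapse = "\t"),
             paste(rownames(vals), x$category,
                   apply(cells, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TIME marker table written by \code{\link{write_time_table}}
#' @param path Path to the TSV file.
#' @return A \code{"time_marker_table"}.
#' @export
read_time_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) < 3L || !identical(colnames(tab)[1:2], c("marker", "category")))
    stop("malformed TIME marker table header in ", path)
  vals <- .parse_numeric_cells(as.matrix(tab[, -(1:2), drop = FALSE]),
                               what = "marker")
  dimnames(vals) <- list(trimws(tab$marker), colnames(tab)[-(1:2)])
  structure(list(values = vals, category = tab$category),
            class = "time_marker_table")
}
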