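# Tokens treated as missing in numeric table cells.
NA_TOKENS <- c("NA", "", "NaN", "na", "NULL")

#' Construct a validated expression matrix
#'
#' Container for one cohort's per-gene z-scored expression: a numeric
#' genes-by-samples matrix with unique row (gene) and column (sample) names.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   dimnames set. Values must be finite or \code{NA}.
#' @param cohort_id Short cohort identifier (e.g. \code{"KIRC"}).
#' @return An object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(values, cohort_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  genes <- rownames(values); samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("values must carry gene rownames and sample colnames")
  genes <- trimws(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA")
  rownames(values) <- genes
  structure(list(cohort_id = as.character(cohort_id), values = values),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples (%.1f%% missing)\n",
              x$cohort_id, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a validated enrichment table
#'
#' Container for precomputed per-sample immune-cell enrichment scores
#' (an xCell-style table): cell types in rows, samples in columns,
#' non-negative values.
#'
#' @param values Numeric matrix (cell types x samples) with dimnames.
#' @return An object of class \code{"enrichment_table"}.
#' @export
enrichment_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry cell-type rownames and sample colnames")
  if (anyDuplicated(trimws(rownames(values))))
    stop("duplicate cell-type names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (any(values < 0, na.rm = TRUE))
    stop("enrichment scores must be >= 0")
  rownames(values) <- trimws(rownames(values))
  structure(list(values = values), class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d cell types x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a gene set
#'
#' @param name Signature name.
#' @param genes Character vector of member gene symbols (non-empty).
#' @param description Optional free-text description.
#' @return An object of class \code{"gene_set"}.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes,
                 description = as.character(description)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%d genes): %s\n", x$name, length(x$genes),
              paste(utils::head(x$genes, 8), collapse = ", ")))
  invisible(x)
}

# Parse a character matrix of cells into numerics, honouring NA tokens and
# raising an error that names the offending row/column.
.parse_numeric_cells <- function(cells, what = "value") {
  raw <- trimws(cells)
  is_na <- is.na(raw) | raw %in% NA_TOKENS
  num <- suppressWarnings(as.numeric(raw))
  bad <- matrix(!is_na & is.na(num), nrow = nrow(cells))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric %s cell '%s' at data row %d, column %d",
                 what, raw[bad][1L], idx[1L], idx[2L]))
  }
  num[is_na] <- NA_real_
  matrix(num, nrow = nrow(cells), ncol = ncol(cells))
}

# Read a generic "first column = row names" numeric TSV into a matrix.
.read_named_tsv_matrix <- function(path, what) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    stop("malformed header in ", path,
         ": expected a name column plus >= 1 sample column")
  if (nrow(tab) == 0L)
    stop("empty matrix in ", path)
  rn <- trimws(tab[[1L]])
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- .parse_numeric_cells(cells, what = what)
  colnames(vals) <- colnames(tab)[-1L]
  rownames(vals) <- rn
  vals
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects tab-separated text with a header row: first column gene symbols,
#' remaining columns one per sample. Values are per-gene z-scores; missing
#' values may be encoded as \code{NA}, \code{NaN} or empty cells. Duplicate
#' gene rows are collapsed by their (pairwise-complete) mean with a warning.
#' Sample order is preserved from the file.
#'
#' @param path Path to the TSV file.
#' @param cohort_id Cohort identifier attached to the result.
#' @param restandardize If \code{TRUE}, re-scale each gene to mean 0, SD 1
#'   across the cohort's samples (for raw, not pre-scaled, input).
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_matrix <- function(path, cohort_id, restandardize = FALSE) {
  vals <- .read_named_tsv_matrix(path, what = "expression")
  rn <- rownames(vals)
  if (anyDuplicated(rn)) {
    dups <- unique(rn[duplicated(rn)])
    warning("collapsing ", length(dups), " duplicated gene row(s) by mean: ",
            paste(utils::head(dups, 5), collapse = ", "))
    keep <- !duplicated(rn)
    collapsed <- vals[keep, , drop = FALSE]
    for (g in dups) {
      m <- colMeans(vals[rn == g, , drop = FALSE], na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      collapsed[g, ] <- m
    }
    vals <- collapsed
  }
  if (restandardize) {
    mu <- rowMeans(vals, na.rm = TRUE)
    sdv <- apply(vals, 1L, stats::sd, na.rm = TRUE)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    vals <- (vals - mu) / sdv
  }
  expression_matrix(vals, cohort_id)
}

#' Write an expression matrix to TSV
#'
#' Inverse of \code{\link{read_expression_matrix}}; numbers are written with
#' 15 significant digits so a read-back round-trip is exact to well beyond
#' 10 significant digits.
#'
#' @param x An \code{\link{expression_matrix}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  .write_named_tsv_matrix(x$values, path, name_col = "gene")
}

.write_named_tsv_matrix <- function(vals, path, name_col) {
  cells <- matrix(sprintf("%.15g", vals), nrow = nrow(vals))
  cells[is.na(vals)] <- "NA"
  lines <- c(paste(c(name_col, colnames(vals)), collapse = "\t"),
             paste(rownames(vals), apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an enrichment-score table from TSV
#'
#' First column cell-type names, remaining columns samples.
#'
#' @param path Path to the TSV file.
#' @return An \code{\link{enrichment_table}}.
#' @export
read_enrichment_table <- function(path) {
  enrichment_table(.read_named_tsv_matrix(path, what = "enrichment"))
}

#' Write an enrichment table to TSV
#' @param x An \code{\link{enrichment_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment_table <- function(x, path) {
  stopifnot(inherits(x, "enrichment_table"))
  .write_named_tsv_matrix(x$values, path, name_col = "cell_type")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path Path to the GMT file.
#' @return Named list of \code{\link{gene_set}} objects, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(f)))
    sets[[i]] <- gene_set(f[1L], f[-(1:2)], f[2L])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in ", path)
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of \code{\link{gene_set}} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else "-",
            s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical time-to-event table from TSV
#'
#' Expects one row per sample with overall-survival (OS) and
#' progression-free-interval (PFI) time/event columns. Rows with blank or
#' unparsable time/event entries are retained with \code{NA} (flagged
#' missing), never silently dropped. Negative times and events outside
#' \{0,1\} are validation errors.
#'
#' @param path Path to the TSV file.
#' @param columns Named list mapping the five roles (\code{sample},
#'   \code{os_time}, \code{os_event}, \code{pfi_time}, \code{pfi_event}) to
#'   the column names used in the file.
#' @return A \code{data.frame} of class \code{"clinical_table"} with columns
#'   sample, os_time, os_event, pfi_time, pfi_event.
#' @export
read_clinical <- function(path,
                          columns = list(sample = "sample",
                                         os_time = "os_time",
                                         os_event = "os_event",
                                         pfi_time = "pfi_time",
                                         pfi_event = "pfi_event")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  need <- unlist(columns)
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols) > 0L)
    stop("clinical table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "),
         " (expected: ", paste(need, collapse = ", "), ")")
  parse_num <- function(x) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    out[x %in% NA_TOKENS] <- NA_real_
    out
  }
  out <- data.frame(sample = trimws(tab[[columns$sample]]),
                    os_time = parse_num(tab[[columns$os_time]]),
                    os_event = parse_num(tab[[columns$os_event]]),
                    pfi_time = parse_num(tab[[columns$pfi_time]]),
                    pfi_event = parse_num(tab[[columns$pfi_event]]),
                    stringsAsFactors = FALSE)
  clinical_table(out)
}

#' Construct a validated clinical table
#'
#' @param df data.frame with columns sample, os_time, os_event, pfi_time,
#'   pfi_event. \code{NA} entries are allowed and mark missing records.
#' @return The validated data.frame, class \code{"clinical_table"}.
#' @export
clinical_table <- function(df) {
  need <- c("sample", "os_time", "os_event", "pfi_time", "pfi_event")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in clinical table")
  for (tc in c("os_time", "pfi_time"))
    if (any(df[[tc]] < 0, na.rm = TRUE))
      stop("negative ", tc, " for sample(s): ",
           paste(df$sample[which(df[[tc]] < 0)], collapse = ", "))
  for (ec in c("os_event", "pfi_event"))
    if (!all(df[[ec]] %in% c(0, 1, NA)))
      stop(ec, " must be 0, 1 or missing")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table to TSV
#' @param x A \code{\link{clinical_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_clinical <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
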