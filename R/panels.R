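#' Canonical 16-gene EMT marker panel
#'
#' Defines the epithelial and mesenchymal gene lists whose mean z-score
#' difference is the EMT score: \code{mean(z[mesenchymal]) - mean(z[epithelial])}.
#' The default panel holds 3 epithelial and 13 mesenchymal markers (16 genes).
#'
#' @param epithelial Character vector of epithelial marker gene symbols.
#' @param mesenchymal Character vector of mesenchymal marker gene symbols.
#' @return An object of class \code{"marker_panel"}: a list with elements
#'   \code{epithelial} and \code{mesenchymal}.
#' @examples
#' p <- marker_panel()
#' length(c(p$epithelial, p$mesenchymal))  # 16
#' @export
marker_panel <- function(epithelial = c("CDH1", "DSP", "TJP1"),
                         mesenchymal = c("VIM", "CDH2", "FOXC2", "SNAI1",
                                         "SNAI2", "TWIST1", "GSC", "FN1",
                                         "ITGB6", "MMP2", "MMP3", "MMP9",
                                         "SOX10")) {
  epithelial <- trimws(as.character(epithelial))
  mesenchymal <- trimws(as.character(mesenchymal))
  if (length(epithelial) == 0L || length(mesenchymal) == 0L)
    stop("both epithelial and mesenchymal lists must be non-empty")
  if (anyDuplicated(epithelial) || anyDuplicated(mesenchymal))
    stop("marker lists must not contain duplicates")
  if (length(intersect(epithelial, mesenchymal)) > 0L)
    stop("epithelial and mesenchymal lists must be disjoint; shared: ",
         paste(intersect(epithelial, mesenchymal), collapse = ", "))
  structure(list(epithelial = epithelial, mesenchymal = mesenchymal),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("EMT marker panel:", length(x$epithelial), "epithelial,",
      length(x$mesenchymal), "mesenchymal genes\n")
  cat("  epithelial: ", paste(x$epithelial, collapse = ", "), "\n", sep = "")
  cat("  mesenchymal:", paste(x$mesenchymal, collapse = ", "), "\n")
  invisible(x)
}

#' Default immune checkpoint marker names
#'
#' The 17 checkpoint molecules profiled by default. Names are the common
#' literature names; use \code{\link{default_marker_aliases}} to resolve them
#' to HGNC gene symbols present in expression matrices.
#'
#' @return Character vector of 17 marker names.
#' @export
default_checkpoint_markers <- function() {
  c("PD1", "PD-L1", "PD-L2", "CTLA4", "LAG3", "KIR", "TIM3", "VISTA",
    "NOX2", "SIGLEC5", "SIGLEC7", "SIGLEC15", "FASLG", "ICOS", "GITR",
    "TNFRSF4", "TNFRSF9")
}

#' Default cytokine marker names
#'
#' The 17 cytokine genes profiled by default.
#'
#' @return Character vector of 17 marker names.
#' @export
default_cytokine_markers <- function() {
  c("IFNA1", "IFNB1", "IFNG", "TNFA", "TGFB1", "IL1A", "IL1B", "IL2",
    "IL3", "IL4", "IL5", "IL6", "CXCL8", "IL10", "IL12A", "IL12B", "STAT6")
}

#' Default immune cell types
#'
#' The 17 immune cell types (innate and adaptive) whose precomputed
#' enrichment scores are profiled by default.
#'
#' @return Character vector of 17 cell-type names.
#' @export
default_immune_cells <- function() {
  c("B cells", "CD4+ T cells", "CD8+ T cells", "Tregs", "NK cells",
    "NKT cells", "Monocytes", "Macrophages", "Macrophages M1",
    "Macrophages M2", "Dendritic cells", "pDC", "Neutrophils",
    "Eosinophils", "Mast cells", "Th1 cells", "Th2 cells")
}

#' Marker-name to gene-symbol alias table
#'
#' Common checkpoint/cytokine names do not always match the official HGNC
#' symbols used as expression-matrix row names (e.g. PD1 is the gene PDCD1).
#' This editable table maps marker names to the symbol looked up in the
#' matrix; names absent from the table are looked up verbatim.
#'
#' @return Named character vector: names are marker names, values HGNC symbols.
#' @export
default_marker_aliases <- function() {
  c("PD1"    = "PDCD1",
    "PD-L1"  = "CD274",
    "PD-L2"  = "PDCD1LG2",
    "TIM3"   = "HAVCR2",
    "VISTA"  = "VSIR",
    "NOX2"   = "CYBB",
    "GITR"   = "TNFRSF18",
    "KIR"    = "KIR3DL1",
    "TNFA"   = "TNF")
}

#' Resolve marker names to gene symbols
#'
#' @param markers Character vector of marker names.
#' @param aliases Named character vector mapping marker name to gene symbol.
#' @return Named character vector of gene symbols (names = marker names).
#' @export
resolve_marker_genes <- function(markers, aliases = default_marker_aliases()) {
  out <- ifelse(markers %in% names(aliases), aliases[markers], markers)
  names(out) <- markers
  out
}

#' Default gene-expression signatures
#'
#' The eight TIME gene signatures scored by default: 6-gene IFN-gamma,
#' 13-gene inflammatory, 9-gene and 3-gene exhausted CD8+ T cells,
#' activated stroma, hypoxia, cytolytic activity and tumor-associated
#' macrophages (TAM). The memberships shipped here are package-curated
#' versions of widely used published signatures of the same names and are
#' meant to be replaced by the user's own GMT file when exact lists matter.
#'
#' @return A named list of \code{\link{gene_set}} objects.
#' @export
default_signatures <- function() {
  defs <- list(
    ifng_6gene = list(
      desc = "6-gene interferon-gamma signature",
      genes = c("IFNG", "STAT1", "IDO1", "CXCL9", "CXCL10", "HLA-DRA")),
    inflammatory_13gene = list(
      desc = "13-gene inflammatory signature",
      genes = c("CCL2", "CCL3", "CCL4", "CXCL9", "CXCL10", "CD8A", "ICOS",
                "IRF1", "IL6", "IL1B", "PTGS2", "TNF", "GZMB")),
    exhausted_cd8_9gene = list(
      desc = "9-gene exhausted CD8+ T-cell signature",
      genes = c("PDCD1", "CTLA4", "HAVCR2", "LAG3", "TIGIT", "BTLA",
                "CD160", "CD244", "ENTPD1")),
    exhausted_cd8_3gene = list(
      desc = "3-gene exhausted CD8+ T-cell signature",
      genes = c("PDCD1", "LAG3", "HAVCR2")),
    activated_stroma = list(
      desc = "activated stromal signature",
      genes = c("SPARC", "COL1A1", "COL1A2", "COL3A1", "COL5A1", "POSTN",
                "THBS2", "FAP", "FN1")),
    hypoxia = list(
      desc = "hypoxia signature",
      genes = c("VEGFA", "CA9", "SLC2A1", "LDHA", "PGK1", "HK2", "ADM",
                "NDRG1")),
    cytolytic_activity = list(
      desc = "cytolytic activity signature",
      genes = c("GZMA", "PRF1")),
    tam = list(
      desc = "tumor-associated macrophage signature",
      genes = c("CD68", "CD163", "MRC1", "MSR1", "CSF1R")))
  out <- lapply(names(defs), function(nm)
    gene_set(nm, defs[[nm]]$genes, defs[[nm]]$desc))
  names(out) <- names(defs)
  out
}
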