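# Shared fixtures and independent oracles used across test files.

# build a small expression matrix object from a numeric matrix
make_expr <- function(values, cohort = "TST") {
  expression_matrix(values, cohort)
}

# expression matrix covering the full 16-gene default panel
panel_expr <- function(n_samples = 4, fill = 0, cohort = "TST") {
  p <- marker_panel()
  genes <- c(p$epithelial, p$mesenchymal)
  m <- matrix(fill, nrow = length(genes), ncol = n_samples,
              dimnames = list(genes, paste0("s", seq_len(n_samples))))
  expression_matrix(m, cohort)
}

# write lines to a temp file, return path
tmp_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# slim simulation: 16 panel genes plus one planted and one null checkpoint
# marker, no signatures/immune cells -- used for replicate-heavy checks
slim_sim_config <- function(seed, n_samples = 400, coupling = 1,
                            noise_sd = 1) {
  specs <- data.frame(name = c("PLANTED", "NULLM"),
                      category = "checkpoint",
                      coupling = c(coupling, 0), baseline = 0,
                      stringsAsFactors = FALSE)
  simulation_config(n_samples = n_samples, seed = seed, noise_sd = noise_sd,
                    marker_specs = specs,
                    signature_couplings = stats::setNames(numeric(0), character(0)))
}

# independent KS-D oracle: scan |ECDF_x - ECDF_y| over all pooled breakpoints
ks_oracle_D <- function(x, y) {
  br <- sort(unique(c(x, y)))
  fx <- vapply(br, function(t) mean(x <= t), numeric(1))
  fy <- vapply(br, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# independent one-way ANOVA oracle: textbook between/within mean squares
anova_oracle_F <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  k <- length(groups); n <- length(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# independent Kaplan-Meier oracle: explicit life-table product-limit loop
km_oracle <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), survival = numeric(0),
                    at_risk = numeric(0))
  for (t in ev_times) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, survival = s, at_risk = n_risk))
  }
  out
}

# brute-force quartile stratification oracle under the stated tie rule:
# rank by (score, input index); cut at floor(n/4) and ceiling(3n/4)
stratify_oracle <- function(score) {
  n <- length(score)
  ord <- order(score, seq_len(n))
  rk <- integer(n); rk[ord] <- seq_len(n)
  out <- rep("intermediate", n)
  out[rk <= floor(n * 0.25)] <- "low"
  out[rk > ceiling(n * 0.75)] <- "high"
  out
}
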