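# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the whole suite runs in seconds except where a
# statistical property needs more data.

# a tiny but complete synthetic bundle (reference + screen + gene sets)
tiny_bundle <- function(seed = 42, n_genes = 40, n_cell_lines = 4,
                        replicates = 2, n_nontargeting = 60, ...) {
  cfg <- simulation_config(n_genes = n_genes, n_cell_lines = n_cell_lines,
                           replicates = replicates,
                           n_nontargeting = n_nontargeting, ...)
  end_to_end_fixture(cfg, seed = seed)
}

# guide -> gene map of a bundle's targeting guides
bundle_guide_map <- function(bundle) {
  g <- bundle$truth$guides
  setNames(g$gene, g$guide_id)
}

# guide-level fold-changes of a bundle after the standard chain
bundle_fc <- function(bundle, min_count = 30) {
  sc <- filter_low_plasmid(bundle$screen, min_count)
  log_fold_changes(normalize_rpm(sc), plasmid_samples(sc))
}

# replicate -> cell line map of a bundle's screen samples
bundle_line_map <- function(bundle) {
  s <- bundle$screen$samples
  s[s$role == "screen", c("sample_id", "cell_line")]
}

# independent brute-force oracle for the two-sample KS D statistic:
# evaluate both ECDFs at every pooled data point and take the largest gap
oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  f1 <- vapply(pts, function(t) mean(x <= t), numeric(1))
  f2 <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(f1 - f2))
}

# independent oracle for average precision: literal evaluation of
# sum_j (R_j - R_{j-1}) P_j over every rank j of the sorted list
oracle_ap <- function(reference, scores) {
  ord <- order(scores, names(scores))
  rel <- names(scores)[ord] %in% reference
  n_rel <- sum(rel)
  r_prev <- 0
  ap <- 0
  for (j in seq_along(rel)) {
    p_j <- sum(rel[seq_len(j)]) / j
    r_j <- sum(rel[seq_len(j)]) / n_rel
    ap <- ap + (r_j - r_prev) * p_j
    r_prev <- r_j
  }
  ap
}

# exhaustive cut-point oracle for the FDR fold-change threshold: try every
# candidate threshold (each classified fold-change, and +Inf), compute the
# FDR of the call set {fc < t} and keep the largest t whose FDR is within
# the target; an empty call set falls back to min(fc) - 1e-6 (low quality)
oracle_fdr_threshold <- function(gene_fc, essential, non_essential, fdr) {
  lab <- ifelse(names(gene_fc) %in% essential, 1L,
                ifelse(names(gene_fc) %in% non_essential, 0L, NA_integer_))
  fc <- gene_fc[!is.na(lab)]
  lab <- lab[!is.na(lab)]
  best <- NULL
  for (t in c(sort(unique(fc)), Inf)) {
    called <- fc < t
    if (!any(called)) next
    if (mean(lab[called] == 0) <= fdr) best <- max(best, t)
  }
  if (is.null(best)) unname(sort(fc)[1]) - 1e-6 else unname(best)
}
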