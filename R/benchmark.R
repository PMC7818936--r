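#' Recall curve of a guide or gene group along the fold-change ranking
#'
#' Items are sorted by fold-change from most negative to most positive and
#' the cumulative fraction of a designated group (e.g. guides targeting
#' essential genes) recovered at each rank is computed. The area under the
#' curve summarises the group's enrichment towards negative (area > 0.5) or
#' positive (area < 0.5) fold-changes; 0.5 is the random expectation. The
#' area is the trapezoidal integral of recall over the normalised rank axis
#' (recall 0 at rank 0), under which a group containing every item scores
#' exactly 0.5. Ties in fold-change are broken by item name, then input
#' order, deterministically.
#'
#' @param values numeric fold-change vector (optionally named).
#' @param group logical mask along `values`, or character vector of names.
#' @return list of class `recall_curve` with `rank` (normalised, i/N),
#'   `recall`, and `area`.
#' @export
recall_curve <- function(values, group) {
  if (is.character(group)) {
    if (is.null(names(values))) stop("`values` must be named to use ids")
    group <- names(values) %in% group
  }
  stopifnot(length(group) == length(values))
  if (!any(group)) stop("group is empty")
  ord <- order(values, names(values) %||% seq_along(values))
  hit <- group[ord]
  recall <- cumsum(hit) / sum(hit)
  n <- length(values)
  area <- sum((recall + c(0, recall[-n])) / 2) / n
  structure(list(rank = seq_len(n) / n, recall = recall, area = area),
            class = "recall_curve")
}

#' @export
print.recall_curve <- function(x, ...) {
  cat(sprintf("recall_curve over %d items, area = %.4f\n",
              length(x$rank), x$area))
  invisible(x)
}

# ROC of essential (positive, more-negative FC ranks first) vs non-essential.
# Returns the step-curve vertices including (0,0) and (1,1); ties in FC move
# diagonally (one vertex per unique threshold).
roc_points <- function(gene_fc, essential, non_essential) {
  lab <- ifelse(names(gene_fc) %in% essential, 1L,
                ifelse(names(gene_fc) %in% non_essential, 0L, NA_integer_))
  keep <- !is.na(lab) & is.finite(gene_fc)
  fc <- gene_fc[keep]; lab <- lab[keep]
  if (sum(lab == 1) == 0 || sum(lab == 0) == 0)
    stop("both essential and non-essential genes must be present")
  ord <- order(fc)
  fc <- fc[ord]; lab <- lab[ord]
  np <- sum(lab == 1); nn <- sum(lab == 0)
  last <- !duplicated(fc, fromLast = TRUE)   # collapse FC ties
  tpr <- c(0, cumsum(lab == 1)[last] / np)
  fpr <- c(0, cumsum(lab == 0)[last] / nn)
  list(fpr = fpr, tpr = tpr, thresholds = c(-Inf, fc[last]),
       n_pos = np, n_neg = nn)
}

#' Standardised partial area under the essential-gene ROC curve
#'
#' Genes are ranked by fold-change (most negative first) and an ROC curve of
#' reference essential (positives) versus non-essential (negatives) genes is
#' built. The area under the curve up to a false-positive-rate cap
#' (default 0.2) is computed by trapezoidal integration, interpolating the
#' curve at the cap, and standardised so the score does not depend on the
#' cap's magnitude. With `standardize = "proportional"` (default) the
#' partial area is divided by the cap: a perfect classifier scores 1 and
#' chance scores `fpr_cap / 2` (0.1 at the default cap). The McClish
#' transformation, which maps chance to 0.5 and perfection to 1, is
#' available with `standardize = "mcclish"`. With `fpr_cap = 1` the
#' proportional score equals the full AROC.
#'
#' @param gene_fc named numeric vector of gene-level fold-changes.
#' @param essential,non_essential character vectors of reference gene sets.
#' @param fpr_cap maximum false positive rate (0 < cap <= 1, default 0.2).
#' @param standardize `"proportional"` or `"mcclish"`.
#' @return A number in \[0, 1\].
#' @export
partial_aroc <- function(gene_fc, essential, non_essential, fpr_cap = 0.2,
                         standardize = c("proportional", "mcclish")) {
  standardize <- match.arg(standardize)
  stopifnot(fpr_cap > 0, fpr_cap <= 1)
  r <- roc_points(gene_fc, essential, non_essential)
  fpr <- r$fpr; tpr <- r$tpr
  if (fpr_cap < 1) {
    inside <- fpr <= fpr_cap
    # interpolate the curve at the cap if it is crossed between vertices
    if (any(!inside)) {
      i <- which(!inside)[1]
      t_cap <- if (fpr[i] > fpr[i - 1])
        tpr[i - 1] + (tpr[i] - tpr[i - 1]) *
          (fpr_cap - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
      else tpr[i - 1]
      fpr <- c(fpr[inside], fpr_cap)
      tpr <- c(tpr[inside], t_cap)
    }
  }
  pauc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  switch(standardize,
         proportional = pauc / fpr_cap,
         mcclish = 0.5 * (1 + (pauc - fpr_cap^2 / 2) /
                            (fpr_cap - fpr_cap^2 / 2)))
}

#' Fold-change threshold at a target essential-gene FDR
#'
#' Walking the ROC of reference essential vs non-essential genes from the
#' most negative fold-change upward, the FDR at a cut is the fraction of
#' non-essential genes among the reference genes already passed. The
#' returned threshold is the most permissive (largest) value such that
#' calling `fc < threshold` keeps the reference FDR at or below `fdr`:
#' it is the fold-change of the first reference gene beyond the accepted
#' prefix (`Inf` when the whole reference passes). Genes outside both
#' reference sets do not enter the FDR computation but are called against
#' the returned threshold. When even the single most negative reference
#' gene violates the FDR, the threshold falls just below the most negative
#' reference fold-change and the sample is flagged low quality.
#'
#' @inheritParams partial_aroc
#' @param fdr target false discovery rate in (0, 1) (default 0.01).
#' @return list with `threshold`, `fdr` (the target), `n_reference_called`
#'   and `low_quality`.
#' @export
fc_threshold_at_fdr <- function(gene_fc, essential, non_essential,
                                fdr = 0.01) {
  stopifnot(fdr > 0, fdr <= 1)
  lab <- ifelse(names(gene_fc) %in% essential, 1L,
                ifelse(names(gene_fc) %in% non_essential, 0L, NA_integer_))
  keep <- !is.na(lab) & is.finite(gene_fc)
  fc <- gene_fc[keep]; lab <- lab[keep]
  if (sum(lab == 1) == 0 || sum(lab == 0) == 0)
    stop("both essential and non-essential genes must be present")
  ord <- order(fc)
  fc <- fc[ord]; lab <- lab[ord]
  cum_fdr <- cumsum(lab == 0) / seq_along(lab)
  # a threshold can only separate distinct fold-changes, so only prefixes
  # ending at a tie boundary are realisable call sets
  closed <- !duplicated(fc, fromLast = TRUE)
  ok <- which(cum_fdr <= fdr & closed)
  if (length(ok) == 0)
    return(list(threshold = unname(fc[1]) - 1e-6, fdr = fdr,
                n_reference_called = 0L, low_quality = TRUE))
  k <- max(ok)
  thr <- if (k == length(fc)) Inf else unname(fc[k + 1])
  list(threshold = thr, fdr = fdr,
       n_reference_called = sum(fc < thr), low_quality = FALSE)
}

#' Call gene dependencies per cell line at a fixed reference FDR
#'
#' For every sample (column), the fold-change threshold at which reference
#' essential genes are recovered at the target FDR is estimated with
#' [fc_threshold_at_fdr()], and every gene (reference or not) with
#' fold-change strictly below that threshold is called a dependency.
#'
#' @param gene_fc gene-level fold-change matrix (genes x cell lines).
#' @param essential,non_essential reference gene sets.
#' @param fdr target FDR (default 0.01).
#' @return Object of class `dependency_calls`: list with `calls` (logical
#'   genes x lines matrix), `thresholds`, `low_quality` (per line) and
#'   `fdr`.
#' @export
call_dependencies <- function(gene_fc, essential, non_essential, fdr = 0.01) {
  gene_fc <- as.matrix(gene_fc)
  res <- lapply(colnames(gene_fc), function(s) {
    fc_threshold_at_fdr(setNames(gene_fc[, s], rownames(gene_fc)),
                        essential, non_essential, fdr)
  })
  thr <- vapply(res, `[[`, numeric(1), "threshold")
  names(thr) <- colnames(gene_fc)
  calls <- sweep(gene_fc, 2, thr, "<")
  structure(list(calls = calls, thresholds = thr,
                 low_quality = vapply(res, `[[`, logical(1), "low_quality"),
                 fdr = fdr),
            class = "dependency_calls")
}

#' @export
print.dependency_calls <- function(x, ...) {
  cat(sprintf("dependency_calls: %d genes x %d lines at %.0f%% FDR; %s\n",
              nrow(x$calls), ncol(x$calls), 100 * x$fdr,
              paste0("median calls/line = ", median(colSums(x$calls)))))
  invisible(x)
}

#' Average precision of a fold-change ranking against reference calls
#'
#' Genes are ranked by fold-change (most negative first; ties broken by
#' gene name) and precision/recall are evaluated at every rank. The score
#' is the non-interpolated step sum `AP = sum_j (R_j - R_{j-1}) * P_j`,
#' i.e. the mean precision at the ranks of the reference genes. AP is 1
#' exactly when all reference genes precede all others.
#'
#' @param reference_calls character vector of reference dependency genes.
#' @param scores named numeric vector of gene fold-changes (more negative
#'   ranks first).
#' @return A number in \[0, 1\].
#' @export
average_precision <- function(reference_calls, scores) {
  if (length(reference_calls) == 0) stop("reference call set is empty")
  if (is.null(names(scores))) stop("`scores` must be named by gene")
  rel <- names(scores) %in% reference_calls
  n_rel <- sum(rel)
  if (n_rel == 0) stop("no reference gene present in `scores`")
  if (n_rel < length(unique(reference_calls)))
    warning("some reference genes are absent from `scores`; ",
            "recall is relative to those present")
  ord <- order(scores, names(scores))
  hit <- rel[ord]
  precision <- cumsum(hit) / seq_along(hit)
  sum(precision[hit]) / n_rel
}

#' Randomly down-sample guides per gene
#'
#' Keeps at most `n` guides per gene, sampled uniformly without
#' replacement; genes with `n` or fewer guides keep all of them. Guides
#' without a gene assignment (e.g. non-targeting) are always kept.
#' Reproducible under a fixed `seed`.
#'
#' @param x matrix with guide row names (counts or fold-changes).
#' @param guide_to_gene mapping as in [gene_level()].
#' @param n number of guides to retain per gene.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return Row-subset of `x`; attribute `selected_guides` records the
#'   selection.
#' @export
downsample_guides <- function(x, guide_to_gene, n, seed = NULL) {
  stopifnot(n >= 1)
  x <- as.matrix(x)
  map <- as_guide_map(guide_to_gene)
  gene <- unname(map[rownames(x)])
  keep <- with_seed(seed, {
    idx <- seq_len(nrow(x))
    by_gene <- split(idx, gene)    # drops NA-gene guides (kept below)
    sel <- unlist(lapply(by_gene, function(ix) {
      if (length(ix) <= n) ix else sort(sample(ix, n))
    }), use.names = FALSE)
    sort(c(sel, idx[is.na(gene)]))
  })
  out <- x[keep, , drop = FALSE]
  attr(out, "selected_guides") <- rownames(out)
  out
}

#' Restrict a screen to the guides of a designed library
#'
#' Deterministic in-silico down-sampling: the screen is reduced to the
#' guides selected in a minimal library so that the same samples can be
#' re-analysed as if screened with the reduced library.
#'
#' @param x matrix with guide row names (counts or fold-changes).
#' @param library a [select_minimal_library()] result, or a character
#'   vector of guide ids.
#' @param include_controls include the library's non-targeting controls
#'   (when `library` is a `minimal_library`).
#' @return Row-subset of `x`. Guides of the library absent from the screen
#'   trigger a warning reporting the overlap fraction.
#' @export
select_by_library <- function(x, library, include_controls = TRUE) {
  x <- as.matrix(x)
  ids <- if (inherits(library, "minimal_library")) {
    c(library$selections$guide_id,
      if (include_controls) library$nontargeting$guide_id)
  } else as.character(library)
  hit <- ids %in% rownames(x)
  if (!all(hit))
    warning(sprintf("%d/%d library guides absent from the screen (overlap %.1f%%)",
                    sum(!hit), length(ids), 100 * mean(hit)))
  if (!any(hit)) stop("no library guide present in the screen")
  x[rownames(x)[rownames(x) %in% ids], , drop = FALSE]
}

#' Per-gene discordance between two sets of dependency calls
#'
#' Counts, for every gene, the cell lines in which two analyses (e.g. full
#' vs minimal library) disagree on the dependency call. Genes discordant in
#' more than `cutoff` lines are flagged for guide replacement.
#'
#' @param calls_a,calls_b [call_dependencies()] results over the same cell
#'   lines.
#' @param cutoff flag genes discordant in more than this many lines
#'   (default 100).
#' @return data.frame with columns `gene`, `n_discordant`, `flagged`,
#'   sorted by decreasing discordance.
#' @export
discordance_counts <- function(calls_a, calls_b, cutoff = 100) {
  a <- calls_a$calls; b <- calls_b$calls
  if (!setequal(colnames(a), colnames(b)))
    stop("the two call sets cover different cell lines")
  b <- b[, colnames(a), drop = FALSE]
  genes <- union(rownames(a), rownames(b))
  pad <- function(m) {
    out <- matrix(FALSE, length(genes), ncol(m),
                  dimnames = list(genes, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  n_disc <- rowSums(pad(a) != pad(b))
  out <- data.frame(gene = genes, n_discordant = unname(n_disc),
                    flagged = unname(n_disc) > cutoff)
  out[order(-out$n_discordant, out$gene), , drop = FALSE]
}

#' Lorenz curve, Gini coefficient and decile skew of plasmid counts
#'
#' Library-cloning QC: an evenly represented plasmid pool has a Lorenz
#' curve close to the diagonal, a Gini coefficient near 0 and a decile
#' skew ratio near 1. The Gini coefficient is half the relative mean
#' absolute difference of the count distribution; the skew ratio is the
#' summed reads of the top 10% of guides (ranked by count) divided by the
#' summed reads of the bottom 10%.
#'
#' @param plasmid_counts non-negative numeric vector, not all zero.
#' @return list with `gini`, `lorenz` (data.frame `p`, `L`) and
#'   `skew_ratio` (`Inf` when the bottom decile has zero reads).
#' @export
gini_lorenz <- function(plasmid_counts) {
  x <- as.numeric(plasmid_counts)
  if (any(x < 0) || any(!is.finite(x))) stop("counts must be finite and >= 0")
  if (sum(x) == 0) stop("all plasmid counts are zero")
  n <- length(x)
  xs <- sort(x)
  gini <- 2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
  lorenz <- data.frame(p = c(0, seq_len(n) / n),
                       L = c(0, cumsum(xs) / sum(xs)))
  k <- ceiling(n / 10)
  bottom <- sum(xs[seq_len(k)])
  top <- sum(xs[seq.int(n - k + 1, n)])
  skew <- if (bottom == 0) Inf else top / bottom
  list(gini = gini, lorenz = lorenz, skew_ratio = skew)
}

#' Rank correlation of gene fold-changes between two analyses
#'
#' Spearman correlation per matched sample over the shared gene universe;
#' the headline concordance metric between a full and a reduced library.
#'
#' @param a,b gene-level fold-change matrices sharing column (sample) names.
#' @param method correlation method (default `"spearman"`).
#' @return Named numeric vector, one correlation per shared sample.
#' @export
correlate_gene_fc <- function(a, b, method = "spearman") {
  a <- as.matrix(a); b <- as.matrix(b)
  genes <- intersect(rownames(a), rownames(b))
  if (length(genes) < 3) stop("fewer than 3 shared genes")
  samples <- intersect(colnames(a), colnames(b))
  if (length(samples) == 0) stop("no shared sample")
  vapply(samples, function(s)
    cor(a[genes, s], b[genes, s], method = method), numeric(1))
}
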