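#' Assemble a pooled-screen count object
#'
#' Bundles an sgRNA read-count matrix with its sample sheet. Counts are
#' guides x samples; the sample sheet designates which columns are plasmid
#' (pDNA) controls and which cell line / replicate each screen sample
#' belongs to.
#'
#' @param counts numeric matrix of non-negative integer read counts with
#'   guide identifiers as row names and sample identifiers as column names.
#' @param samples data.frame with columns `sample_id`, `cell_line`, `role`
#'   (one of `"plasmid"` or `"screen"`) and optionally `replicate`. Every
#'   column of `counts` must appear exactly once.
#' @return An object of class `screen_counts`: a list with elements `counts`
#'   and `samples`.
#' @examples
#' cnt <- matrix(c(100L, 5L, 80L, 120L), 2,
#'               dimnames = list(c("g1", "g2"), c("pdna", "s1")))
#' sheet <- data.frame(sample_id = c("pdna", "s1"),
#'                     cell_line = c(NA, "LINE1"),
#'                     role = c("plasmid", "screen"))
#' sc <- screen_counts(cnt, sheet)
#' plasmid_samples(sc)
#' @export
screen_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have guide row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("guide identifiers must be unique")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "cell_line", "role")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id))
    stop("sample sheet must list every count column exactly once")
  if (!all(samples$role %in% c("plasmid", "screen")))
    stop("sample role must be 'plasmid' or 'screen'")
  if (!any(samples$role == "plasmid"))
    stop("no plasmid (pDNA) sample designated in the sample sheet")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d guides x %d samples (%d plasmid, %d screen)\n",
              nrow(x$counts), ncol(x$counts),
              length(plasmid_samples(x)), length(screen_samples(x))))
  invisible(x)
}

#' @rdname screen_counts
#' @param x a `screen_counts` object.
#' @export
plasmid_samples <- function(x) x$samples$sample_id[x$samples$role == "plasmid"]

#' @rdname screen_counts
#' @export
screen_samples <- function(x) x$samples$sample_id[x$samples$role == "screen"]

#' Remove guides poorly represented in the plasmid library
#'
#' Guides whose read count in the plasmid (pDNA) control is below
#' `min_count` are excluded before any normalisation: such guides were
#' under-represented in the cloned library and their fold-changes are
#' dominated by sampling noise. With several designated pDNA columns the
#' filter statistic is the mean raw count across them. Ties at exactly
#' `min_count` are retained. Row order is preserved.
#'
#' @param x a [screen_counts()] object.
#' @param min_count minimum pDNA read count to keep a guide (default 30).
#' @return A filtered `screen_counts` object. An empty result is returned
#'   with a warning, not an error.
#' @export
filter_low_plasmid <- function(x, min_count = 30) {
  stopifnot(inherits(x, "screen_counts"), min_count >= 0)
  pd <- plasmid_samples(x)
  stat <- rowMeans(x$counts[, pd, drop = FALSE])
  keep <- stat >= min_count
  if (!any(keep))
    warning("all guides fall below the plasmid count threshold")
  screen_counts_unchecked(x$counts[keep, , drop = FALSE], x$samples)
}

# internal constructor skipping validation (row subset of a valid object)
screen_counts_unchecked <- function(counts, samples) {
  structure(list(counts = counts, samples = samples), class = "screen_counts")
}

#' Reads-per-million normalisation
#'
#' Scales each sample column to reads per million:
#' `G'_i = (G_i / sum_j G_j) * 1e6`.
#'
#' @param counts numeric matrix (guides x samples) or a [screen_counts()]
#'   object.
#' @return A numeric matrix of the same shape; every column sums to 1e6.
#' @export
normalize_rpm <- function(counts) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("zero-total sample column(s): ",
         paste(colnames(m)[tot <= 0], collapse = ", "))
  sweep(m, 2, tot, "/") * 1e6
}

#' Log2 fold-changes against the plasmid reference
#'
#' Adds a pseudo-count of 1 to the whole RPM-normalised matrix and computes
#' per-guide `log2(sample + 1) - log2(plasmid + 1)`. With several plasmid
#' columns, the reference is their mean RPM profile. Plasmid columns are
#' dropped from the output.
#'
#' @param norm RPM-normalised matrix from [normalize_rpm()].
#' @param plasmid character vector of plasmid column names present in `norm`.
#' @param pseudo_count pseudo-count added to the whole matrix (default 1).
#' @return Guide-level log2 fold-change matrix (guides x screen samples)
#'   with attributes `level = "guide"`, `plasmid_reference` and
#'   `pseudo_count`.
#' @export
log_fold_changes <- function(norm, plasmid, pseudo_count = 1) {
  norm <- as.matrix(norm)
  if (length(plasmid) < 1 || !all(plasmid %in% colnames(norm)))
    stop("plasmid reference column(s) missing from the matrix")
  ref <- rowMeans(norm[, plasmid, drop = FALSE])
  scr <- setdiff(colnames(norm), plasmid)
  fc <- log2(norm[, scr, drop = FALSE] + pseudo_count) -
    log2(ref + pseudo_count)
  structure(fc, level = "guide",
            plasmid_reference = plasmid, pseudo_count = pseudo_count)
}

#' Aggregate guide fold-changes to gene level
#'
#' Gene-level fold-changes are the unweighted mean of the fold-changes of
#' all guides targeting the gene, per sample. Guides without a gene
#' assignment (e.g. non-targeting controls) are dropped from aggregation.
#'
#' @param fc guide-level fold-change matrix (guides x samples).
#' @param guide_to_gene named character vector mapping guide id to gene
#'   symbol, or a data.frame with columns `guide_id` and `gene`.
#' @return Gene-level matrix (genes x samples), attribute `level = "gene"`.
#' @export
gene_level <- function(fc, guide_to_gene) {
  fc <- as.matrix(fc)
  map <- as_guide_map(guide_to_gene)
  gene <- unname(map[rownames(fc)])
  keep <- !is.na(gene) & gene != ""
  fc <- fc[keep, , drop = FALSE]
  gene <- gene[keep]
  if (nrow(fc) == 0) stop("no guide maps to a gene")
  out <- rowsum(fc, gene) / as.vector(table(gene)[sort(unique(gene))])
  out <- out[sort(unique(gene)), , drop = FALSE]
  structure(out, level = "gene")
}

as_guide_map <- function(guide_to_gene) {
  if (is.data.frame(guide_to_gene)) {
    if (anyDuplicated(guide_to_gene$guide_id)) {
      conf <- unique(guide_to_gene[, c("guide_id", "gene")])
      if (anyDuplicated(conf$guide_id))
        stop("guide(s) mapped to conflicting genes: ",
             paste(unique(conf$guide_id[duplicated(conf$guide_id)]),
                   collapse = ", "))
      guide_to_gene <- conf
    }
    setNames(as.character(guide_to_gene$gene), guide_to_gene$guide_id)
  } else {
    if (is.null(names(guide_to_gene)))
      stop("`guide_to_gene` must be named by guide id")
    guide_to_gene
  }
}

#' Average technical replicates of the same cell line
#'
#' @param fc fold-change matrix (guide or gene level), samples as columns.
#' @param sample_to_cell_line named character vector mapping sample id to
#'   cell line, or a data.frame with columns `sample_id` and `cell_line`.
#' @return Matrix with one column per cell line (mean over its replicates),
#'   columns in sorted cell-line order; `level` attribute preserved.
#' @export
average_replicates <- function(fc, sample_to_cell_line) {
  fc <- as.matrix(fc)
  if (is.data.frame(sample_to_cell_line))
    sample_to_cell_line <- setNames(as.character(sample_to_cell_line$cell_line),
                                    sample_to_cell_line$sample_id)
  cl <- unname(sample_to_cell_line[colnames(fc)])
  if (anyNA(cl))
    stop("sample(s) missing from the cell-line mapping: ",
         paste(colnames(fc)[is.na(cl)], collapse = ", "))
  out <- t(rowsum(t(fc), cl) / as.vector(table(cl)[sort(unique(cl))]))
  structure(out[, sort(unique(cl)), drop = FALSE],
            level = attr(fc, "level", exact = TRUE))
}
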