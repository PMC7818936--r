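#' Per-sample median fold-change of non-targeting guides
#'
#' The comparison sample for KS-based efficacy scoring: for every screen
#' sample, the median log2 fold-change over all non-targeting guides. Since
#' Cas9-induced double-strand breaks carry a small fitness cost that
#' non-targeting guides escape, these medians sit slightly above zero and
#' form the empirical "no on-target activity" baseline.
#'
#' @param fc guide-level fold-change matrix (guides x samples).
#' @param non_targeting character vector of non-targeting guide ids.
#' @return Named numeric vector, one median per sample.
#' @export
nontargeting_reference <- function(fc, non_targeting) {
  fc <- as.matrix(fc)
  nt <- intersect(non_targeting, rownames(fc))
  if (length(nt) == 0)
    stop("no non-targeting guide present in the fold-change matrix; ",
         "KS scoring is impossible")
  apply(fc[nt, , drop = FALSE], 2, median)
}

#' Two-sample Kolmogorov-Smirnov D statistic
#'
#' The empirical guide-efficacy score: the maximum absolute difference
#' between the empirical CDFs of a guide's fold-changes across samples and
#' of the per-sample non-targeting medians. Values near 0 mean the guide
#' behaves like a non-targeting control (little or no on-target activity);
#' values near 1 mean a strongly shifted fold-change distribution. The
#' statistic is symmetric in its arguments and lies in \[0, 1\].
#'
#' @param x,y numeric vectors (both non-empty, finite).
#' @return The D statistic, a number in \[0, 1\].
#' @seealso [ks_scores_all()] for scoring a whole screen,
#'   [ks_pvalue_asymptotic()] for the accompanying (unused for ranking)
#'   p-value.
#' @export
ks_score <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  ord <- order(pooled)
  # +1/n at each x point, -1/m at each y point; D is the max |partial sum|,
  # evaluated after absorbing ties (identical pooled values step together).
  steps <- c(rep(1 / n, n), rep(-1 / m, m))[ord]
  csum <- cumsum(steps)
  v <- pooled[ord]
  at_tie_end <- c(v[-1] != v[-length(v)], TRUE)
  max(abs(csum[at_tie_end]))
}

#' Asymptotic two-sample KS p-value
#'
#' Kolmogorov's limiting distribution
#' `Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)` evaluated at
#' `lambda = sqrt(n*m/(n+m)) * d`. No exact small-sample correction: the
#' score, not significance, drives guide ranking.
#'
#' @param d KS D statistic.
#' @param n,m the two sample sizes.
#' @return p-value in \[0, 1\].
#' @export
ks_pvalue_asymptotic <- function(d, n, m) {
  lambda <- sqrt(n * m / (n + m)) * d
  if (lambda < 1e-9) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' KS efficacy scores for every guide in a screen
#'
#' Applies [ks_score()] per guide against the per-sample non-targeting
#' median reference (default), or against the pooled vector of all
#' non-targeting fold-changes when `pool_reference = TRUE`. Non-targeting
#' guides are scored too (useful for QC) and flagged. Guides that fail to
#' score (e.g. no finite value) are reported with `NA`, not an error.
#'
#' @param fc guide-level, per-sample (unaveraged) fold-change matrix.
#' @param non_targeting character vector of non-targeting guide ids.
#' @param pool_reference compare against the pooled non-targeting values
#'   instead of their per-sample medians.
#' @return data.frame with columns `guide_id`, `ks_score`, `ks_pvalue`,
#'   `n_samples_used`, `is_nontargeting`.
#' @export
ks_scores_all <- function(fc, non_targeting, pool_reference = FALSE) {
  fc <- as.matrix(fc)
  nt <- intersect(non_targeting, rownames(fc))
  ref <- if (pool_reference) {
    if (length(nt) == 0) stop("no non-targeting guide present")
    as.vector(fc[nt, , drop = FALSE])
  } else nontargeting_reference(fc, non_targeting)
  m <- length(ref)
  res <- lapply(rownames(fc), function(g) {
    v <- fc[g, ]
    v <- v[is.finite(v)]
    d <- tryCatch(ks_score(v, ref), error = function(e) NA_real_)
    data.frame(guide_id = g, ks_score = d,
               ks_pvalue = if (is.na(d)) NA_real_ else
                 ks_pvalue_asymptotic(d, length(v), m),
               n_samples_used = length(v))
  })
  out <- do.call(rbind, res)
  out$is_nontargeting <- out$guide_id %in% non_targeting
  rownames(out) <- NULL
  out
}

#' Is a JACKS score within the accepted range?
#'
#' JACKS estimates per-guide efficacy relative to the gene mean; values far
#' from 1 indicate outlier guides. The design filter keeps guides with
#' JACKS in `[low, high]` (endpoints inclusive, default \[0, 2\]). A missing
#' value returns `FALSE` (it disqualifies a guide from the green tier but
#' not from amber/red, where no efficacy filter applies).
#'
#' @param jacks numeric vector (may contain `NA`).
#' @param low,high inclusive range ends (defaults 0 and 2).
#' @return logical vector.
#' @export
jacks_in_range <- function(jacks, low = 0, high = 2) {
  !is.na(jacks) & jacks >= low & jacks <= high
}

#' Annotate poly-T stretches in spacer sequences
#'
#' Runs of >= 4 consecutive thymines can terminate Pol III transcription
#' from the U6 promoter, so spacers containing them are flagged (the PAM is
#' not part of the input). The reported position is the distance of the
#' PAM-proximal end of the longest T run from the 3' end of the spacer
#' (0 = adjacent to the PAM); when several runs share the maximum length,
#' the most PAM-proximal one is reported.
#'
#' @param spacer character vector of spacer sequences over \{A, C, G, T\}.
#' @return data.frame with columns `spacer`, `max_t_stretch`,
#'   `position_from_pam` (`NA` when the spacer has no T) and `flag_4plus`.
#' @export
annotate_poly_t <- function(spacer) {
  spacer <- toupper(spacer)
  if (any(grepl("[^ACGT]", spacer)))
    stop("spacer sequences must contain only A, C, G, T")
  one <- function(s) {
    r <- rle(strsplit(s, "")[[1]] == "T")
    if (!any(r$values)) return(c(0L, NA_integer_))
    lens <- r$lengths[r$values]
    mx <- max(lens)
    ends <- cumsum(r$lengths)[r$values]       # 1-based 5'->3' end of each run
    end3 <- max(ends[lens == mx])             # most PAM-proximal maximal run
    c(mx, nchar(s) - end3)
  }
  ann <- t(vapply(spacer, one, integer(2)))
  data.frame(spacer = spacer,
             max_t_stretch = ann[, 1],
             position_from_pam = ann[, 2],
             flag_4plus = ann[, 1] >= 4L,
             row.names = NULL)
}
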