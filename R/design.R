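#' Selection configuration for minimal-library design
#'
#' Collects every tunable of the tiered selection procedure. Defaults
#' reproduce the standard design: 2 guides per gene; source precedence
#' Project Score > Avana > Brunello > TKOv3; green tier requiring a single
#' perfect genome alignment, no 1-mismatch alignment and an efficacy filter
#' (JACKS in \[0, 2\] for Project Score / Avana, Rule Set 2 > 0.4 for
#' Brunello, none for TKOv3); amber requiring only a single perfect
#' alignment; red allowing up to 3 perfect alignments; ranking by KS score
#' (Project Score, Avana), Rule Set 2 (Brunello) or input order (TKOv3);
#' and 200 non-targeting controls.
#'
#' @param guides_per_gene guides to select per gene (default 2).
#' @param source_precedence character vector, highest priority first.
#' @param jacks_range inclusive JACKS acceptance range (default `c(0, 2)`).
#' @param rule_set2_min strict lower bound on Rule Set 2 for the green tier
#'   of sequence-score-ranked sources (default 0.4).
#' @param red_max_perfect maximum number of perfect genome alignments
#'   admitted at the red tier (default 3).
#' @param ranking named list mapping source to ranking metric
#'   (`"ks"`, `"rule_set2"` or `"input_order"`).
#' @param efficacy_filter named list mapping source to the green-tier
#'   efficacy filter (`"jacks"`, `"rule_set2"` or `"none"`).
#' @param forced_exclusions named list: gene -> character vector of sources
#'   that must not be used for that gene.
#' @param n_nontargeting number of non-targeting controls (default 200).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(guides_per_gene = 2,
                             source_precedence = c("ProjectScore", "Avana",
                                                   "Brunello", "TKOv3"),
                             jacks_range = c(0, 2),
                             rule_set2_min = 0.4,
                             red_max_perfect = 3,
                             ranking = list(ProjectScore = "ks",
                                            Avana = "ks",
                                            Brunello = "rule_set2",
                                            TKOv3 = "input_order"),
                             efficacy_filter = list(ProjectScore = "jacks",
                                                    Avana = "jacks",
                                                    Brunello = "rule_set2",
                                                    TKOv3 = "none"),
                             forced_exclusions = list(),
                             n_nontargeting = 200) {
  stopifnot(guides_per_gene >= 1, length(jacks_range) == 2,
            jacks_range[1] <= jacks_range[2], red_max_perfect >= 1)
  structure(list(guides_per_gene = as.integer(guides_per_gene),
                 source_precedence = source_precedence,
                 jacks_range = jacks_range,
                 rule_set2_min = rule_set2_min,
                 red_max_perfect = as.integer(red_max_perfect),
                 ranking = ranking,
                 efficacy_filter = efficacy_filter,
                 forced_exclusions = forced_exclusions,
                 n_nontargeting = as.integer(n_nontargeting)),
            class = "selection_config")
}

check_guide_records <- function(records) {
  req <- c("guide_id", "sequence", "gene", "library",
           "n_perfect", "n_1mm", "n_2mm")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("guide record table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(records)
}

#' Drop guides without a genome position or gene annotation
#'
#' Guides that could not be placed on the reference genome build, or that
#' target no annotated gene, cannot be tiered and are removed up front.
#' A guide is considered unmapped when its `chromosome`/`start` fields are
#' missing (if present in the table) or when `n_perfect` is `NA`.
#'
#' @param records guide record data.frame (see [select_minimal_library()]).
#' @return Filtered data.frame; attribute `removed` logs the removals with
#'   a reason.
#' @export
exclude_unmapped <- function(records) {
  check_guide_records(records)
  no_gene <- is.na(records$gene) | records$gene == ""
  unmapped <- is.na(records$n_perfect)
  if ("chromosome" %in% names(records))
    unmapped <- unmapped | is.na(records$chromosome)
  drop <- no_gene | unmapped
  removed <- data.frame(guide_id = records$guide_id[drop],
                        reason = ifelse(no_gene[drop], "no_gene", "unmapped"))
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Drop spacers with conflicting gene annotation across source libraries
#'
#' The same spacer sequence occasionally appears in several source
#' libraries annotated to different genes; such guides are discarded from
#' all sources. Spacers duplicated with a consistent gene are collapsed to
#' a single record (the highest-precedence source), with the other sources
#' kept in an `also_in` provenance column.
#'
#' @param records guide record data.frame.
#' @param source_precedence ordering used to pick the surviving duplicate.
#' @return Filtered data.frame; attribute `removed` logs dropped guides.
#' @export
exclude_conflicting <- function(records,
                                source_precedence = c("ProjectScore", "Avana",
                                                      "Brunello", "TKOv3")) {
  check_guide_records(records)
  dt <- data.table::as.data.table(records)
  dt[, sequence := toupper(sequence)]
  dt[, n_genes := data.table::uniqueN(gene), by = sequence]
  conflict <- dt$n_genes > 1
  removed <- data.frame(guide_id = dt$guide_id[conflict],
                        reason = rep("conflicting_gene", sum(conflict)))
  dt <- dt[!conflict]
  src_rank <- match(dt$library, source_precedence)
  src_rank[is.na(src_rank)] <- length(source_precedence) + 1L
  dt[, src_rank := src_rank]
  data.table::setorder(dt, sequence, src_rank, guide_id)
  dt[, also_in := if (.N > 1) paste(library[-1], collapse = ";") else
    NA_character_, by = sequence]
  dt <- dt[!duplicated(sequence)]
  dt[, c("n_genes", "src_rank") := NULL]
  out <- as.data.frame(dt)
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

# green-tier efficacy predicate per record, driven by config$efficacy_filter
efficacy_ok <- function(records, config) {
  filt <- vapply(records$library, function(s)
    config$efficacy_filter[[s]] %||% "none", character(1))
  ok <- rep(TRUE, nrow(records))
  j <- filt == "jacks"
  ok[j] <- jacks_in_range(records$jacks[j],
                          config$jacks_range[1], config$jacks_range[2])
  r <- filt == "rule_set2"
  ok[r] <- !is.na(records$rule_set2[r]) &
    records$rule_set2[r] > config$rule_set2_min
  ok
}

#' Assign the off-target/efficacy stringency tier of each guide
#'
#' Tiers, from most to least stringent:
#' * **green** — single perfect genome match, no 1-mismatch alignment, and
#'   the source's efficacy filter passes (JACKS within range for Project
#'   Score/Avana, Rule Set 2 above threshold for Brunello, no filter for
#'   TKOv3);
#' * **amber** — single perfect alignment, no efficacy filter;
#' * **red** — up to `red_max_perfect` (default 3) perfect alignments, no
#'   efficacy filter;
#' * **ineligible** — anything else (including guides with missing
#'   off-target counts).
#'
#' A guide's tier is the most stringent level it satisfies.
#'
#' @param records guide record data.frame.
#' @param config a [selection_config()].
#' @return factor with levels `green`, `amber`, `red`, `ineligible`.
#' @export
assign_tier <- function(records, config = selection_config()) {
  check_guide_records(records)
  np <- records$n_perfect; n1 <- records$n_1mm
  known <- !is.na(np)
  green <- known & np == 1 & !is.na(n1) & n1 == 0 & efficacy_ok(records, config)
  amber <- known & np == 1
  red <- known & np >= 1 & np <= config$red_max_perfect
  tier <- rep("ineligible", nrow(records))
  tier[red] <- "red"
  tier[amber] <- "amber"
  tier[green] <- "green"
  factor(tier, levels = c("green", "amber", "red", "ineligible"))
}

# per-record ranking metric value; larger is better; NA ranks last
ranking_metric <- function(records, config) {
  metric_name <- vapply(records$library, function(s)
    config$ranking[[s]] %||% "input_order", character(1))
  val <- rep(NA_real_, nrow(records))
  val[metric_name == "ks"] <- records$ks[metric_name == "ks"]
  val[metric_name == "rule_set2"] <-
    records$rule_set2[metric_name == "rule_set2"]
  io <- metric_name == "input_order"
  val[io] <- -seq_len(nrow(records))[io]
  list(name = metric_name, value = val)
}

#' Rank the guides of one gene within one source library
#'
#' Descending KS score (Project Score, Avana), descending Rule Set 2
#' (Brunello) or input order (TKOv3); ties and missing metrics are broken
#' deterministically by guide id, with missing metrics ranked last (and a
#' warning).
#'
#' @param records guide records of a single gene and source.
#' @param config a [selection_config()].
#' @return `records` reordered.
#' @export
rank_within_source <- function(records, config = selection_config()) {
  m <- ranking_metric(records, config)
  if (anyNA(m$value))
    warning("guide(s) without ranking metric ranked last: ",
            paste(records$guide_id[is.na(m$value)], collapse = ", "))
  key <- ifelse(is.na(m$value), -Inf, m$value)
  out <- records[order(-key, records$guide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a minimal library by tiered, source-prioritised selection
#'
#' For every gene, selection slots (default 2) are filled by looping over
#' stringency tiers (green, then amber, then red) and, within a tier, over
#' source libraries in precedence order, taking the top-ranked eligible
#' guides of each source until the quota is reached. A spacer sequence is
#' never selected twice for a gene; genes listed in
#' `config$forced_exclusions` skip the blacklisted sources; genes that end
#' short of the quota are reported in `genes_with_shortfall`.
#'
#' The required columns of `records` are `guide_id`, `sequence`, `gene`,
#' `library`, `n_perfect`, `n_1mm`, `n_2mm`, plus the efficacy metrics the
#' configuration refers to (`ks`, `jacks`, `rule_set2`). Records should
#' already be cleaned with [exclude_unmapped()] and [exclude_conflicting()].
#'
#' @param records guide record data.frame.
#' @param config a [selection_config()].
#' @param gene_universe optional character vector of genes that must be
#'   covered (e.g. all protein-coding genes); genes with no eligible guide
#'   then appear in the shortfall list.
#' @return Object of class `minimal_library`: list with `selections`
#'   (data.frame gene, guide_id, sequence, source, tier, metric,
#'   metric_value, rank_in_source), `nontargeting` (filled by
#'   [select_nontargeting()]), `genes_with_shortfall` and `config`.
#' @export
select_minimal_library <- function(records, config = selection_config(),
                                   gene_universe = NULL) {
  check_guide_records(records)
  if (nrow(records) == 0) stop("empty guide reference")
  keep_src <- records$library %in% config$source_precedence
  records <- records[keep_src, , drop = FALSE]
  m <- ranking_metric(records, config)
  dt <- data.table::data.table(
    gene = records$gene,
    guide_id = records$guide_id,
    sequence = toupper(records$sequence),
    source = records$library,
    tier = assign_tier(records, config),
    metric = m$name,
    metric_value = m$value,
    sort_key = ifelse(is.na(m$value), -Inf, m$value))
  if (length(config$forced_exclusions)) {
    excl <- data.table::data.table(
      gene = rep(names(config$forced_exclusions),
                 lengths(config$forced_exclusions)),
      source = unlist(config$forced_exclusions, use.names = FALSE))
    dt <- dt[!excl, on = c("gene", "source")]
  }
  dt <- dt[tier != "ineligible"]
  dt[, tier_rank := as.integer(tier)]
  dt[, src_rank := match(source, config$source_precedence)]
  data.table::setorder(dt, gene, tier_rank, src_rank, -sort_key, guide_id)
  dt[, rank_in_source := seq_len(.N), by = .(gene, tier_rank, source)]
  dt <- dt[!duplicated(sequence), , ]           # no spacer selected twice
  sel <- dt[, head(.SD, config$guides_per_gene), by = gene]
  sel[, tier := as.character(tier)]
  selections <- as.data.frame(
    sel[, .(gene, guide_id, sequence, source, tier, metric, metric_value,
            rank_in_source)])
  universe <- union(gene_universe %||% character(0), unique(records$gene))
  got <- table(factor(selections$gene, levels = sort(universe)))
  shortfall <- names(got)[got < config$guides_per_gene]
  structure(list(selections = selections,
                 nontargeting = data.frame(guide_id = character(0),
                                           sequence = character(0),
                                           distance = numeric(0)),
                 genes_with_shortfall = shortfall,
                 config = config),
            class = "minimal_library")
}

#' @export
print.minimal_library <- function(x, ...) {
  cat(sprintf(paste0("minimal_library: %d guides over %d genes ",
                     "(%s), %d non-targeting controls, %d gene(s) short\n"),
              nrow(x$selections), length(unique(x$selections$gene)),
              paste(sprintf("%d %s", as.vector(table(x$selections$tier)),
                            names(table(x$selections$tier))), collapse = ", "),
              nrow(x$nontargeting), length(x$genes_with_shortfall)))
  invisible(x)
}

#' Select non-targeting control guides
#'
#' Controls are first filtered to guides with no perfect alignment, no
#' 1-mismatch alignment and at most three 2-mismatch alignments to the
#' genome build, then ranked by similarity of their fold-change profile to
#' the per-sample median profile of all non-targeting guides (mean
#' absolute deviation across samples), and the closest `n` are kept.
#'
#' @param controls guide record data.frame of candidate non-targeting
#'   guides (columns `guide_id`, `sequence`, `n_perfect`, `n_1mm`,
#'   `n_2mm`).
#' @param fc guide-level fold-change matrix containing the controls.
#' @param n number of controls to select (default 200).
#' @param max_2mm maximum 2-mismatch alignments allowed (default 3).
#' @return data.frame `guide_id`, `sequence`, `distance`, best first. If
#'   fewer than `n` controls survive the filter, all are returned with a
#'   warning.
#' @export
select_nontargeting <- function(controls, fc, n = 200, max_2mm = 3) {
  fc <- as.matrix(fc)
  ok <- !is.na(controls$n_perfect) & controls$n_perfect == 0 &
    !is.na(controls$n_1mm) & controls$n_1mm == 0 &
    !is.na(controls$n_2mm) & controls$n_2mm <= max_2mm
  pool <- controls[ok & controls$guide_id %in% rownames(fc), , drop = FALSE]
  if (nrow(pool) == 0) stop("no eligible non-targeting control")
  ref <- nontargeting_reference(fc, controls$guide_id)
  d <- rowMeans(abs(sweep(fc[pool$guide_id, , drop = FALSE], 2, ref)))
  ord <- order(d, pool$guide_id)
  out <- data.frame(guide_id = pool$guide_id[ord],
                    sequence = pool$sequence[ord],
                    distance = unname(d[ord]))
  if (nrow(out) < n)
    warning(sprintf("only %d of the requested %d controls pass the filter",
                    nrow(out), n))
  head(out, n)
}

#' Re-select guides for discordant genes with a source blacklisted
#'
#' Genes whose dependency calls disagree between the full and the minimal
#' library in many cell lines usually carry source-specific off-target
#' guide pairs; their selection is repeated with the offending source
#' excluded and the replacements are spliced into the library.
#'
#' @param library a [select_minimal_library()] result.
#' @param discordant_genes character vector (e.g. flagged genes from
#'   [discordance_counts()]).
#' @param records the guide reference used for the original selection.
#' @param config the original [selection_config()].
#' @param exclude_source source to blacklist for those genes
#'   (default `"ProjectScore"`).
#' @return Updated `minimal_library`; replaced selections carry
#'   `replaced = TRUE`.
#' @export
replace_discordant <- function(library, discordant_genes, records,
                               config = library$config,
                               exclude_source = "ProjectScore") {
  if (length(discordant_genes) == 0) return(library)
  cfg <- config
  cfg$forced_exclusions <- modifyList(
    cfg$forced_exclusions,
    setNames(rep(list(exclude_source), length(discordant_genes)),
             discordant_genes))
  redo <- select_minimal_library(
    records[records$gene %in% discordant_genes, , drop = FALSE], cfg)
  old <- library$selections
  old$replaced <- FALSE
  new <- redo$selections
  if (nrow(new)) new$replaced <- TRUE
  library$selections <-
    rbind(old[!old$gene %in% discordant_genes, , drop = FALSE], new)
  library$selections <- library$selections[
    order(library$selections$gene, library$selections$guide_id), , drop = FALSE]
  rownames(library$selections) <- NULL
  library$genes_with_shortfall <-
    union(setdiff(library$genes_with_shortfall, discordant_genes),
          redo$genes_with_shortfall)
  library$config$forced_exclusions <- cfg$forced_exclusions
  library
}
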