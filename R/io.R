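#' Read an sgRNA count matrix
#'
#' Tab- or comma-separated (auto-detected), header row of sample ids,
#' first column guide ids; gzip transparently supported.
#'
#' @param path file path.
#' @return numeric matrix with guide row names.
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "numeric"
  m
}

#' Read a sample sheet
#'
#' TSV/CSV with columns `sample_id`, `cell_line`, `role`
#' (`plasmid`/`screen`) and optionally `replicate`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE,
                                  colClasses = list(character = "sample_id")))
}

#' Read a guide reference library table
#'
#' TSV/CSV with at least `guide_id`, `sequence`, `gene`, `library`,
#' `n_perfect`, `n_1mm`, `n_2mm`; efficacy metric columns (`ks`, `jacks`,
#' `rule_set2`) and coordinates are optional.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_guide_library <- function(path) {
  check_guide_records(as.data.frame(data.table::fread(path, header = TRUE)))
}

#' Read essential / non-essential gene sets
#'
#' TSV/CSV with columns `gene` and `set` (values `essential` /
#' `non_essential`).
#'
#' @param path file path.
#' @return list with `essential` and `non_essential` character vectors.
#' @export
read_gene_sets <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!all(c("gene", "set") %in% names(df)))
    stop("gene set file needs columns `gene` and `set`")
  ess <- df$gene[df$set == "essential"]
  non <- df$gene[df$set == "non_essential"]
  if (length(intersect(ess, non)))
    stop("gene(s) in both the essential and non-essential set")
  list(essential = ess, non_essential = non)
}

#' Write a fold-change matrix with provenance header
#'
#' Tab-separated, guides/genes as rows; a `#`-prefixed header comment
#' records the plasmid reference and pseudo-count.
#'
#' @param fc fold-change matrix from [log_fold_changes()] or
#'   [gene_level()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(fc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# level=%s plasmid_reference=%s pseudo_count=%s",
                     attr(fc, "level") %||% "guide",
                     paste(attr(fc, "plasmid_reference") %||% "NA",
                           collapse = ","),
                     attr(fc, "pseudo_count") %||% "NA"), con)
  writeLines(paste(c("id", colnames(fc)), collapse = "\t"), con)
  utils::write.table(format(fc, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a minimal library and its provenance sidecar
#'
#' The selections go to `<path>` as TSV (`gene`, `guide_id`, `sequence`,
#' `source`, `tier`, ...); non-targeting controls, shortfall genes and the
#' resolved configuration go to `<path>.provenance.json`.
#'
#' @param library a [select_minimal_library()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_minimal_library <- function(library, path) {
  stopifnot(inherits(library, "minimal_library"))
  data.table::fwrite(library$selections, path, sep = "\t")
  jsonlite::write_json(
    list(nontargeting = library$nontargeting,
         genes_with_shortfall = library$genes_with_shortfall,
         config = unclass(library$config),
         tier_counts = as.list(table(library$selections$tier))),
    paste0(path, ".provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a guide efficacy table
#'
#' @param efficacy data.frame from [ks_scores_all()], optionally joined
#'   with external metrics.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_efficacy_table <- function(efficacy, path) {
  data.table::fwrite(efficacy, path, sep = "\t")
  invisible(path)
}
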