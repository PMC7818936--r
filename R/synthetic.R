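#' Configuration of the synthetic screen generator
#'
#' Defines the generative model used to test the pipeline end to end:
#' a multi-source guide reference with planted off-target strata and
#' efficiency classes, log-normal plasmid abundances, and
#' negative-binomial read counts whose expectation is the plasmid
#' abundance scaled by `2^(fitness effect)`.
#'
#' Defaults encode the study conditions the pipeline targets: one third of
#' genes essential with a mean knockout effect of -3 (log2 fold-change
#' units per fully efficient guide); non-essential genes at 0;
#' non-targeting guides with a small uniform growth advantage of +0.3
#' (the fitness cost of Cas9-induced double-strand breaks that they
#' escape); 20% of guides inefficient (efficiency near 0); occasional
#' off-target outlier guides that inherit the fitness effect of an
#' unrelated gene; negative-binomial dispersion 0.2 and a mean sequencing
#' depth of 500 reads per guide.
#'
#' @param n_genes number of protein-coding genes (default 100).
#' @param guides_per_gene named integer vector: guides per gene per source
#'   library (default ProjectScore 5, Avana 4, Brunello 4, TKOv3 4).
#' @param fraction_essential fraction of genes with a fitness effect
#'   (default 1/3).
#' @param essential_effect mean log2 fold-change of a fully efficient guide
#'   of an essential gene (default -3).
#' @param nontargeting_delta uniform positive fitness offset of
#'   non-targeting guides (default +0.3).
#' @param n_nontargeting non-targeting guides in the reference
#'   (default 300).
#' @param n_cell_lines,replicates screened cell lines and technical
#'   replicates per line (defaults 20 and 3): KS efficacy
#'   scoring compares empirical CDFs across samples, so its resolution is
#'   `1 / n_samples`; tens of replicate-level samples are the intended
#'   operating regime of the score.
#' @param fraction_inefficient fraction of gene-targeting guides with
#'   efficiency near 0 (default 0.2).
#' @param fraction_offtarget fraction of guides acting on a random other
#'   gene (default 0.02).
#' @param efficiency_efficient,efficiency_inefficient uniform ranges the
#'   efficiency of the two classes is drawn from.
#' @param offtarget_strata named probabilities of the off-target strata a
#'   guide's alignment summary is drawn from (`green`: 1 perfect / 0
#'   1-mismatch; `amber`: 1 perfect, some 1-mismatch; `red`: 2-3 perfect;
#'   `ineligible`: 0 or >3 perfect).
#' @param polyt_rate fraction of spacers with a planted TTTT stretch.
#' @param plasmid_sdlog sd(log) of the log-normal plasmid abundances.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`; default 0.2).
#' @param depth mean reads per guide per sample (default 500).
#' @param n_plasmid plasmid (pDNA) sample columns (default 1).
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 100,
                              guides_per_gene = c(ProjectScore = 5, Avana = 4,
                                                  Brunello = 4, TKOv3 = 4),
                              fraction_essential = 1 / 3,
                              essential_effect = -3,
                              nontargeting_delta = 0.3,
                              n_nontargeting = 300,
                              n_cell_lines = 20,
                              replicates = 3,
                              fraction_inefficient = 0.2,
                              fraction_offtarget = 0.02,
                              efficiency_efficient = c(0.85, 1),
                              efficiency_inefficient = c(0, 0.1),
                              offtarget_strata = c(green = 0.85, amber = 0.08,
                                                   red = 0.05,
                                                   ineligible = 0.02),
                              polyt_rate = 0.05,
                              plasmid_sdlog = 0.5,
                              nb_dispersion = 0.2,
                              depth = 500,
                              n_plasmid = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              guides_per_gene = guides_per_gene,
              fraction_essential = fraction_essential,
              essential_effect = essential_effect,
              nontargeting_delta = nontargeting_delta,
              n_nontargeting = as.integer(n_nontargeting),
              n_cell_lines = as.integer(n_cell_lines),
              replicates = as.integer(replicates),
              fraction_inefficient = fraction_inefficient,
              fraction_offtarget = fraction_offtarget,
              efficiency_efficient = efficiency_efficient,
              efficiency_inefficient = efficiency_inefficient,
              offtarget_strata = offtarget_strata / sum(offtarget_strata),
              polyt_rate = polyt_rate,
              plasmid_sdlog = plasmid_sdlog,
              nb_dispersion = nb_dispersion,
              depth = depth,
              n_plasmid = as.integer(n_plasmid))
  fr <- c(cfg$fraction_essential, cfg$fraction_inefficient,
          cfg$fraction_offtarget, cfg$polyt_rate)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$depth > 0, cfg$nb_dispersion >= 0,
            cfg$n_genes >= 1, all(cfg$guides_per_gene >= 0))
  structure(cfg, class = "sim_config")
}

random_spacer <- function(n, len = 19, polyt = logical(n)) {
  s <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G"), len, replace = TRUE), collapse = ""),
    character(1))
  # overwrite a random window with TTTT in flagged spacers; elsewhere the
  # alphabet excludes T so the planted run is the only (and longest) one
  if (any(polyt)) {
    pos <- sample.int(len - 3L, sum(polyt), replace = TRUE)
    s[polyt] <- vapply(seq_along(pos), function(i) {
      x <- s[polyt][i]
      paste0(substr(x, 1, pos[i] - 1), "TTTT", substr(x, pos[i] + 4, len))
    }, character(1))
  }
  s
}

#' Simulate a multi-source guide reference with ground truth
#'
#' Emits a guide-record table in the dialect [select_minimal_library()]
#' consumes, together with the generative ground truth. Off-target
#' alignment summaries are drawn from configurable strata so that known
#' fractions of guides are green/amber/red/ineligible; JACKS values are
#' centred on 1 with planted out-of-range outliers for off-target guides;
#' Rule Set 2 is uniform; a `ks` column provides a synthetic efficacy
#' ranking (monotone in the planted efficiency, with noise) so the design
#' module can run without screens — the full pipeline replaces it with
#' [ks_scores_all()] output.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `records` (guide table including non-targeting
#'   controls, `library = "Control"`), and `truth` (list `genes`:
#'   gene/essential/effect; `guides`: class, efficiency, effective gene).
#' @export
simulate_reference <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    essential <- rbinom(config$n_genes, 1, config$fraction_essential) == 1
    effect <- ifelse(essential, config$essential_effect, 0)
    src <- rep(names(config$guides_per_gene), config$guides_per_gene)
    n_per_gene <- length(src)
    gene_col <- rep(genes, each = n_per_gene)
    source_col <- rep(src, times = config$n_genes)
    n <- length(gene_col)
    guide_id <- sprintf("%s_%s_%02d", gene_col, source_col,
                        as.vector(replicate(config$n_genes,
                                            stats::ave(seq_len(n_per_gene),
                                                       src, FUN = seq_along))))
    cls <- sample(c("efficient", "inefficient", "offtarget"), n, replace = TRUE,
                  prob = c(1 - config$fraction_inefficient -
                             config$fraction_offtarget,
                           config$fraction_inefficient,
                           config$fraction_offtarget))
    eff <- ifelse(cls == "inefficient",
                  runif(n, config$efficiency_inefficient[1],
                        config$efficiency_inefficient[2]),
                  runif(n, config$efficiency_efficient[1],
                        config$efficiency_efficient[2]))
    donor <- ifelse(cls == "offtarget", sample(genes, n, replace = TRUE),
                    gene_col)
    stratum <- sample(names(config$offtarget_strata), n, replace = TRUE,
                      prob = config$offtarget_strata)
    n_perfect <- ifelse(stratum == "green" | stratum == "amber", 1L,
                        ifelse(stratum == "red", sample(2:3, n, TRUE),
                               sample(c(0L, 4:6), n, TRUE)))
    n_1mm <- ifelse(stratum == "amber", 1L + stats::rpois(n, 2), 0L)
    n_2mm <- stats::rpois(n, 1)
    jacks <- rnorm(n, 1, 0.3)
    jacks[cls == "offtarget"] <- rnorm(sum(cls == "offtarget"), 3, 0.5)
    jacks[source_col %in% c("Brunello", "TKOv3")] <- NA_real_
    rule_set2 <- round(runif(n), 4)
    rule_set2[source_col %in% c("TKOv3")] <- NA_real_
    ks_synth <- pmin(1, pmax(0, eff * 0.8 + rnorm(n, 0, 0.08)))
    ks_synth[!source_col %in% c("ProjectScore", "Avana")] <- NA_real_
    polyt <- runif(n) < config$polyt_rate
    records <- data.frame(
      guide_id = guide_id,
      sequence = random_spacer(n, polyt = polyt),
      gene = gene_col,
      library = source_col,
      chromosome = sprintf("chr%d", 1 + (match(gene_col, genes) %% 22)),
      start = 1000L + 100L * seq_len(n),
      end = 1018L + 100L * seq_len(n),
      strand = sample(c("+", "-"), n, TRUE),
      n_perfect = n_perfect, n_1mm = n_1mm, n_2mm = n_2mm,
      jacks = round(jacks, 4), rule_set2 = rule_set2,
      ks = round(ks_synth, 4))
    nt_n <- config$n_nontargeting
    controls <- if (nt_n == 0) NULL else data.frame(
      guide_id = sprintf("CTRL%04d", seq_len(nt_n)),
      sequence = random_spacer(nt_n),
      gene = NA_character_, library = "Control",
      chromosome = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_,
      n_perfect = 0L, n_1mm = 0L,
      n_2mm = sample(0:5, nt_n, TRUE),
      jacks = NA_real_, rule_set2 = NA_real_, ks = NA_real_)
    truth <- list(
      genes = data.frame(gene = genes, essential = essential,
                         effect = effect),
      guides = data.frame(guide_id = c(guide_id, controls$guide_id),
                          gene = c(gene_col, rep(NA, nt_n)),
                          class = c(cls, rep("nontargeting", nt_n)),
                          efficiency = c(round(eff, 4), rep(NA, nt_n)),
                          effective_gene = c(donor, rep(NA, nt_n))))
    list(records = rbind(records, controls), truth = truth)
  })
}

#' Simulate a pooled CRISPR screen count matrix
#'
#' Plasmid abundances are log-normal; plasmid read counts are
#' negative-binomial around the abundance scaled to the sequencing depth.
#' Each screen sample's expected counts are the plasmid abundances scaled
#' by `2^(true effect)` — where the true effect of a guide is its
#' (possibly off-target) gene's fitness effect times the guide efficiency,
#' or the non-targeting growth offset for controls — renormalised to the
#' same total depth (sequencing measures relative abundance), and then
#' overdispersed with the negative-binomial read model.
#'
#' @param reference a [simulate_reference()] result (or a compatible list
#'   with `records` and `truth`).
#' @param config the [simulation_config()] used for the reference.
#' @param seed integer seed.
#' @return list with `screen` (a [screen_counts()] object), and
#'   `dependencies` (logical genes x cell-lines ground-truth matrix).
#' @export
simulate_screen <- function(reference, config = simulation_config(),
                            seed = 1) {
  records <- reference$records
  truth <- reference$truth
  n <- nrow(records)
  with_seed(seed, {
    gene_effect <- setNames(truth$genes$effect, truth$genes$gene)
    g <- truth$guides[match(records$guide_id, truth$guides$guide_id), ]
    effect <- ifelse(g$class == "nontargeting", config$nontargeting_delta,
                     gene_effect[g$effective_gene] * g$efficiency)
    abundance <- rlnorm(n, meanlog = 0, sdlog = config$plasmid_sdlog)
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    depth_total <- config$depth * n
    draw <- function(mu) {
      if (is.finite(size)) rnbinom(n, mu = mu, size = size)
      else stats::rpois(n, mu)
    }
    pd_mu <- abundance / sum(abundance) * depth_total
    cols <- list()
    for (p in seq_len(config$n_plasmid))
      cols[[sprintf("pdna_%d", p)]] <- draw(pd_mu)
    lines <- sprintf("LINE%02d", seq_len(config$n_cell_lines))
    for (l in lines) {
      scr_ab <- abundance * 2^effect
      scr_mu <- scr_ab / sum(scr_ab) * depth_total
      for (r in seq_len(config$replicates))
        cols[[sprintf("%s_r%d", l, r)]] <- draw(scr_mu)
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- records$guide_id
    samples <- data.frame(
      sample_id = colnames(counts),
      cell_line = c(rep(NA_character_, config$n_plasmid),
                    rep(lines, each = config$replicates)),
      role = c(rep("plasmid", config$n_plasmid),
               rep("screen", config$n_cell_lines * config$replicates)),
      replicate = c(rep(NA_integer_, config$n_plasmid),
                    rep(seq_len(config$replicates), config$n_cell_lines)))
    deps <- matrix(rep(truth$genes$essential, length(lines)),
                   ncol = length(lines),
                   dimnames = list(truth$genes$gene, lines))
    list(screen = screen_counts(counts, samples), dependencies = deps)
  })
}

#' One-call synthetic fixture: reference, screen, gene sets, ground truth
#'
#' Everything needed to run the scoring, design and benchmarking stages:
#' a simulated reference, a simulated screen of it, and
#' essential/non-essential reference gene sets sampled from the true
#' classes (with optional label noise).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (drives reference and screen).
#' @param label_noise fraction of reference-set labels flipped between the
#'   essential and non-essential sets (default 0).
#' @return list of class `sim_bundle` with `records`, `truth`, `screen`,
#'   `dependencies`, `essential`, `non_essential`, `non_targeting`,
#'   `config`, `seed`.
#' @export
end_to_end_fixture <- function(config = simulation_config(), seed = 1,
                               label_noise = 0) {
  ref <- simulate_reference(config, seed = seed)
  scr <- simulate_screen(ref, config, seed = seed + 1)
  sets <- with_seed(seed + 2, {
    ess <- ref$truth$genes$gene[ref$truth$genes$essential]
    non <- ref$truth$genes$gene[!ref$truth$genes$essential]
    if (label_noise > 0) {
      flip_e <- runif(length(ess)) < label_noise
      flip_n <- runif(length(non)) < label_noise
      list(essential = c(ess[!flip_e], non[flip_n]),
           non_essential = c(non[!flip_n], ess[flip_e]))
    } else list(essential = ess, non_essential = non)
  })
  structure(list(records = ref$records, truth = ref$truth,
                 screen = scr$screen, dependencies = scr$dependencies,
                 essential = sets$essential,
                 non_essential = sets$non_essential,
                 non_targeting = ref$records$guide_id[
                   ref$records$library == "Control"],
                 config = config, seed = seed),
            class = "sim_bundle")
}
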