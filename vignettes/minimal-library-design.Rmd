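---
title: "Minimal CRISPR-Cas9 library design and benchmarking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal CRISPR-Cas9 library design and benchmarking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicrispr)
```

## The problem

Genome-wide CRISPR-Cas9 loss-of-fitness screens use libraries of 4-19
sgRNAs per gene. Guide number drives cost: cells must be kept at several
hundred-fold coverage of the library through transduction, culture and
sequencing, which puts primary models (organoids, limited patient
material) out of reach of full-size libraries. If two reliably active,
specific guides per gene suffice, the footprint of a screen drops by an
order of magnitude.

`minicrispr` implements the full loop that makes such a minimal library
defensible: empirical per-guide efficacy scoring from existing
large-scale screen data, tiered guide selection under off-target and
efficacy constraints, and a benchmarking suite that quantifies how much
of the full library's signal the reduced library preserves — all
exercisable on synthetic screens with known ground truth.

## Screen analysis model

Raw sgRNA read counts are processed in a fixed order:

1. guides with a mean plasmid (pDNA) count below 30 are removed — their
   representation in the cloned library is too low for fold-changes to be
   meaningful;
2. each sample is scaled to reads per million,
   $G'_i = (G_i / \sum_j G_j) \times 10^6$;
3. a pseudo-count of 1 is added to the whole normalised matrix and
   per-guide log2 fold-changes are taken against the plasmid reference,
   $\mathrm{FC}_i = \log_2(G'_{i,s} + 1) - \log_2(G'_{i,\mathrm{pDNA}} + 1)$;
4. gene-level fold-changes are the unweighted mean over a gene's guides;
   technical replicates of a cell line are mean-averaged.

With several designated pDNA columns, the count filter uses their mean
raw count and the fold-change reference their mean RPM profile — a
pooled reference is the least surprising generalisation of a single
plasmid column. Gene aggregation and replicate averaging are both plain
means, so their order does not matter (this commutation is tested); the
default pipeline runs guide-FC → gene-FC → replicate average.

## The KS efficacy score

Non-targeting guides do not cut, and cells that carry them escape the
small fitness cost of Cas9-induced double-strand breaks. Across samples
they are therefore mildly positively enriched, and they define the
empirical "no on-target activity" baseline. For every guide, the package
computes the two-sample Kolmogorov-Smirnov $D$ statistic between the
guide's fold-changes across samples and the per-sample medians of all
non-targeting guides:

$$D = \sup_t \left| F_{\mathrm{guide}}(t) - F_{\mathrm{NT\;median}}(t) \right| \in [0, 1].$$

A score near 0 means the guide behaves like a control (dead or targeting
a fitness-neutral gene at low activity); a score near 1 means a strongly
shifted distribution. The score — not the p-value — ranks guides. The
p-value is reported for completeness using the plain asymptotic
Kolmogorov series, without small-sample refinement, because nothing
downstream consumes it.

Two design choices deserve a note:

* the comparison sample is the vector of per-sample non-targeting
  *medians* (one value per sample), not the pool of all non-targeting
  fold-changes; pooling is available via `pool_reference = TRUE`.
* the ECDF of the statistic steps in units of $1/n_{\mathrm{samples}}$, so
  the score has meaningful resolution only with tens of samples. The
  score is designed for compendium-scale data (hundreds of replicate
  samples); the simulator's default of 60 samples (20 lines × 3
  replicates) is the smallest configuration we consider representative of
  that regime.

## Tiered library design

The selection operates on a multi-source reference of guide records
(spacer, gene, source library, off-target alignment summary at 0/1/2
mismatches, and externally computed efficacy metrics — JACKS, Rule Set
2 — which are consumed as inputs, never computed). After removing
unmapped or gene-less guides and spacers with conflicting gene
annotation across sources, each guide gets the most stringent tier it
satisfies:

| tier | off-target constraint | efficacy filter |
|------|----------------------|-----------------|
| green | 1 perfect alignment, 0 one-mismatch alignments | JACKS ∈ [0, 2] (Project Score, Avana); Rule Set 2 > 0.4 (Brunello); none (TKOv3) |
| amber | 1 perfect alignment | none |
| red | 1-3 perfect alignments | none |

For each gene, two slots are filled by looping over tiers (outer) and
over sources in precedence order Project Score → Avana → Brunello →
TKOv3 (inner), ranking within a source by KS score (Project Score,
Avana), Rule Set 2 (Brunello) or input order (TKOv3), with ties broken
by guide identifier. Tier-first looping means every source is exhausted
at green before any amber guide is considered; this matches the
observation that tier composition dominates source composition in the
target design. The alternative source-first order, and all thresholds,
are configurable through `selection_config()`.

The implementation is a single vectorised ordering (tier, source rank,
metric, id) followed by taking the first two distinct spacers per gene.
This is provably equivalent to the nested loop: a selection stage either
fills the quota (selection for the gene ends) or selects *every*
candidate eligible at that stage, so no record can ever be picked at a
less stringent tier than its own. The equivalence is what lets a
~19,000-gene, ~320,000-record design run in seconds.

Non-targeting controls are filtered to guides with no perfect alignment,
no 1-mismatch alignment and at most three 2-mismatch alignments, then
ranked by mean absolute deviation between their fold-change profile and
the per-sample non-targeting median profile (the similarity metric is a
package choice; any sensible profile distance would do), keeping the
closest 200.

Genes whose dependency calls disagree between the full and the minimal
library in more than 100 cell lines (see benchmarking) are re-selected
with the offending source blacklisted (`replace_discordant()`).

## Benchmarking statistics

* **Recall curves** sort items by fold-change (most negative first) and
  accumulate the fraction of a group recovered per rank. The area is a
  trapezoidal integral over the normalised rank axis with recall 0 at
  rank 0; under this convention a group containing every item scores
  exactly 0.5, which is also the expectation of a random group.
* **Partial AROC**: ROC of reference essential (positive) vs
  non-essential genes, trapezoidal area up to a false-positive-rate cap
  of 0.2, divided by the cap. Chance is cap/2 = 0.1; a perfect screen
  scores 1. The McClish standardisation (chance 0.5) is available behind
  a flag. Ties in fold-change move the curve diagonally.
* **Dependency calls**: per cell line, the fold-change threshold is the
  largest value such that calling `FC < threshold` keeps the fraction of
  non-essential genes among called reference genes at or below 1%
  (walking the ROC from the most negative fold-change; only prefixes
  ending at distinct fold-change values are realisable call sets). Genes
  outside the reference sets do not shape the threshold but are called
  against it. If no cut achieves the FDR the sample is flagged low
  quality and the threshold falls just below the most negative reference
  fold-change.
* **Average precision**: the non-interpolated step formula
  $\mathrm{AP} = \sum_j (R_j - R_{j-1}) P_j$ over the ranked gene list,
  with the full library's 1%-FDR calls as the reference set and the
  minimal library's gene fold-changes as the ranking.
* **Down-sampling**: per-gene sampling without replacement
  (`downsample_guides()`, seeded), or deterministic restriction to a
  designed library (`select_by_library()`).
* **Plasmid QC**: Gini coefficient (half the relative mean absolute
  difference), Lorenz curve, and the decile skew ratio (summed reads of
  the top 10% of guides over the bottom 10%).

## The synthetic screen generator

The generator exists so every claim above can be tested against known
ground truth without any external dataset. Its model:

* plasmid abundances are log-normal (sdlog 0.5), scaled to a mean depth
  of 500 reads per guide;
* read counts are negative-binomial with dispersion 0.2
  (variance $\mu + 0.2\mu^2$);
* one third of genes are essential with a fitness effect of −3 (log2
  units for a fully efficient guide); non-essential genes have effect 0;
* a guide's true effect is its gene's effect times a per-guide
  efficiency: 80% of guides are efficient (efficiency 0.85-1), 20%
  inefficient (0-0.1); 2% of guides are off-target outliers that inherit
  the effect of a random other gene;
* non-targeting guides carry a uniform +0.3 fitness offset — the growth
  advantage of never cutting — implemented as a planted effect rather
  than a compositional artefact, the simplest mechanism with the right
  direction;
* each screen sample's expected counts are the plasmid abundances scaled
  by $2^{\mathrm{effect}}$ and renormalised to the same total depth,
  because sequencing measures relative abundance.

That renormalisation has a consequence worth stating: measured
fold-changes equal planted effects minus a global compositional constant
($\log_2$ of the abundance-weighted mean of $2^{\mathrm{effect}}$),
exactly as in real screens where the dropout of essential-gene guides
inflates everyone else's share of reads. Parameter-recovery tests
therefore either use configurations where the shift is negligible (few
essential genes) or measure effects relative to the non-essential
baseline. Thresholded statistics (dependency calls, AROC, AP) are
rank-based or reference-calibrated and are unaffected.

What the generator does *not* emulate: copy-number-driven fold-change
bias, locus-dependent cutting toxicity, sequencing error, PCR jackpot
effects, or context-specific (non-pan-essential) dependencies. Passing
tests on synthetic screens therefore demonstrate correctness of the
statistics and of the selection logic under the stated generative model,
not robustness to those real-data artefacts — the package deliberately
leaves copy-number correction to dedicated tools.

Gene essentiality is constant across simulated cell lines (the
pan-cancer core-essential regime that the reference gene sets represent);
the per-line dependency ground truth is that flag.

## Numerical conventions and degenerate inputs

* All ranking ties (fold-change, KS, metric) break by identifier, making
  every output byte-reproducible under a fixed seed; the run manifests
  record seeds and input/output checksums (the manifest carries a
  wall-clock timestamp and is the one non-reproducible output file).
* KS on tied data absorbs ties before taking the maximum ECDF gap.
* `filter_low_plasmid` keeps guides at exactly the threshold ("less
  than" excludes); an all-filtered matrix is a warning, not an error.
* A guide observed in a single sample is still scored
  (`n_samples_used = 1`); guides with no finite value get `NA` scores
  and are reported, not fatal.
* Zero-total count columns, missing plasmid designations, empty gene
  sets and empty reference sets are errors that name the offending
  sample or field.
* Problem sizes in the test-suite and acceptance script (300-gene
  screens for pipeline properties, a 18,761-gene reference for the
  design-size identity, 20 cell lines × 3 replicates) are chosen as the
  smallest configurations representative of each claim.

## A worked example

```{r example, eval = FALSE}
bundle <- end_to_end_fixture(simulation_config(n_genes = 300), seed = 1)
screen <- filter_low_plasmid(bundle$screen)
fc <- log_fold_changes(normalize_rpm(screen), plasmid_samples(screen))
eff <- ks_scores_all(fc, bundle$non_targeting)

records <- bundle$records[!is.na(bundle$records$gene), ]
records$ks <- eff$ks_score[match(records$guide_id, eff$guide_id)]
records <- exclude_conflicting(exclude_unmapped(records))
library2 <- select_minimal_library(records)
library2
```

The same pipeline is available from the shell through the
`exec/minicrispr` script (`simulate`, `score`, `design`, `benchmark`
subcommands), each run emitting a JSON manifest.

## Known limitations

* KS scores need tens of samples; on a handful of samples the score is
  quantised and the efficient/inefficient ranking degrades gracefully
  but measurably.
* The selection assumes externally provided off-target summaries and
  efficacy metrics; it performs no alignment and no sequence-based
  scoring of its own.
* `average_precision` computes recall against the reference genes
  present in the scored universe and warns when some are missing.
* The FDR threshold is a per-sample empirical quantity; on low-quality
  screens (flagged) it collapses to an empty call set rather than
  guessing.
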