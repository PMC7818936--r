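test_that("recall curve: direction, closed form for the full group, ends", {
  set.seed(10)
  v <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  # a group containing every item has area exactly 0.5
  expect_equal(recall_curve(v, rep(TRUE, 200))$area, 0.5)
  # a group concentrated at the most negative ranks has area near 1
  grp <- names(sort(v))[1:20]
  rc <- recall_curve(v, grp)
  expect_gt(rc$area, 0.9)
  expect_equal(rc$recall[length(rc$recall)], 1)
  expect_true(all(diff(rc$recall) >= 0))
  # enrichment towards positive fold-changes gives area < 0.5
  expect_lt(recall_curve(v, names(sort(v, decreasing = TRUE))[1:20])$area, 0.4)
  expect_error(recall_curve(v, rep(FALSE, 200)), "empty")
})

test_that("recall area of a random group sits at the 0.5 random expectation", {
  set.seed(11)
  areas <- replicate(30, {
    v <- rnorm(500)
    recall_curve(v, sample(c(TRUE, FALSE), 500, TRUE, prob = c(.2, .8)))$area
  })
  # SE of one area is ~ sqrt(1/12)/sqrt(n_group) ~ 0.029; 3 SE of the mean
  expect_lt(abs(mean(areas) - 0.5), 3 * 0.029 / sqrt(30))
})

test_that("partial AROC: perfect separation, full-range equality, chance", {
  ess <- sprintf("E%02d", 1:20)
  non <- sprintf("N%02d", 1:40)
  sep <- setNames(c(runif(20, -5, -3), runif(40, -1, 1)), c(ess, non))
  expect_equal(partial_aroc(sep, ess, non, fpr_cap = 0.2), 1.0)
  # fpr_cap = 1 recovers the full AROC
  set.seed(12)
  mixed <- setNames(c(rnorm(20, -1.2), rnorm(40, 0)), c(ess, non))
  full <- partial_aroc(mixed, ess, non, fpr_cap = 1)
  wilcox_auc <- {
    r <- rank(-mixed)  # more negative fold-change = higher score
    (sum(r[ess]) - 20 * 21 / 2) / (20 * 40)
  }
  expect_equal(full, wilcox_auc, tolerance = 1e-12)
  # shuffled labels give the documented chance value cap/2 = 0.1
  chance <- replicate(400, {
    lab <- sample(c(ess, non))
    partial_aroc(setNames(mixed, lab), ess, non, fpr_cap = 0.2)
  })
  expect_lt(abs(mean(chance) - 0.1), 3 * stats::sd(chance) / sqrt(400))
  # McClish standardisation maps chance to ~0.5 and perfection to 1
  expect_equal(partial_aroc(sep, ess, non, 0.2, standardize = "mcclish"), 1)
  expect_error(partial_aroc(sep, ess, character(0)), "present")
})

test_that("partial AROC equals the pROC trapezoidal oracle", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:20) {
    ess <- sprintf("E%02d", 1:15)
    non <- sprintf("N%02d", 1:25)
    fc <- setNames(c(rnorm(15, -runif(1, 0, 2)), rnorm(25)), c(ess, non))
    for (cap in c(0.2, 0.5, 1)) {
      ours <- partial_aroc(fc, ess, non, fpr_cap = cap)
      r <- pROC::roc(response = c(rep(1, 15), rep(0, 25)),
                     predictor = -fc, quiet = TRUE, direction = "<")
      ref <- as.numeric(pROC::auc(r, partial.auc = c(1, 1 - cap),
                                  partial.auc.focus = "specificity",
                                  partial.auc.correct = FALSE)) / cap
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  }
})

test_that("FDR threshold: separation, vacuous FDR, monotonicity, oracle", {
  ess <- sprintf("E%02d", 1:10)
  non <- sprintf("N%02d", 1:20)
  sep <- setNames(c(seq(-5, -3, length.out = 10), seq(-1, 1, length.out = 20)),
                  c(ess, non))
  r <- fc_threshold_at_fdr(sep, ess, non, 0.01)
  # threshold sits between the classes: every essential called, nothing else
  expect_gt(r$threshold, -3)
  expect_lte(r$threshold, -1)
  expect_identical(r$n_reference_called, 10L)
  expect_false(r$low_quality)
  # fdr = 1 calls everything
  expect_identical(fc_threshold_at_fdr(sep, ess, non, 1)$threshold, Inf)
  # inverted screen: nothing achievable, flagged low quality
  inv <- setNames(c(seq(1, 2, length.out = 10), seq(-2, -1, length.out = 20)),
                  c(ess, non))
  bad <- fc_threshold_at_fdr(inv, ess, non, 0.01)
  expect_true(bad$low_quality)
  expect_lt(bad$threshold, min(inv[c(ess, non)]))
  # monotone in fdr
  set.seed(14)
  v <- setNames(c(rnorm(10, -2), rnorm(20)), c(ess, non))
  thr <- vapply(c(0.01, 0.05, 0.1, 0.25, 0.5),
                function(q) fc_threshold_at_fdr(v, ess, non, q)$threshold,
                numeric(1))
  expect_true(all(diff(thr) >= 0))
  # interleaved toy vector equals the exhaustive cut-point oracle
  for (i in 1:50) {
    fc <- setNames(round(rnorm(10, c(rep(-1, 4), rep(0, 6))), 1),
                   sprintf("G%02d", 1:10))
    e <- sprintf("G%02d", 1:4); n <- sprintf("G%02d", 5:10)
    q <- sample(c(0.01, 0.1, 0.3, 0.5), 1)
    expect_equal(fc_threshold_at_fdr(fc, e, n, q)$threshold,
                 oracle_fdr_threshold(fc, e, n, q))
  }
})

test_that("dependency calls: empty sets, determinism, ground truth recovery", {
  ess <- c("E1", "E2"); non <- c("N1", "N2", "N3")
  m <- matrix(c(1, 2, 0.5, 1.5, 2.5), 5, 2,
              dimnames = list(c(ess, non), c("L1", "L2")))
  calls <- call_dependencies(m, ess, non)
  expect_identical(sum(calls$calls), 0L)      # nothing below threshold
  expect_true(all(calls$low_quality))
  # identical samples give identical calls
  b <- tiny_bundle(seed = 15)
  gf <- average_replicates(gene_level(bundle_fc(b), bundle_guide_map(b)),
                           bundle_line_map(b))
  two <- call_dependencies(cbind(gf[, 1, drop = FALSE],
                                 dup = gf[, 1]), b$essential, b$non_essential)
  expect_identical(unname(two$calls[, 1]), unname(two$calls[, 2]))
  # planted dependencies are recovered with high precision
  cd <- call_dependencies(gf, b$essential, b$non_essential)
  truth <- b$dependencies[rownames(cd$calls), colnames(cd$calls)]
  precision <- sum(cd$calls & truth) / sum(cd$calls)
  expect_gt(precision, 0.9)
  expect_identical(unname(cd$calls), unname(sweep(gf, 2, cd$thresholds, "<")))
})

test_that("average precision: closed forms and the step-formula oracle", {
  sc <- setNames(seq(-5, 5, length.out = 10), sprintf("g%02d", 1:10))
  # reference occupying the top |reference| ranks scores 1
  expect_equal(average_precision(sprintf("g%02d", 1:3), sc), 1)
  # a single relevant gene at rank k scores 1/k
  for (k in c(1, 4, 9)) {
    expect_equal(average_precision(names(sort(sc))[k], sc), 1 / k)
  }
  set.seed(16)
  for (i in 1:50) {
    scores <- setNames(rnorm(20), sprintf("g%02d", 1:20))
    ref <- sample(names(scores), sample(1:10, 1))
    expect_equal(average_precision(ref, scores), oracle_ap(ref, scores),
                 tolerance = 1e-12)
  }
  expect_error(average_precision(character(0), sc), "empty")
  expect_warning(average_precision(c("g01", "absent"), sc), "absent")
})

test_that("guide down-sampling: identity, determinism, per-gene uniformity", {
  set.seed(17)
  fc <- matrix(rnorm(20), 10, 2,
               dimnames = list(sprintf("gA_%d", 1:10), c("s1", "s2")))
  map <- setNames(c(rep("A", 5), rep("B", 5)), rownames(fc))
  # n at least the per-gene count is the identity
  expect_identical(downsample_guides(fc, map, 5, seed = 1),
                   structure(fc, selected_guides = rownames(fc)))
  d1 <- downsample_guides(fc, map, 2, seed = 99)
  d2 <- downsample_guides(fc, map, 2, seed = 99)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 4L)
  # every pair of a 5-guide gene appears with equal frequency
  draws <- table(replicate(4000, paste(
    sort(match(rownames(downsample_guides(fc, map, 2))[1:2], rownames(fc))),
    collapse = "-")))
  expect_identical(length(draws), 10L)   # choose(5, 2)
  expect_gt(stats::chisq.test(draws)$p.value, 1e-4)
  # unmapped (control) guides are always retained
  map2 <- map; map2["gA_1"] <- NA
  expect_true("gA_1" %in% rownames(downsample_guides(fc, map2, 1, seed = 3)))
})

test_that("library restriction reduces the screen deterministically", {
  b <- tiny_bundle(seed = 18)
  fc <- bundle_fc(b)
  expect_equal(select_by_library(fc, rownames(fc)), fc, ignore_attr = TRUE)
  two <- rownames(fc)[1:2]
  red <- select_by_library(fc, two)
  g <- gene_level(red, bundle_guide_map(b))
  expect_equal(unname(g[1, ]), unname(colMeans(fc[two, ])))
  expect_warning(select_by_library(fc, c(two, "missing_guide")), "overlap")
})

test_that("discordance counting equals the symmetric difference per gene", {
  mk <- function(m) structure(list(calls = m, thresholds = NULL,
                                   low_quality = NULL, fdr = 0.01),
                              class = "dependency_calls")
  set.seed(19)
  a <- matrix(runif(50) < 0.3, 5, 10,
              dimnames = list(sprintf("G%d", 1:5), sprintf("L%d", 1:10)))
  b <- a; b["G2", 1:3] <- !b["G2", 1:3]
  d <- discordance_counts(mk(a), mk(b), cutoff = 2)
  expect_identical(d$n_discordant[d$gene == "G2"], 3)
  expect_true(d$flagged[d$gene == "G2"])
  expect_identical(sum(d$n_discordant), 3)
  expect_identical(discordance_counts(mk(a), mk(a))$n_discordant, rep(0, 5))
  # random pair equals brute-force XOR count
  r <- matrix(runif(50) < 0.5, 5, 10, dimnames = dimnames(a))
  expect_identical(discordance_counts(mk(a), mk(r))$n_discordant,
                   sort(unname(rowSums(xor(a, r))), decreasing = TRUE))
  bad <- mk(a[, 1:3]); colnames(bad$calls) <- c("X", "Y", "Z")
  expect_error(discordance_counts(mk(a), bad), "cell lines")
})

test_that("Gini/Lorenz/skew quantify plasmid evenness", {
  even <- gini_lorenz(rep(100, 50))
  expect_equal(even$gini, 0)
  expect_equal(even$skew_ratio, 1)
  # a single guide holding all reads approaches gini 1
  expect_gt(gini_lorenz(c(rep(0.0001, 999), 1e6))$gini, 0.99)
  # brute-force mean-absolute-difference oracle
  x <- c(1, 2, 3, 4)
  mad_gini <- sum(outer(x, x, function(a, b) abs(a - b))) /
    (2 * length(x)^2 * mean(x))
  expect_equal(gini_lorenz(x)$gini, mad_gini)
  set.seed(20)
  y <- rlnorm(200, 5, 1)
  oracle <- sum(outer(y, y, function(a, b) abs(a - b))) /
    (2 * length(y)^2 * mean(y))
  expect_equal(gini_lorenz(y)$gini, oracle, tolerance = 1e-12)
  lz <- gini_lorenz(y)$lorenz
  expect_equal(lz$L[1], 0); expect_equal(lz$L[nrow(lz)], 1)
  expect_true(all(diff(lz$L) >= 0))
  expect_error(gini_lorenz(c(0, 0)), "zero")
})

test_that("gene fold-change concordance is rank-based", {
  set.seed(21)
  a <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("G%02d", 1:20), c("s1", "s2")))
  expect_equal(unname(correlate_gene_fc(a, a)), c(1, 1))
  # monotone transforms leave Spearman untouched
  expect_equal(unname(correlate_gene_fc(a, a^3 + 2 * a)), c(1, 1))
  b <- a + matrix(rnorm(40, 0, 0.5), 20, 2)
  manual <- cor(rank(a[, "s1"]), rank(b[, "s1"]))
  expect_equal(unname(correlate_gene_fc(a, b)["s1"]), manual)
  expect_error(correlate_gene_fc(a[1:2, ], a[1:2, ]), "3 shared")
})
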