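test_that("protein-table filtering removes contaminants, weak evidence and non-human rows", {
  tab <- toy_protein_table()
  out <- filter_protein_table(tab)
  # row 3 has a single peptide, rows 4-5 are contaminants
  expect_equal(out$accession, c("P01", "P02", "P06"))
  expect_equal(nrow(filter_protein_table(tab[0, ])), 0L)
  expect_error(filter_protein_table(tab[, -3]), "hl_ratio")

  nh <- tab; nh$is_human[1] <- FALSE
  expect_false("P01" %in% filter_protein_table(nh)$accession)
  # require_ratio = FALSE relaxes only the ratio-count rule
  low <- tab; low$n_ratios[1] <- 1L
  expect_false("P01" %in% filter_protein_table(low)$accession)
  expect_true("P01" %in% filter_protein_table(low, require_ratio = FALSE)$accession)
})

test_that("labeling by gene symbol assigns TP/FP/unknown and rejects overlapping lists", {
  tab <- label_proteins(toy_protein_table(), tp_genes = c("G01", "G02"),
                        fp_genes = "G03")
  expect_equal(tab$label, c("TP", "TP", "FP", "unknown", "unknown", "unknown"))
  expect_error(label_proteins(toy_protein_table(), "G01", "G01"), "both")
})

test_that("FP-median normalization matches hand-computed values", {
  mk <- function(ratios, labels) {
    data.frame(hl_ratio = ratios, label = labels, stringsAsFactors = FALSE)
  }
  t1 <- normalize_ratios(mk(c(1, 1, 1, 4), c("FP", "FP", "FP", "unknown")))
  expect_equal(t1$norm_log2_ratio[4], 2)
  t2 <- normalize_ratios(mk(c(2, 2, 2), c("FP", "FP", "FP")))
  expect_equal(t2$norm_log2_ratio, c(0, 0, 0))
  t3 <- normalize_ratios(mk(c(1, 2, 4, 6), c("FP", "FP", "FP", "TP")))
  expect_equal(t3$norm_log2_ratio[4], log2(6 / 2), tolerance = 1e-12)
  # even FP count: the normalizer is the midpoint of the two central values,
  # so a protein at that midpoint ratio maps to exactly 0
  t4 <- normalize_ratios(mk(c(1, 2, 4, 8, 3), c(rep("FP", 4), "unknown")))
  expect_equal(t4$norm_log2_ratio[5], 0)
  expect_error(normalize_ratios(mk(4, "TP")), "no FP")
})

roc_table <- function(ratios, labels) {
  data.frame(accession = sprintf("P%02d", seq_along(ratios)),
             norm_log2_ratio = ratios, label = labels,
             stringsAsFactors = FALSE)
}

test_that("ROC cutoff maximizes TPR-FPR on the worked example", {
  # descending ratios labeled T,T,F,T,F
  res <- roc_cutoff(roc_table(c(5, 4, 3, 2, 1), c("TP", "TP", "FP", "TP", "FP")))
  expect_equal(res$tpr_minus_fpr_max, 2 / 3)
  expect_equal(res$cutoff, 4)
  expect_false(res$degenerate)

  # perfect separation: cutoff at the lowest TP ratio, max = 1
  res2 <- roc_cutoff(roc_table(c(5, 4, 3, 2), c("TP", "TP", "FP", "FP")))
  expect_equal(res2$tpr_minus_fpr_max, 1)
  expect_equal(res2$cutoff, 4)

  # inverted labels: no rank beats 0 -> degenerate
  res3 <- roc_cutoff(roc_table(c(5, 4, 3, 2), c("FP", "FP", "TP", "TP")))
  expect_lte(res3$tpr_minus_fpr_max, 0)
  expect_true(res3$degenerate)

  expect_error(roc_cutoff(roc_table(c(2, 1), c("FP", "FP"))), "no TP")
  expect_error(roc_cutoff(roc_table(c(2, 1), c("TP", "TP"))), "no FP")
})

test_that("TPR and FPR are non-decreasing and end at 1; unknowns shift neither", {
  set.seed(41)
  tab <- roc_table(rnorm(60), sample(c("TP", "FP", "unknown"), 60, TRUE))
  res <- roc_cutoff(tab)
  expect_true(all(diff(res$roc$tpr) >= 0))
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_equal(res$roc$tpr[nrow(res$roc)], 1)
  expect_equal(res$roc$fpr[nrow(res$roc)], 1)
  unk <- res$roc$label == "unknown"
  expect_true(all(res$roc$tpr[unk] == res$roc$tpr[which(unk) - 1] |
                    which(unk) == 1))
})

test_that("ROC cutoff equals the brute-force threshold scan, including with ties", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    ratios <- if (i %% 2 == 0) round(rnorm(n), 1) else rnorm(n)  # force ties
    labels <- sample(c("TP", "FP", "unknown"), n, TRUE, prob = c(.3, .3, .4))
    if (!any(labels == "TP") || !any(labels == "FP")) next
    res <- roc_cutoff(roc_table(ratios, labels))
    bf <- roc_bruteforce(ratios, labels)
    expect_equal(res$cutoff, bf$cutoff, info = i)
    expect_equal(res$tpr_minus_fpr_max, bf$max, tolerance = 1e-12, info = i)
  }
})

test_that("replicate crossing keeps accessions present in enough sets", {
  expect_equal(cross_replicates(list(c("A", "B"), c("B", "C"), "C"), 2),
               c("B", "C"))
  expect_equal(cross_replicates(list(c("A", "B"), c("A", "B")), 2), c("A", "B"))
  expect_equal(cross_replicates(list("A", "A", "B"), 3), character(0))
  expect_error(cross_replicates(list("A"), 2), "exceeds")
})

test_that("rescaling all H/L ratios leaves the selected protein set unchanged", {
  sim <- simulate_experiment(small_config(seed = 13))
  base <- enrichment_analysis(sim$protein_table, sim$tp_genes, sim$fp_genes)
  scaled_tab <- sim$protein_table
  scaled_tab$hl_ratio <- scaled_tab$hl_ratio * 7.3
  scaled <- enrichment_analysis(scaled_tab, sim$tp_genes, sim$fp_genes)
  expect_equal(base$final_set, scaled$final_set)
})

test_that("above-cutoff membership uses a closed threshold", {
  tab <- roc_table(c(3, 2, 1), c("TP", "TP", "FP"))
  expect_setequal(above_cutoff(tab, 2), c("P01", "P02"))
})
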