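test_that("configuration validation rejects bad probabilities and empty designs", {
  expect_error(sim_config(biotin_site_rate = 1.5), "in \\[0, 1\\]")
  expect_error(sim_config(decoy_rate = -0.1), "in \\[0, 1\\]")
  expect_error(sim_config(n_tp_proteins = 0, n_fp_proteins = 0,
                          n_unknown_proteins = 0), "zero proteins")
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_experiment(small_config(seed = 5))
  b <- simulate_experiment(small_config(seed = 5))
  expect_identical(a$protein_table, b$protein_table)
  expect_identical(a$site_table, b$site_table)
  expect_identical(a$psm_table, b$psm_table)
  expect_identical(a$peaklists, b$peaklists)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_experiment(small_config(seed = 6))
  expect_false(identical(a$protein_table, c$protein_table))
})

test_that("a design without TP proteins yields no TP rows and a degenerate ROC", {
  sim <- simulate_experiment(sim_config(seed = 2, n_tp_proteins = 0L,
                                        n_fp_proteins = 30L,
                                        n_unknown_proteins = 20L,
                                        protein_length = 200L,
                                        n_noise_peaks = 10L))
  expect_false(any(sim$ground_truth$protein_labels$category == "TP"))
  expect_length(sim$tp_genes, 0L)
  tab <- filter_protein_table(sim$protein_table[sim$protein_table$replicate == "R1", ])
  tab <- label_proteins(tab, sim$tp_genes, sim$fp_genes)
  tab <- normalize_ratios(tab)
  expect_error(roc_cutoff(tab), "no TP")
})

test_that("with full marker prevalence and no noise, biotinylated spectra carry exactly the three markers unassigned", {
  mz <- predicted_marker_ions(biotin_phenol_mod())
  sp <- simulate_peaklists(30, 30, marker_mzs = mz, prevalence_biotin = 1,
                           prevalence_other = 0, n_noise_peaks = 0L, seed = 9)
  for (pl in sp$peaklists) {
    un <- unassigned_masses(pl$mz, pl$assigned_mz, 0.01)
    if (pl$is_biotinylated) {
      expect_length(un, 3L)
      expect_equal(sort(un), sort(unname(mz)), tolerance = 1e-4)
    } else {
      expect_length(un, 0L)
    }
  }
})

test_that("planted defect-free sites are recovered exactly by the filter cascade", {
  cfg <- small_config(seed = 4, decoy_rate = 0, unlocalized_rate = 0,
                      light_state_rate = 0, redundant_rate = 0)
  sim <- simulate_experiment(cfg)
  surv <- filter_site_table(sim$site_table)
  got <- sort(paste(surv$accession, surv$position))
  want <- sort(paste(sim$ground_truth$true_sites$accession,
                     sim$ground_truth$true_sites$position))
  expect_equal(got, want)
  expect_true(all(sim$ground_truth$true_sites$clean))
})

test_that("background log2 ratios are centered at the configured mean", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_experiment(cfg)
  gt <- sim$ground_truth$protein_labels
  fp_rows <- sim$protein_table$gene_symbol %in%
    gt$gene_symbol[gt$category == "FP"]
  x <- log2(sim$protein_table$hl_ratio[fp_rows])
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - cfg$fp_log2_ratio_mean), 3 * se)
})

test_that("every site row traces to exactly one ground-truth site", {
  sim <- simulate_experiment(small_config(seed = 3))
  gt_keys <- paste(sim$ground_truth$true_sites$accession,
                   sim$ground_truth$true_sites$position)
  row_keys <- paste(sim$site_table$accession, sim$site_table$position)
  expect_true(all(row_keys %in% gt_keys))
  expect_false(any(duplicated(gt_keys)))
})

test_that("toy structures respect the burial ground truth at the 5 A^2 threshold", {
  st_exposed <- simulate_structure(3, buried_fraction = 0, seed = 1)
  expect_false(any(st_exposed$ground_truth$buried))
  for (p in st_exposed$ground_truth$position) {
    expect_gt(tyrosine_subset_asa(st_exposed$atoms, p, "OH_ONLY"), 5)
  }
  st_buried <- simulate_structure(3, buried_fraction = 1, seed = 1)
  expect_true(all(st_buried$ground_truth$buried))
  for (p in st_buried$ground_truth$position) {
    for (s in c("OH_ONLY", "OH_IPSO_ORTHO", "FULL_RING")) {
      expect_lt(tyrosine_subset_asa(st_buried$atoms, p, s), 5)
    }
  }
})
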