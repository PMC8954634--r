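toy_psms <- function() {
  data.frame(
    spectrum_id = sprintf("s%d", 1:5),
    is_human = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    delta_fwd_rev_score = c(3.2, 0, 5.1, -0.1, 1.4),
    stringsAsFactors = FALSE
  )
}

toy_sites <- function() {
  data.frame(
    accession = c("P1", "P1", "P1", "P2", "P2", "X1"),
    position = c(10L, 10L, 22L, 7L, 31L, 4L),
    is_human = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    best_delta_fwd_rev = c(3.1, 1.2, -2.0, 4.4, 2.2, 9.9),
    fully_localized = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    silac_state = c("heavy", "heavy", "heavy", "light", "heavy", "heavy"),
    stringsAsFactors = FALSE
  )
}

test_that("PSM filtering drops non-human and negative-score rows, keeping the zero boundary", {
  out <- filter_psm_table(toy_psms())
  expect_equal(out$spectrum_id, c("s1", "s2", "s5"))  # score 0 retained
  expect_equal(nrow(filter_psm_table(toy_psms()[0, ])), 0L)
  expect_error(filter_psm_table(toy_psms()[, -2]), "is_human")
  # idempotent and order-preserving
  expect_identical(filter_psm_table(out), out)
})

test_that("site filtering applies the cascade and deduplicates keeping the best score", {
  out <- filter_site_table(toy_sites())
  # survivors: P1@10 (deduped to score 3.1); others fail one rule each
  expect_equal(nrow(out), 1L)
  expect_equal(out$accession, "P1")
  expect_equal(out$position, 10L)
  expect_equal(out$best_delta_fwd_rev, 3.1)
  expect_identical(filter_site_table(out), out)

  res <- filter_site_table(toy_sites(), counts = TRUE)
  expect_equal(res$removed,
               list(nonhuman = 1L, decoy_score = 1L, unlocalized = 1L,
                    light_state = 1L, redundant = 1L))
  expect_equal(nrow(toy_sites()) - Reduce(`+`, res$removed), nrow(res$sites))
})

test_that("filter composition equals conjunction filtering and never increases counts", {
  sim <- simulate_experiment(small_config(seed = 19))
  s <- sim$site_table
  once <- filter_site_table(s)
  keep <- s$is_human & s$best_delta_fwd_rev >= 0 & as.logical(s$fully_localized) &
    s$silac_state != "light"
  conj <- s[keep, ]
  # same surviving keys before dedup; dedup yields unique keys
  expect_setequal(paste(once$accession, once$position),
                  unique(paste(conj$accession, conj$position)))
  expect_false(any(duplicated(paste(once$accession, once$position))))
  expect_lte(nrow(once), nrow(s))
})

test_that("replicate-overlap sets are nested and match enumeration", {
  sets <- list(c("s1", "s2"), c("s2", "s3"), "s3")
  ov <- site_replicate_overlap(sets)
  expect_equal(ov$min_1, c("s1", "s2", "s3"))
  expect_equal(ov$min_2, c("s2", "s3"))
  expect_equal(ov$min_3, character(0))
  for (k in 2:3) expect_true(all(ov[[k]] %in% ov[[k - 1]]))

  same <- site_replicate_overlap(list(c("a", "b"), c("a", "b"), c("a", "b")))
  expect_equal(same$min_1, same$min_3)
  single <- site_replicate_overlap(list(c("x", "y")))
  expect_equal(single$min_1, c("x", "y"))
})

test_that("per-replicate splitting projects filtered sites onto their replicate sets", {
  sim <- simulate_experiment(small_config(seed = 23))
  per <- split_sites_by_replicate(sim$site_table)
  expect_setequal(names(per),
                  unique(unlist(strsplit(sim$site_table$replicates, ";"))))
  filtered <- filter_site_table(sim$site_table)
  for (r in names(per)) {
    in_rep <- vapply(strsplit(filtered$replicates, ";"),
                     function(x) r %in% x, logical(1))
    expect_identical(per[[r]], filtered[in_rep, ])
  }
  # union over replicates recovers every surviving site
  expect_setequal(unlist(lapply(per, function(d)
    paste(d$accession, d$position, sep = "@"))),
    paste(filtered$accession, filtered$position, sep = "@"))
})

test_that("Spectrum Mill column aliases map onto canonical names", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  df <- data.frame(accession_number = "P1", position = 5, is_human = TRUE,
                   bestDeltaForwardReverseScore = 2.5,
                   Best_numLocalizedVMsites_y = TRUE, silac_state = "heavy")
  write_tsv_table(df, tmp)
  back <- read_tsv_table(tmp, aliases = spectrum_mill_aliases())
  expect_true(all(c("accession", "best_delta_fwd_rev", "fully_localized") %in%
                    names(back)))
  expect_equal(nrow(filter_site_table(back)), 1L)
})
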