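make_pl <- function(mz, intensity, assigned = numeric(0), bio = TRUE,
                    id = "s1") {
  list(spectrum_id = id, precursor_mz = 500, mz = mz, intensity = intensity,
       assigned_mz = assigned, is_biotinylated = bio)
}

test_that("top-fragment extraction keeps the most intense peaks with the low-m/z tie rule", {
  pl <- make_pl(c(100, 200, 300), c(5, 1, 3))
  expect_equal(extract_top_fragments(pl, 25)$mz, c(100, 200, 300))

  set.seed(31)
  mz <- sort(runif(30, 100, 1000))
  int <- sample(seq(1, 30))  # distinct intensities
  got <- extract_top_fragments(make_pl(mz, int), 25)
  want <- sort(mz[order(-int)[1:25]])
  expect_equal(got$mz, want)

  tie <- make_pl(c(200, 300), c(7, 7))
  expect_equal(extract_top_fragments(tie, 1)$mz, 200)
  expect_error(extract_top_fragments(make_pl(numeric(0), numeric(0)), 5),
               "empty")
})

test_that("unassigned-mass selection respects the matching tolerance", {
  expect_length(unassigned_masses(c(100, 200), c(100, 200), 0.01), 0L)
  expect_equal(unassigned_masses(c(100, 200), numeric(0), 0.01), c(100, 200))
  # within tolerance of an assignment -> excluded; just outside -> kept
  expect_length(unassigned_masses(497.2220, 497.2217, 0.01), 0L)
  expect_equal(unassigned_masses(497.2350, 497.2217, 0.01), 497.2350)
})

test_that("marker frequencies are exact per-class presence fractions", {
  bio <- lapply(1:4, function(i) make_pl(c(150.005, 300), c(10, 5),
                                         id = paste0("b", i)))
  oth <- lapply(1:5, function(i) make_pl(c(300), c(5), bio = FALSE,
                                         id = paste0("o", i)))
  cand <- marker_frequencies(c(bio, oth), bin_width = 0.01)
  row150 <- cand[cand$mz_bin_center > 150 & cand$mz_bin_center < 150.01, ]
  expect_equal(row150$freq_biotin, 1.0)
  expect_equal(row150$freq_other, 0.0)
  expect_equal(row150$n_biotin_spectra, 4L)
  expect_equal(row150$n_other_spectra, 5L)

  # a peak present twice in one spectrum's bin counts once
  dup <- make_pl(c(150.002, 150.004), c(9, 9), id = "b9")
  cand2 <- marker_frequencies(c(bio, list(dup), oth), bin_width = 0.01)
  row2 <- cand2[cand2$mz_bin_center > 150 & cand2$mz_bin_center < 150.01, ]
  expect_equal(row2$freq_biotin, 1.0)

  expect_error(marker_frequencies(bio), "non-biotinylated")
  expect_error(marker_frequencies(oth), "no biotinylated")
})

test_that("frequencies are invariant to spectrum order", {
  set.seed(33)
  sp <- simulate_peaklists(40, 40, seed = 12)$peaklists
  a <- marker_frequencies(sp)
  b <- marker_frequencies(sp[sample(length(sp))])
  expect_equal(a[order(a$mz_bin_center), ], b[order(b$mz_bin_center), ],
               ignore_attr = TRUE)
})

test_that("candidate screening thresholds and ranks candidates", {
  cand <- data.frame(
    mz_bin_center = c(100.005, 200.005, 300.005),
    freq_biotin = c(0.9, 0.5, 0.7),
    freq_other = c(0.01, 0.02, 0.3),
    n_biotin_spectra = 100, n_other_spectra = 100
  )
  all_ranked <- screen_candidates(cand, 0, 1)
  # ranked by freq_biotin - freq_other: 0.89 > 0.48 > 0.40
  expect_equal(all_ranked$mz_bin_center, c(100.005, 200.005, 300.005))
  expect_equal(all_ranked$rank, 1:3)
  scr <- screen_candidates(cand, min_freq_biotin = 0.6, max_freq_other = 0.05)
  expect_equal(scr$mz_bin_center, 100.005)
  expect_equal(nrow(screen_candidates(cand, min_freq_biotin = 0.95,
                                      max_freq_other = 0.05)), 0L)
})

test_that("planted marker prevalences are recovered within binomial 99% CI", {
  mzs <- predicted_marker_ions(biotin_phenol_mod())
  sp <- simulate_peaklists(500, 500, marker_mzs = mzs,
                           prevalence_biotin = 0.8, prevalence_other = 0.02,
                           seed = 17)$peaklists
  is_bio <- vapply(sp, `[[`, logical(1), "is_biotinylated")
  # spectrum-level presence of an unassigned peak within 0.01 Da of each
  # predicted marker (window semantics absorb the 5 ppm jitter)
  present <- vapply(sp, function(pl) {
    un <- unassigned_masses(extract_top_fragments(pl, 25)$mz, pl$assigned_mz)
    vapply(mzs, function(m) any(abs(un - m) <= 0.01), logical(1))
  }, logical(length(mzs)))
  for (k in seq_along(mzs)) {
    for (cls in c(TRUE, FALSE)) {
      p0 <- if (cls) 0.8 else 0.02
      n <- sum(is_bio == cls)
      phat <- mean(present[k, is_bio == cls])
      expect_lt(abs(phat - p0), 2.576 * sqrt(p0 * (1 - p0) / n) + 1e-9)
    }
  }
})

test_that("the three planted biotin-phenol markers rank top of the screen", {
  mzs <- predicted_marker_ions(biotin_phenol_mod())
  sp <- simulate_peaklists(200, 200, marker_mzs = mzs, seed = 23)$peaklists
  cand <- marker_frequencies(sp)
  scr <- screen_candidates(cand, predicted_mzs = mzs)
  expect_gte(nrow(scr), 3L)
  expect_true(all(scr$predicted_match[1:3] != ""))
  expect_setequal(as.numeric(scr$predicted_match[1:3]), round(unname(mzs), 5))
})

test_that("MGF and assignment files round-trip through the readers", {
  sp <- simulate_peaklists(3, 2, seed = 40)$peaklists
  tmp_mgf <- tempfile(fileext = ".mgf")
  tmp_tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_mgf, tmp_tsv)), add = TRUE)
  write_mgf(sp, tmp_mgf)
  write_assignments(sp, tmp_tsv)
  back <- join_peaklists(read_mgf(tmp_mgf), read_assignments(tmp_tsv))
  expect_length(back, 5L)
  expect_equal(back[[1]]$spectrum_id, sp[[1]]$spectrum_id)
  expect_equal(back[[1]]$mz, sp[[1]]$mz, tolerance = 1e-5)
  expect_equal(back[[1]]$assigned_mz, sp[[1]]$assigned_mz, tolerance = 1e-5)
  expect_equal(vapply(back, `[[`, logical(1), "is_biotinylated"),
               vapply(sp, `[[`, logical(1), "is_biotinylated"))
})
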