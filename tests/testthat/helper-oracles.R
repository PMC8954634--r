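# Independent oracles used to check implementations by a different route.

# Tryptic digest by exhaustive substring enumeration: a substring is a valid
# fragment iff it starts at the sequence start or right after a K/R, ends at
# the sequence end or on a K/R, and carries at most max_missed internal K/R.
digest_bruteforce <- function(sequence, max_missed) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  out <- list()
  for (s in seq_len(n)) {
    if (s > 1 && !(aa[s - 1] %in% c("K", "R"))) next
    for (e in s:n) {
      if (e < n && !(aa[e] %in% c("K", "R"))) next
      internal <- if (e > s) sum(aa[s:(e - 1)] %in% c("K", "R")) else 0L
      if (internal <= max_missed) {
        out[[length(out) + 1L]] <- c(s, e, internal)
      }
    }
  }
  m <- do.call(rbind, out)
  data.frame(peptide = substring(sequence, m[, 1], m[, 2]),
             start = m[, 1], end = m[, 2], n_missed = m[, 3])
}

# ROC cutoff by direct per-threshold recount over distinct ratio values.
roc_bruteforce <- function(ratio, label) {
  n_tp <- sum(label == "TP")
  n_fp <- sum(label == "FP")
  thr <- sort(unique(ratio), decreasing = TRUE)
  diffs <- vapply(thr, function(t) {
    sum(ratio >= t & label == "TP") / n_tp -
      sum(ratio >= t & label == "FP") / n_fp
  }, numeric(1))
  best <- which.max(diffs)  # first index = highest threshold on ties
  list(cutoff = thr[best], max = diffs[best])
}

# Accessible area of one of two identical spheres (radius r, probe p,
# center distance d): full expanded sphere minus the buried spherical cap.
two_sphere_asa_analytic <- function(r, probe, d) {
  R <- r + probe
  if (d >= 2 * R) return(4 * pi * R^2)
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# Dense Monte-Carlo ASA with random (non-lattice) directions: an
# implementation-independent numeric oracle for small atom sets.
asa_montecarlo <- function(xyz, radii, probe, n = 2e5, seed = 42) {
  set.seed(seed)
  expanded <- radii + probe
  vapply(seq_len(nrow(xyz)), function(i) {
    dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- sweep(dirs * expanded[i], 2, xyz[i, ], "+")
    blocked <- rep(FALSE, n)
    for (j in seq_len(nrow(xyz))[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      blocked <- blocked | d2 < expanded[j]^2
    }
    4 * pi * expanded[i]^2 * mean(!blocked)
  }, numeric(1))
}

# Small labeled protein table used across enrichment tests.
toy_protein_table <- function() {
  data.frame(
    accession = sprintf("P%02d", 1:6),
    gene_symbol = sprintf("G%02d", 1:6),
    hl_ratio = c(8, 4, 2, 1, 0.5, 6),
    n_distinct_peptides = c(5, 3, 1, 4, 6, 2),
    n_ratios = c(4, 3, 2, 2, 5, 2),
    is_contaminant = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    is_human = TRUE,
    stringsAsFactors = FALSE
  )
}

# A small fast configuration for generator-heavy tests.
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_tp_proteins = 15L, n_fp_proteins = 30L,
             n_unknown_proteins = 20L, protein_length = 200L,
             n_noise_peaks = 10L, ...)
}
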