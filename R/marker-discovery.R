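#' Extract the most abundant fragment ions of a spectrum
#'
#' Returns the `top_n` highest-intensity peaks; ties are broken in favor of
#' the lower m/z. If the spectrum has fewer peaks than requested, all are
#' returned.
#'
#' @param peaklist A peak list: list with numeric `mz` and `intensity`.
#' @param top_n Number of peaks to keep (default 25).
#' @return data.frame with columns `mz`, `intensity`, sorted by m/z.
#' @export
extract_top_fragments <- function(peaklist, top_n = 25L) {
  stopifnot(top_n >= 1L)
  mz <- peaklist$mz
  intensity <- peaklist$intensity
  if (length(mz) == 0L) stop("empty peak list")
  keep <- order(-intensity, mz)[seq_len(min(top_n, length(mz)))]
  keep <- sort(keep)
  data.frame(mz = mz[keep], intensity = intensity[keep])
}

#' Fragment masses not assigned to canonical ion types
#'
#' @param fragment_mz Numeric vector of fragment m/z values.
#' @param assigned_mz Numeric vector of m/z values assigned to canonical
#'   peptide fragment ion types during identification.
#' @param tol_da Matching tolerance in Da (default 0.01): fragments within
#'   `tol_da` of any assigned m/z are considered assigned.
#' @return The unassigned fragment m/z values, in input order.
#' @export
unassigned_masses <- function(fragment_mz, assigned_mz, tol_da = 0.01) {
  stopifnot(tol_da > 0)
  if (length(fragment_mz) == 0L || length(assigned_mz) == 0L) {
    return(fragment_mz)
  }
  keep <- vapply(fragment_mz, function(m) {
    min(abs(assigned_mz - m)) > tol_da
  }, logical(1))
  fragment_mz[keep]
}

mz_bin <- function(mz, bin_width) as.integer(floor(mz / bin_width))

#' Per-class frequencies of unassigned fragment masses
#'
#' For every spectrum, the `top_n` most abundant fragments are extracted
#' and those matching an assigned canonical ion are removed; the surviving
#' masses are binned on a fixed grid of width `bin_width` anchored at 0.
#' Each bin's frequency is the fraction of spectra of that class containing
#' at least one unassigned peak in the bin (a spectrum counts once per bin
#' regardless of peak multiplicity), so frequencies are exact rational
#' counts.
#'
#' @param peaklists List of peak lists, each with `mz`, `intensity`,
#'   `assigned_mz` and logical `is_biotinylated`.
#' @param bin_width Bin width in Da (default 0.01).
#' @param top_n Fragments extracted per spectrum (default 25).
#' @param tol_da Assignment-matching tolerance (default `bin_width`).
#' @return data.frame of candidates: `mz_bin_center`, `freq_biotin`,
#'   `freq_other`, `n_biotin_spectra`, `n_other_spectra`.
#' @export
marker_frequencies <- function(peaklists, bin_width = 0.01, top_n = 25L,
                               tol_da = bin_width) {
  is_bio <- vapply(peaklists, `[[`, logical(1), "is_biotinylated")
  n_bio <- sum(is_bio); n_oth <- sum(!is_bio)
  if (n_bio == 0L) stop("no biotinylated spectra in input")
  if (n_oth == 0L) stop("no non-biotinylated spectra in input")
  per_spectrum_bins <- lapply(peaklists, function(pl) {
    frag <- extract_top_fragments(pl, top_n)
    un <- unassigned_masses(frag$mz, pl$assigned_mz, tol_da)
    unique(mz_bin(un, bin_width))
  })
  bio_bins <- unlist(per_spectrum_bins[is_bio])
  oth_bins <- unlist(per_spectrum_bins[!is_bio])
  all_bins <- sort(unique(c(bio_bins, oth_bins)))
  k_bio <- tabulate(match(bio_bins, all_bins), nbins = length(all_bins))
  k_oth <- tabulate(match(oth_bins, all_bins), nbins = length(all_bins))
  data.frame(
    mz_bin_center = (all_bins + 0.5) * bin_width,
    freq_biotin = k_bio / n_bio,
    freq_other = k_oth / n_oth,
    n_biotin_spectra = n_bio,
    n_other_spectra = n_oth
  )
}

#' Screen marker-ion candidates
#'
#' Keeps candidate bins whose frequency among biotinylated spectra is at
#' least `min_freq_biotin` and among non-biotinylated spectra at most
#' `max_freq_other`, ranked by `freq_biotin - freq_other` descending. The
#' screening thresholds are configurable; no canonical values exist, so
#' the defaults are deliberately permissive.
#'
#' @param candidates Output of [marker_frequencies()].
#' @param min_freq_biotin,max_freq_other Screening thresholds in \[0, 1\].
#' @param predicted_mzs Optional numeric vector of theoretically predicted
#'   marker m/z values (e.g. [predicted_marker_ions()]); candidates whose
#'   bin contains a predicted value get an annotation column.
#' @param bin_width Bin width of the candidate grid, used only for the
#'   predicted-m/z annotation (default 0.01).
#' @return The screened candidates, ranked, with a `rank` column (and
#'   `predicted_match` when `predicted_mzs` is given).
#' @export
screen_candidates <- function(candidates, min_freq_biotin = 0.5,
                              max_freq_other = 0.05, predicted_mzs = NULL,
                              bin_width = 0.01) {
  stopifnot(min_freq_biotin >= 0, min_freq_biotin <= 1,
            max_freq_other >= 0, max_freq_other <= 1)
  keep <- candidates$freq_biotin >= min_freq_biotin &
    candidates$freq_other <= max_freq_other
  out <- candidates[keep, , drop = FALSE]
  out <- out[order(-(out$freq_biotin - out$freq_other), out$mz_bin_center), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(predicted_mzs) && nrow(out) > 0L) {
    out$predicted_match <- vapply(out$mz_bin_center, function(ctr) {
      hit <- which(mz_bin(predicted_mzs, bin_width) ==
                     mz_bin(ctr, bin_width))
      if (length(hit) > 0L) sprintf("%.5f", predicted_mzs[hit[1]]) else ""
    }, character(1))
  }
  rownames(out) <- NULL
  out
}
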