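#' In-silico tryptic digestion ("trypsin allow P")
#'
#' Cleaves after every lysine or arginine, including when the next residue
#' is proline ("allow P" specificity), and returns every fragment carrying
#' up to `max_missed` missed cleavage sites.
#'
#' @param sequence Protein sequence (standard one-letter codes).
#' @param max_missed Maximum number of internal missed cleavage sites
#'   (default 4).
#' @return A data.frame with columns `peptide`, `start`, `end` (1-based
#'   inclusive coordinates in the protein) and `n_missed`.
#' @examples
#' tryptic_digest("AKPB", max_missed = 0)  # cleaves K|P
#' @export
tryptic_digest <- function(sequence, max_missed = 4L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  stopifnot(max_missed >= 0L)
  aa <- strsplit(sequence, "")[[1]]
  # cleavage happens after position p for every K/R (even before P)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]       # a terminal K/R cleaves nothing
  bounds <- c(0L, cut_after, n)               # fragment boundaries
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    for (j in (i + 1L):jmax) {
      out[[length(out) + 1L]] <- c(bounds[i] + 1L, bounds[j], j - i - 1L)
    }
  }
  m <- do.call(rbind, out)
  data.frame(
    peptide = substring(sequence, m[, 1], m[, 2]),
    start = m[, 1], end = m[, 2], n_missed = m[, 3],
    stringsAsFactors = FALSE
  )
}
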