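#' Filter a peptide-spectrum-match table
#'
#' Removes PSMs from non-human proteins and PSMs with a delta
#' forward-reverse score below zero (a score of exactly 0 is retained).
#' Order-preserving and idempotent.
#'
#' @param psms PSM table with columns `is_human` and
#'   `delta_fwd_rev_score`.
#' @return The filtered table.
#' @export
filter_psm_table <- function(psms) {
  require_columns(psms, c("is_human", "delta_fwd_rev_score"), "PSM table")
  out <- psms[psms$is_human & psms$delta_fwd_rev_score >= 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a biotinylation-site table
#'
#' Applies, in order: drop non-human entries; drop sites with best delta
#' forward-reverse score below zero; drop sites that are not fully
#' localized; drop sites identified in the SILAC light state; remove
#' redundant entries by deduplicating on (accession, position), keeping
#' the row with the highest best delta forward-reverse score. Idempotent.
#'
#' @param sites Site table with columns `accession`, `position`,
#'   `is_human`, `best_delta_fwd_rev`, `fully_localized`, `silac_state`.
#' @param counts If TRUE, return a list with the filtered table and the
#'   number of rows removed by each rule.
#' @return The filtered table (or a list when `counts = TRUE`).
#' @export
filter_site_table <- function(sites, counts = FALSE) {
  require_columns(sites, c("accession", "position", "is_human",
                           "best_delta_fwd_rev", "fully_localized",
                           "silac_state"), "site table")
  removed <- integer(0)
  step <- function(df, keep, rule) {
    removed[[rule]] <<- nrow(df) - sum(keep)
    df[keep, , drop = FALSE]
  }
  out <- step(sites, sites$is_human, "nonhuman")
  out <- step(out, out$best_delta_fwd_rev >= 0, "decoy_score")
  out <- step(out, as.logical(out$fully_localized), "unlocalized")
  out <- step(out, out$silac_state != "light", "light_state")
  # dedup on (accession, position), best score first; stable for ties
  if (nrow(out) > 0L) {
    ord <- order(out$accession, out$position, -out$best_delta_fwd_rev)
    out <- out[ord, , drop = FALSE]
    key <- paste(out$accession, out$position, sep = "@")
    dup <- duplicated(key)
    removed[["redundant"]] <- sum(dup)
    out <- out[!dup, , drop = FALSE]
  } else {
    removed[["redundant"]] <- 0L
  }
  rownames(out) <- NULL
  if (counts) list(sites = out, removed = as.list(removed)) else out
}

site_keys <- function(sites) {
  unique(paste(sites$accession, sites$position, sep = "@"))
}

#' Replicate-overlap site sets
#'
#' For k = 1..n, the set of (accession, position) site keys present in at
#' least k of the per-replicate site sets. The sets are nested:
#' `set[[k + 1]]` is a subset of `set[[k]]`.
#'
#' @param per_replicate_sites List (one element per replicate) of site
#'   tables (with `accession`, `position`) or of precomputed
#'   `"accession@position"` key vectors.
#' @return Named list `min_1` .. `min_n` of sorted key vectors.
#' @export
site_replicate_overlap <- function(per_replicate_sites) {
  stopifnot(length(per_replicate_sites) >= 1L)
  keysets <- lapply(per_replicate_sites, function(x) {
    if (is.data.frame(x)) site_keys(x) else unique(as.character(x))
  })
  counts <- table(unlist(keysets))
  n <- length(keysets)
  out <- lapply(seq_len(n), function(k) sort(names(counts)[counts >= k]))
  names(out) <- paste0("min_", seq_len(n))
  out
}

#' Split a filtered site table into per-replicate site tables
#'
#' Applies the filter cascade, then projects the surviving sites onto each
#' replicate via the `replicates` set column (semicolon-separated replicate
#' identifiers), yielding the per-replicate site tables that feed
#' [site_replicate_overlap()].
#'
#' @param sites Site table with a `replicates` column.
#' @return Named list of filtered per-replicate site tables.
#' @export
split_sites_by_replicate <- function(sites) {
  require_columns(sites, "replicates", "site table")
  filtered <- filter_site_table(sites)
  repsets <- strsplit(filtered$replicates, ";", fixed = TRUE)
  reps <- sort(unique(unlist(strsplit(sites$replicates, ";", fixed = TRUE))))
  stats::setNames(lapply(reps, function(r) {
    filtered[vapply(repsets, function(x) r %in% x, logical(1)), , drop = FALSE]
  }), reps)
}
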