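#' Filter a per-replicate protein quantification table
#'
#' Removes known contaminant proteins, non-human entries, proteins
#' identified by fewer than `min_peptides` distinct peptides, and (when
#' `require_ratio`) proteins with fewer than two observed SILAC ratios.
#'
#' @param table Protein table with columns `accession`, `gene_symbol`,
#'   `hl_ratio`, `n_distinct_peptides`, `n_ratios`, `is_contaminant`,
#'   `is_human`.
#' @param min_peptides Minimum distinct peptides (default 2).
#' @param require_ratio Require at least two observed SILAC ratios
#'   (default TRUE).
#' @return The filtered table, order preserved.
#' @export
filter_protein_table <- function(table, min_peptides = 2L, require_ratio = TRUE) {
  require_columns(table, c("accession", "gene_symbol", "hl_ratio",
                           "n_distinct_peptides", "n_ratios",
                           "is_contaminant", "is_human"), "protein table")
  keep <- !table$is_contaminant & table$is_human &
    table$n_distinct_peptides >= min_peptides
  if (require_ratio) keep <- keep & table$n_ratios >= 2L
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label proteins as TP/FP/unknown by gene symbol
#'
#' Gene symbol is the unique identifier for matching against the curated
#' true-positive and false-positive lists.
#'
#' @param table Protein table with `gene_symbol`.
#' @param tp_genes,fp_genes Character vectors of gene symbols.
#' @return The table with a `label` column (`"TP"`, `"FP"`, `"unknown"`).
#' @export
label_proteins <- function(table, tp_genes, fp_genes) {
  require_columns(table, "gene_symbol", "protein table")
  overlap <- intersect(tp_genes, fp_genes)
  if (length(overlap) > 0L) {
    stop("gene(s) present in both TP and FP lists: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  table$label <- "unknown"
  table$label[table$gene_symbol %in% tp_genes] <- "TP"
  table$label[table$gene_symbol %in% fp_genes] <- "FP"
  table
}

#' Normalize SILAC ratios to the false-positive median
#'
#' Divides every H/L ratio by the median H/L ratio of FP-labeled proteins
#' and takes log2, centering the distribution of nonspecific binders at
#' log2(H/L) = 0. For an even FP count the median is the midpoint of the
#' two central values.
#'
#' @param table Labeled protein table (one replicate) with `hl_ratio` and
#'   `label`.
#' @return The table with a `norm_log2_ratio` column.
#' @export
normalize_ratios <- function(table) {
  require_columns(table, c("hl_ratio", "label"), "protein table")
  fp <- table$hl_ratio[table$label == "FP"]
  if (length(fp) == 0L) stop("no FP-labeled proteins: normalizer undefined")
  stopifnot(all(table$hl_ratio > 0))
  table$norm_log2_ratio <- log2(table$hl_ratio / stats::median(fp))
  table
}

#' ROC cutoff at maximum TPR minus FPR
#'
#' Ranks proteins by normalized log2 ratio in descending order and walks
#' the ranking: at each rank, TPR is the cumulative TP count over total
#' TPs and FPR the cumulative FP count over total FPs
#' (unknown-label proteins occupy ranks but change neither rate). The
#' cutoff is the normalized ratio at the rank maximizing TPR - FPR; a tie
#' in the maximum is broken toward the higher ratio (more stringent
#' cutoff). Tied ratio values are only eligible as a cutoff at the last
#' rank of the tie group, so the cutoff is always attainable as a closed
#' threshold.
#'
#' @param table Normalized, labeled protein table (one replicate) with
#'   `norm_log2_ratio` and `label`.
#' @return A `roc_result` list: `roc` (ranked data.frame with `tpr`,
#'   `fpr`), `cutoff`, `tpr_minus_fpr_max`, and `degenerate` (TRUE when
#'   the maximum TPR - FPR is <= 0, i.e. the ranking carries no signal).
#' @export
roc_cutoff <- function(table) {
  require_columns(table, c("norm_log2_ratio", "label"), "protein table")
  n_tp <- sum(table$label == "TP")
  n_fp <- sum(table$label == "FP")
  if (n_tp == 0L) stop("no TP-labeled proteins among ranked entries")
  if (n_fp == 0L) stop("no FP-labeled proteins among ranked entries")
  ord <- order(-table$norm_log2_ratio)
  ranked <- table[ord, , drop = FALSE]
  tpr <- cumsum(ranked$label == "TP") / n_tp
  fpr <- cumsum(ranked$label == "FP") / n_fp
  r <- ranked$norm_log2_ratio
  # a rank is a valid threshold only if the next ratio is strictly lower
  valid <- c(r[-length(r)] > r[-1], TRUE)
  diff_vals <- tpr - fpr
  diff_valid <- ifelse(valid, diff_vals, -Inf)
  best <- which.max(diff_valid)  # first index: highest ratio wins ties
  ranked$tpr <- tpr
  ranked$fpr <- fpr
  structure(list(
    roc = ranked,
    cutoff = r[best],
    tpr_minus_fpr_max = diff_vals[best],
    degenerate = diff_vals[best] <= 0
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> cutoff = %.4f (max TPR-FPR = %.4f)%s\n",
              x$cutoff, x$tpr_minus_fpr_max,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Proteins at or above the ROC cutoff
#'
#' Closed threshold: a protein whose normalized ratio equals the cutoff is
#' above cutoff.
#'
#' @param table Normalized protein table with `accession` and
#'   `norm_log2_ratio`.
#' @param cutoff Normalized log2 ratio cutoff.
#' @return Character vector of accessions.
#' @export
above_cutoff <- function(table, cutoff) {
  require_columns(table, c("accession", "norm_log2_ratio"), "protein table")
  unique(table$accession[table$norm_log2_ratio >= cutoff])
}

#' Cross replicates: retain proteins above cutoff in enough replicates
#'
#' @param above_cutoff_sets List of character vectors (one per replicate)
#'   of accessions above cutoff.
#' @param min_replicates Minimum number of replicates a protein must appear
#'   in (default 2).
#' @return Character vector of retained accessions (sorted).
#' @export
cross_replicates <- function(above_cutoff_sets, min_replicates = 2L) {
  if (min_replicates > length(above_cutoff_sets)) {
    stop("min_replicates exceeds the number of replicate sets")
  }
  counts <- table(unlist(lapply(above_cutoff_sets, unique)))
  sort(names(counts)[counts >= min_replicates])
}

#' Per-replicate enrichment analysis with replicate crossing
#'
#' Runs the full protein-level enrichment branch: filter each replicate's
#' table, label against the TP/FP gene lists, normalize to the FP median,
#' select the ROC cutoff, and cross replicates.
#'
#' @param protein_table Multi-replicate protein table (column `replicate`).
#' @param tp_genes,fp_genes Gene lists.
#' @param min_peptides,min_replicates See [filter_protein_table()] and
#'   [cross_replicates()].
#' @return A list: `per_replicate` (named list of `roc_result`s plus the
#'   normalized tables), `above_cutoff` (named list of accession sets),
#'   `final_set` (crossed accessions), `degenerate` (any replicate flagged).
#' @export
enrichment_analysis <- function(protein_table, tp_genes, fp_genes,
                                min_peptides = 2L, min_replicates = 2L) {
  require_columns(protein_table, "replicate", "protein table")
  reps <- unique(protein_table$replicate)
  per_rep <- list()
  sets <- list()
  for (r in reps) {
    tab <- protein_table[protein_table$replicate == r, , drop = FALSE]
    tab <- filter_protein_table(tab, min_peptides = min_peptides)
    tab <- label_proteins(tab, tp_genes, fp_genes)
    tab <- normalize_ratios(tab)
    roc <- roc_cutoff(tab)
    per_rep[[r]] <- list(table = tab, roc = roc)
    sets[[r]] <- above_cutoff(tab, roc$cutoff)
  }
  list(
    per_replicate = per_rep,
    above_cutoff = sets,
    final_set = cross_replicates(sets, min_replicates),
    degenerate = any(vapply(per_rep, function(x) x$roc$degenerate, logical(1)))
  )
}
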