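## Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Error if `df` lacks any of `cols`, naming the missing ones.
require_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read or write a canonical-dialect TSV table
#'
#' All tables in this package are UTF-8 tab-separated files with a header
#' row and no quoting or row names. `read_tsv_table()` optionally maps
#' export-dialect column names to the canonical ones via an alias map.
#'
#' @param path File path.
#' @param aliases Named character vector mapping source column name ->
#'   canonical column name (see [spectrum_mill_aliases()]), or `NULL`.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path, aliases = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(aliases)) {
    hit <- names(df) %in% names(aliases)
    names(df)[hit] <- unname(aliases[names(df)[hit]])
  }
  df
}

#' @rdname read_tsv_table
#' @param df Data frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Column aliases for Spectrum Mill-style exports
#'
#' Maps the column names used in Spectrum Mill peptide/site reports to this
#' package's canonical column names, so exported tables can be read with
#' `read_tsv_table(path, aliases = spectrum_mill_aliases())`.
#'
#' @return Named character vector (source name -> canonical name).
#' @export
spectrum_mill_aliases <- function() {
  c(
    bestDeltaForwardReverseScore = "best_delta_fwd_rev",
    deltaForwardReverseScore = "delta_fwd_rev_score",
    Best_numLocalizedVMsites_y = "fully_localized",
    accessionNumber_VMsites_numVMsitesPresent_numVMsitesLocalizedBest_earliestVMsiteAA_latestVMsiteAA = "site_key",
    accession_number = "accession",
    geneSymbol = "gene_symbol"
  )
}

# Deterministic JSON writer: stable key order as supplied, no timestamps.
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
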