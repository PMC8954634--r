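#' Read and write MS/MS peak lists in MGF format
#'
#' Minimal Mascot Generic Format support for the peak lists this pipeline
#' consumes: one `BEGIN IONS`/`END IONS` block per spectrum with `TITLE`
#' and `PEPMASS` headers followed by `m/z intensity` pairs. Fragment-ion
#' assignments and the biotinylated flag travel in a separate TSV
#' (see [write_assignments()]), mirroring how search-engine ion-assignment
#' exports accompany raw peak lists.
#'
#' @param peaklists A list of peak lists as produced by
#'   [simulate_experiment()]: each a list with `spectrum_id`, `mz`,
#'   `intensity`, `precursor_mz`, `assigned_mz`, `is_biotinylated`.
#' @param path File path.
#' @return `read_mgf()` returns a list of peak lists (without assignment
#'   metadata); `write_mgf()` returns `path` invisibly.
#' @export
write_mgf <- function(peaklists, path) {
  blocks <- vapply(peaklists, function(pl) {
    paste0(
      "BEGIN IONS\n",
      "TITLE=", pl$spectrum_id, "\n",
      sprintf("PEPMASS=%.5f\n", pl$precursor_mz),
      "CHARGE=2+\n",
      paste(sprintf("%.5f %.2f", pl$mz, pl$intensity), collapse = "\n"),
      "\nEND IONS"
    )
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' @rdname write_mgf
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced blocks")
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    headers <- grep("=", block, fixed = TRUE, value = TRUE)
    peaks <- block[!grepl("=", block, fixed = TRUE)]
    kv <- strsplit(headers, "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    mat <- do.call(rbind, lapply(strsplit(trimws(peaks), "\\s+"), as.numeric))
    list(
      spectrum_id = unname(vals[keys == "TITLE"]),
      precursor_mz = as.numeric(vals[keys == "PEPMASS"]),
      mz = mat[, 1],
      intensity = mat[, 2]
    )
  })
}

#' Read and write per-spectrum fragment-ion assignment tables
#'
#' The assignment TSV carries, per spectrum, the m/z values assigned to
#' canonical peptide fragment ion types during database search and whether
#' the spectrum was matched to a biotinylated peptide.
#'
#' @param peaklists List of peak lists with `spectrum_id`, `assigned_mz`,
#'   `is_biotinylated`.
#' @param path File path.
#' @return `read_assignments()` returns a data.frame with columns
#'   `spectrum_id`, `is_biotinylated`, and list-column `assigned_mz`.
#' @export
write_assignments <- function(peaklists, path) {
  df <- data.frame(
    spectrum_id = vapply(peaklists, `[[`, character(1), "spectrum_id"),
    is_biotinylated = vapply(peaklists, `[[`, logical(1), "is_biotinylated"),
    assigned_mzs = vapply(peaklists, function(pl) {
      paste(sprintf("%.5f", pl$assigned_mz), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  write_tsv_table(df, path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- read_tsv_table(path)
  require_columns(df, c("spectrum_id", "is_biotinylated", "assigned_mzs"),
                  "assignment table")
  df$assigned_mz <- lapply(strsplit(as.character(df$assigned_mzs), ";"),
                           function(x) as.numeric(x[nzchar(x)]))
  df$assigned_mzs <- NULL
  df
}

#' Reassemble full peak lists from an MGF file plus its assignment TSV
#'
#' @param spectra Output of [read_mgf()].
#' @param assignments Output of [read_assignments()].
#' @return List of complete peak lists (with `assigned_mz` and
#'   `is_biotinylated`) ready for [marker_frequencies()].
#' @export
join_peaklists <- function(spectra, assignments) {
  idx <- match(vapply(spectra, `[[`, character(1), "spectrum_id"),
               assignments$spectrum_id)
  if (anyNA(idx)) stop("assignment table is missing spectra present in MGF")
  lapply(seq_along(spectra), function(i) {
    pl <- spectra[[i]]
    pl$assigned_mz <- assignments$assigned_mz[[idx[i]]]
    pl$is_biotinylated <- assignments$is_biotinylated[idx[i]]
    pl
  })
}
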