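#' Mitochondrial evidence for a protein
#'
#' A protein has mitochondrial evidence if any of three independent
#' categories fires: (i) the case-insensitive substring `"mitoch"` occurs
#' in its annotation text (looked up by accession or gene name);
#' (ii) it appears in a supplied mitochondrial protein list; (iii) it
#' appears in the supplied true-positive list. The flag is the OR of the
#' categories; each category is reported separately.
#'
#' @param protein Accession or gene name.
#' @param annotations Annotation table with columns `accession`,
#'   `gene_name`, `annotation_text` and logical columns `in_mito_list_a`,
#'   `in_mito_list_b`.
#' @param mito_list,tp_list Optional character vectors of
#'   accessions/genes.
#' @return List with `has_evidence` and logical `categories`
#'   (`annotation`, `mito_list`, `tp_list`).
#' @export
has_mito_evidence <- function(protein, annotations, mito_list = character(0),
                              tp_list = character(0)) {
  require_columns(annotations, c("accession", "gene_name", "annotation_text"),
                  "annotation table")
  row <- annotation_row(protein, annotations)
  cat_ann <- FALSE
  cat_list <- protein %in% mito_list
  if (!is.null(row)) {
    cat_ann <- grepl("mitoch", row$annotation_text, ignore.case = TRUE)
    for (col in c("in_mito_list_a", "in_mito_list_b")) {
      if (col %in% names(annotations) && isTRUE(row[[col]])) cat_list <- TRUE
    }
    cat_list <- cat_list || row$accession %in% mito_list ||
      row$gene_name %in% mito_list
  }
  cat_tp <- protein %in% tp_list ||
    (!is.null(row) && (row$accession %in% tp_list || row$gene_name %in% tp_list))
  list(
    has_evidence = cat_ann || cat_list || cat_tp,
    categories = c(annotation = cat_ann, mito_list = cat_list, tp_list = cat_tp)
  )
}

annotation_row <- function(protein, annotations) {
  hit <- which(annotations$accession == protein |
                 annotations$gene_name == protein)
  if (length(hit) == 0L) return(NULL)
  annotations[hit[1], , drop = FALSE]
}

#' Transmembrane evidence for a protein
#'
#' TRUE if the UniProt-style transmembrane annotation text contains the
#' substring `"TRANSMEM"` (case-insensitive) or the precomputed TMHMM
#' evidence flag is set.
#'
#' @param protein Accession or gene name.
#' @param annotations Annotation table with `transmembrane_text` and
#'   optionally `tmhmm_evidence`.
#' @return Logical flag.
#' @export
is_transmembrane <- function(protein, annotations) {
  require_columns(annotations, c("accession", "gene_name",
                                 "transmembrane_text"), "annotation table")
  row <- annotation_row(protein, annotations)
  if (is.null(row)) return(FALSE)
  grepl("TRANSMEM", row$transmembrane_text, ignore.case = TRUE) ||
    ("tmhmm_evidence" %in% names(row) && isTRUE(row$tmhmm_evidence))
}

#' Map a biotinylation site to a topological domain
#'
#' Returns the side label of the unique domain whose 1-based inclusive
#' span contains the site position, or `"unknown"` when no domain does.
#'
#' @param position 1-based residue position of the site.
#' @param domains Domain table for the site's protein: columns `start`,
#'   `end`, `side`. Domains must not overlap.
#' @return Side label (e.g. `"matrix"`, `"intermembrane"`, `"membrane"`)
#'   or `"unknown"`.
#' @export
map_site_to_domain <- function(position, domains) {
  if (nrow(domains) == 0L) return("unknown")
  require_columns(domains, c("start", "end", "side"), "domain table")
  stopifnot(all(domains$start <= domains$end))
  ord <- order(domains$start)
  d <- domains[ord, , drop = FALSE]
  if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)])) {
    stop("overlapping topology domains")
  }
  hit <- which(d$start <= position & d$end >= position)
  if (length(hit) == 0L) "unknown" else d$side[hit]
}

#' Per-site topology report
#'
#' Annotates every filtered biotinylation site with its protein's
#' mitochondrial and transmembrane evidence and, where topology domains
#' are known, the domain side the site maps to; tallies sites per side.
#'
#' @param sites Filtered site table (`accession`, `position`).
#' @param annotations Annotation table.
#' @param domains Domain table (`accession`, `start`, `end`, `side`).
#' @param mito_list,tp_list Passed to [has_mito_evidence()].
#' @return A list: `per_site` (data.frame with `mito_evidence`,
#'   `transmembrane`, `known_topology`, `side`) and `side_counts` (named
#'   integer vector over sides of sites on known-topology proteins).
#' @export
topology_report <- function(sites, annotations, domains,
                            mito_list = character(0), tp_list = character(0)) {
  require_columns(sites, c("accession", "position"), "site table")
  if (nrow(sites) == 0L) {
    return(list(per_site = cbind(sites, mito_evidence = logical(0),
                                 transmembrane = logical(0),
                                 known_topology = logical(0),
                                 side = character(0)),
                side_counts = integer(0)))
  }
  per <- sites
  per$mito_evidence <- vapply(sites$accession, function(a) {
    has_mito_evidence(a, annotations, mito_list, tp_list)$has_evidence
  }, logical(1))
  per$transmembrane <- vapply(sites$accession, function(a) {
    is_transmembrane(a, annotations)
  }, logical(1))
  per$known_topology <- sites$accession %in% unique(domains$accession)
  per$side <- vapply(seq_len(nrow(sites)), function(i) {
    if (!per$known_topology[i]) return("unknown")
    map_site_to_domain(sites$position[i],
                       domains[domains$accession == sites$accession[i], ,
                               drop = FALSE])
  }, character(1))
  counted <- per$side[per$known_topology]
  side_counts <- if (length(counted) > 0L) {
    tab <- table(counted)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  rownames(per) <- NULL
  list(per_site = per, side_counts = side_counts)
}
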