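#' Run the full synthetic proximity-labeling analysis pipeline
#'
#' Orchestrates the stages end to end on synthetic data: simulate inputs,
#' discover diagnostic marker ions from the MS2 peak lists, run the
#' protein-level SILAC enrichment branch (ROC cutoff + replicate
#' crossing), run the peptide/site-level branch (filter cascades +
#' replicate overlap), map filtered sites to membrane topology, and score
#' tyrosine surface exposure on a toy structure. Every stage writes its
#' outputs under `out_dir`; downstream stages read the files the upstream
#' stages wrote, so the run also exercises all I/O paths. Outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "markers", "enrich", "sites", "topology", "exposure")`.
#'   Later stages require the files of the stages they depend on.
#' @param bin_width,top_n,min_freq_biotin,max_freq_other Marker-discovery
#'   parameters (see [marker_frequencies()], [screen_candidates()]).
#' @param min_replicates Replicate-crossing threshold for both branches.
#' @param exposure_subset,exposure_threshold,fn_margin,probe_radius,n_points
#'   Surface-exposure parameters (see [tyrosine_subset_asa()],
#'   [score_exposure()]).
#' @param n_tyrosines,buried_fraction Toy-structure parameters.
#' @return A `run_report` list: per-stage record counts in/out, parameters,
#'   warnings, elapsed seconds (in memory only; the serialized
#'   `run_report.json` omits timing so outputs stay deterministic), and
#'   `final_protein_set` / `final_site_keys` for branch comparison.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         stages = c("simulate", "markers", "enrich", "sites",
                                    "topology", "exposure"),
                         bin_width = 0.01, top_n = 25L,
                         min_freq_biotin = 0.5, max_freq_other = 0.05,
                         min_replicates = 2L,
                         exposure_subset = "OH_IPSO_ORTHO",
                         exposure_threshold = 5, fn_margin = 3,
                         probe_radius = 1.4, n_points = 960L,
                         n_tyrosines = 10L, buried_fraction = 0.3) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("missing input for stage '", stage, "': ", path)
    }
    path
  }
  report <- list(stages = list())
  t0 <- proc.time()[["elapsed"]]
  record <- function(stage, n_in, n_out, params = list(), warnings = character(0)) {
    report$stages[[stage]] <<- list(
      records_in = n_in, records_out = n_out,
      removed = n_in - n_out, params = params, warnings = warnings
    )
  }

  final_protein_set <- NULL
  final_site_keys <- NULL

  ## --- simulate -------------------------------------------------------
  if ("simulate" %in% stages) {
    sim <- simulate_experiment(config)
    seqs <- Biostrings::AAStringSet(stats::setNames(sim$proteins$sequence,
                                                    sim$proteins$accession))
    Biostrings::writeXStringSet(seqs, p("proteins.fasta"))
    write_tsv_table(sim$protein_table, p("protein_table.tsv"))
    write_tsv_table(sim$site_table, p("site_table.tsv"))
    write_tsv_table(sim$psm_table, p("psm_table.tsv"))
    write_mgf(sim$peaklists, p("spectra.mgf"))
    write_assignments(sim$peaklists, p("assignments.tsv"))
    write_tsv_table(sim$annotations, p("annotations.tsv"))
    write_tsv_table(sim$domains, p("domains.tsv"))
    writeLines(sim$tp_genes, p("tp_genes.txt"))
    writeLines(sim$fp_genes, p("fp_genes.txt"))
    write_json_report(list(
      protein_labels = sim$ground_truth$protein_labels,
      true_sites = sim$ground_truth$true_sites,
      marker_mzs = sim$ground_truth$marker_mzs
    ), p("ground_truth.json"))
    structure_sim <- simulate_structure(n_tyrosines, buried_fraction,
                                        seed = config$seed)
    write_structure_pdb(structure_sim$atoms, p("structure.pdb"))
    tagged <- with_seed(config$seed + 1L, {
      gt <- structure_sim$ground_truth
      gt$position[stats::runif(nrow(gt)) < ifelse(gt$buried, 0.1, 0.8)]
    })
    write_tsv_table(data.frame(position = structure_sim$ground_truth$position,
                               buried = structure_sim$ground_truth$buried,
                               tagged = structure_sim$ground_truth$position %in% tagged),
                    p("structure_sites.tsv"))
    record("simulate",
           n_in = 0L,
           n_out = nrow(sim$protein_table) + nrow(sim$site_table) +
             nrow(sim$psm_table),
           params = unclass(config))
  }

  ## --- marker discovery ----------------------------------------------
  if ("markers" %in% stages) {
    spectra <- read_mgf(need(p("spectra.mgf"), "markers"))
    assignments <- read_assignments(need(p("assignments.tsv"), "markers"))
    peaklists <- join_peaklists(spectra, assignments)
    candidates <- marker_frequencies(peaklists, bin_width = bin_width,
                                     top_n = top_n)
    screened <- screen_candidates(candidates,
                                  min_freq_biotin = min_freq_biotin,
                                  max_freq_other = max_freq_other,
                                  predicted_mzs = predicted_marker_ions(biotin_phenol_mod()),
                                  bin_width = bin_width)
    write_tsv_table(screened, p("marker_candidates.tsv"))
    record("markers", n_in = length(peaklists), n_out = nrow(screened),
           params = list(bin_width = bin_width, top_n = top_n,
                         min_freq_biotin = min_freq_biotin,
                         max_freq_other = max_freq_other))
  }

  ## --- protein-level enrichment branch --------------------------------
  if ("enrich" %in% stages) {
    protein_table <- read_tsv_table(need(p("protein_table.tsv"), "enrich"))
    tp_genes <- readLines(need(p("tp_genes.txt"), "enrich"))
    fp_genes <- readLines(need(p("fp_genes.txt"), "enrich"))
    enr <- enrichment_analysis(protein_table, tp_genes, fp_genes,
                               min_replicates = min_replicates)
    for (r in names(enr$per_replicate)) {
      roc <- enr$per_replicate[[r]]$roc
      write_tsv_table(
        roc$roc[, c("accession", "gene_symbol", "label", "norm_log2_ratio",
                    "tpr", "fpr")],
        p(sprintf("roc_%s.tsv", r)))
    }
    writeLines(enr$final_set, p("enriched_proteins.txt"))
    final_protein_set <- enr$final_set
    record("enrich", n_in = nrow(protein_table),
           n_out = length(enr$final_set),
           params = list(min_replicates = min_replicates),
           warnings = if (enr$degenerate) "degenerate ROC in >=1 replicate"
           else character(0))
  }

  ## --- peptide/site branch --------------------------------------------
  if ("sites" %in% stages) {
    psms <- read_tsv_table(need(p("psm_table.tsv"), "sites"))
    fpsms <- filter_psm_table(psms)
    write_tsv_table(fpsms, p("filtered_psms.tsv"))
    sites <- read_tsv_table(need(p("site_table.tsv"), "sites"))
    res <- filter_site_table(sites, counts = TRUE)
    write_tsv_table(res$sites, p("filtered_sites.tsv"))
    per_rep <- split_sites_by_replicate(sites)
    overlap <- site_replicate_overlap(per_rep)
    write_json_report(list(
      psm_filter = list(records_in = nrow(psms), records_out = nrow(fpsms)),
      site_filter = list(records_in = nrow(sites),
                         records_out = nrow(res$sites),
                         removed_per_rule = res$removed),
      replicate_overlap_counts = lapply(overlap, length)
    ), p("site_filter_summary.json"))
    write_json_report(overlap, p("site_overlap_sets.json"))
    final_site_keys <- overlap[[min(min_replicates, length(overlap))]]
    record("sites", n_in = nrow(sites), n_out = nrow(res$sites),
           params = list(min_replicates = min_replicates))
  }

  ## --- topology mapping -----------------------------------------------
  if ("topology" %in% stages) {
    fsites <- read_tsv_table(need(p("filtered_sites.tsv"), "topology"))
    annotations <- read_tsv_table(need(p("annotations.tsv"), "topology"))
    domains <- read_tsv_table(need(p("domains.tsv"), "topology"))
    tp_genes <- readLines(need(p("tp_genes.txt"), "topology"))
    topo <- topology_report(fsites, annotations, domains, tp_list = tp_genes)
    write_tsv_table(topo$per_site, p("topology_sites.tsv"))
    write_json_report(list(side_counts = as.list(topo$side_counts)),
                      p("topology_summary.json"))
    record("topology", n_in = nrow(fsites), n_out = nrow(topo$per_site),
           params = list())
  }

  ## --- surface exposure -----------------------------------------------
  if ("exposure" %in% stages) {
    atoms <- read_structure_pdb(need(p("structure.pdb"), "exposure"))
    smap <- read_tsv_table(need(p("structure_sites.tsv"), "exposure"))
    asa <- vapply(smap$position, function(pos) {
      tyrosine_subset_asa(atoms, pos, subset = exposure_subset,
                          probe_radius = probe_radius, n_points = n_points)
    }, numeric(1))
    names(asa) <- as.character(smap$position)
    score <- score_exposure(as.character(smap$position[smap$tagged]), asa,
                            threshold = exposure_threshold,
                            fn_margin = fn_margin)
    write_tsv_table(data.frame(position = smap$position, tagged = smap$tagged,
                               asa = round(asa, 4)),
                    p("exposure_asa.tsv"))
    write_json_report(list(
      fp_score = score$fp_score,
      is_false_positive = score$is_false_positive,
      fn_flags = score$fn_flags,
      n_below_threshold = score$n_below_threshold,
      n_below_min_untagged = score$n_below_min_untagged,
      params = list(subset = exposure_subset, threshold = exposure_threshold,
                    fn_margin = fn_margin, probe_radius = probe_radius,
                    n_points = n_points)
    ), p("exposure_score.json"))
    record("exposure", n_in = nrow(smap), n_out = nrow(smap),
           params = list(subset = exposure_subset,
                         threshold = exposure_threshold))
  }

  report$final_protein_set <- final_protein_set
  report$final_site_keys <- final_site_keys
  write_json_report(report$stages, p("run_report.json"))
  report$elapsed_seconds <- proc.time()[["elapsed"]] - t0
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s in %6d  out %6d  removed %6d%s\n", s,
                st$records_in, st$records_out, st$removed,
                if (length(st$warnings) > 0)
                  paste0("  [", paste(st$warnings, collapse = "; "), "]")
                else ""))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_seconds))
  invisible(x)
}

#' Compare the protein-level and site-level branches
#'
#' The streptavidin-style protein branch and the anti-biotin site branch
#' identify overlapping but different protein sets; this reports their
#' intersection and differences at protein level.
#'
#' @param protein_set Accessions from the protein-level branch.
#' @param site_protein_set Accessions of proteins carrying sites from the
#'   site-level branch.
#' @return List with `overlap`, `only_protein_branch`, `only_site_branch`
#'   (sorted character vectors) and `counts`.
#' @export
compare_branches <- function(protein_set, site_protein_set) {
  protein_set <- unique(as.character(protein_set))
  site_protein_set <- unique(as.character(site_protein_set))
  overlap <- sort(intersect(protein_set, site_protein_set))
  only_p <- sort(setdiff(protein_set, site_protein_set))
  only_s <- sort(setdiff(site_protein_set, protein_set))
  list(
    overlap = overlap,
    only_protein_branch = only_p,
    only_site_branch = only_s,
    counts = c(overlap = length(overlap),
               only_protein_branch = length(only_p),
               only_site_branch = length(only_s))
  )
}
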