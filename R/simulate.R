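#' Configuration for a synthetic proximity-labeling experiment
#'
#' Bundles every knob of the synthetic-data generator. Defaults encode the
#' study conditions the pipeline is designed around: a three-replicate
#' SILAC design in which true-positive (TP) proteins are enriched in the
#' heavy channel (log2 H/L ~ N(2.0, 0.7)) over a background of
#' false-positive (FP) and unknown proteins (log2 H/L ~ N(0, 0.5)),
#' biotin-phenol deposited on tyrosines, MS2 spectra of biotinylated
#' peptides carrying the three diagnostic marker ions at high prevalence,
#' and site-report defects (decoy-favored, unlocalized, light-state,
#' redundant rows) planted at low rates to exercise every filter.
#'
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param n_tp_proteins,n_fp_proteins,n_unknown_proteins Protein counts per
#'   category (TP/FP lists are scaled-down stand-ins for curated lists).
#' @param tp_log2_ratio_mean,tp_log2_ratio_sd Log2 H/L distribution of TP
#'   proteins, drawn independently per replicate.
#' @param fp_log2_ratio_mean,fp_log2_ratio_sd Background log2 H/L
#'   distribution (FP and unknown proteins).
#' @param n_replicates Number of biological replicates (default 3).
#' @param biotin_site_rate Probability each tyrosine in a human protein
#'   carries a planted biotin-phenol site.
#' @param marker_prevalence_biotin,marker_prevalence_other Probability each
#'   marker ion appears in a biotinylated / non-biotinylated spectrum.
#' @param n_noise_peaks Unassigned noise peaks per spectrum.
#' @param decoy_rate,unlocalized_rate,light_state_rate Per-site probability
#'   of each planted defect (negative delta forward-reverse score;
#'   ambiguous localization; SILAC light-state identification).
#' @param redundant_rate Probability a site row is duplicated with a lower
#'   score (redundant-entry defect).
#' @param site_detect_rate Per-replicate detection probability of a site
#'   (at least one replicate is always kept).
#' @param protein_length Length of each simulated protein sequence.
#' @param contaminant_rate,nonhuman_rate Fraction of unknown-category
#'   proteins flagged as known contaminants / non-human entries.
#' @param underpowered_rate Probability that a non-TP protein-replicate row
#'   is reported with a single distinct peptide (exercises the two-peptide
#'   filter).
#' @param tm_fraction Fraction of TP proteins given transmembrane
#'   annotations and topology domains.
#' @param n_assigned_peaks Canonical (assigned) fragment peaks per spectrum.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_tp_proteins = 50L,
                       n_fp_proteins = 100L,
                       n_unknown_proteins = 100L,
                       tp_log2_ratio_mean = 2.0, tp_log2_ratio_sd = 0.7,
                       fp_log2_ratio_mean = 0.0, fp_log2_ratio_sd = 0.5,
                       n_replicates = 3L,
                       biotin_site_rate = 0.3,
                       marker_prevalence_biotin = 0.8,
                       marker_prevalence_other = 0.02,
                       n_noise_peaks = 20L,
                       decoy_rate = 0.1,
                       unlocalized_rate = 0.1,
                       light_state_rate = 0.1,
                       redundant_rate = 0.1,
                       site_detect_rate = 0.8,
                       protein_length = 300L,
                       contaminant_rate = 0.05,
                       nonhuman_rate = 0.05,
                       underpowered_rate = 0.05,
                       tm_fraction = 0.4,
                       n_assigned_peaks = 8L) {
  cfg <- as.list(environment())
  probs <- c("biotin_site_rate", "marker_prevalence_biotin",
             "marker_prevalence_other", "decoy_rate", "unlocalized_rate",
             "light_state_rate", "redundant_rate", "site_detect_rate",
             "contaminant_rate", "nonhuman_rate", "underpowered_rate",
             "tm_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(p, " must be in [0, 1]")
  }
  counts <- c("n_tp_proteins", "n_fp_proteins", "n_unknown_proteins",
              "n_replicates", "n_noise_peaks", "protein_length",
              "n_assigned_peaks")
  for (k in counts) {
    if (cfg[[k]] < 0) stop(k, " must be non-negative")
  }
  if (cfg$n_tp_proteins + cfg$n_fp_proteins + cfg$n_unknown_proteins == 0L) {
    stop("configuration yields zero proteins")
  }
  if (cfg$n_replicates < 1L) stop("n_replicates must be at least 1")
  class(cfg) <- "sim_config"
  cfg
}

## Residue sampling weights: i.i.d. with K/R boosted so tryptic peptides
## average 7-30 residues, and Y at a typical proteome frequency.
RESIDUE_WEIGHTS <- local({
  w <- stats::setNames(rep(1, 20), names(RESIDUE_COMPOSITIONS))
  w["K"] <- 1.4; w["R"] <- 1.4; w["Y"] <- 0.9; w["P"] <- 1.1; w["C"] <- 0.5
  w / sum(w)
})

random_protein_sequence <- function(length) {
  paste(sample(names(RESIDUE_WEIGHTS), length, replace = TRUE,
               prob = RESIDUE_WEIGHTS), collapse = "")
}

#' Simulate MS2 peak lists with planted diagnostic marker ions
#'
#' Generates biotinylated and non-biotinylated spectra. Every spectrum has
#' canonical assigned fragment peaks and unassigned noise peaks; each
#' marker ion is additionally planted (as an unassigned peak) with the
#' class-specific prevalence, with a N(0, 5 ppm) relative m/z jitter and a
#' high intensity draw so markers survive top-N extraction.
#'
#' @param n_biotin,n_other Spectrum counts per class.
#' @param marker_mzs Numeric vector of marker-ion m/z values to plant
#'   (default: the three biotin-phenol markers).
#' @param prevalence_biotin,prevalence_other Per-marker planting
#'   probability in each class.
#' @param n_noise_peaks,n_assigned_peaks Peaks per spectrum.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param ids Optional character vector of spectrum ids
#'   (length `n_biotin + n_other`).
#' @return A list with `peaklists` (list of peak lists) and
#'   `planted` (data.frame: spectrum_id, one logical column per marker).
#' @export
simulate_peaklists <- function(n_biotin, n_other,
                               marker_mzs = predicted_marker_ions(biotin_phenol_mod()),
                               prevalence_biotin = 0.8,
                               prevalence_other = 0.02,
                               n_noise_peaks = 20L,
                               n_assigned_peaks = 8L,
                               seed = NULL,
                               ids = NULL) {
  marker_mzs <- unname(marker_mzs)
  run <- function() {
    n <- n_biotin + n_other
    is_bio <- rep(c(TRUE, FALSE), c(n_biotin, n_other))
    if (is.null(ids)) ids <- sprintf("spec%05d", seq_len(n))
    stopifnot(length(ids) == n)
    planted <- matrix(FALSE, n, length(marker_mzs))
    peaklists <- vector("list", n)
    for (i in seq_len(n)) {
      assigned <- sort(stats::runif(n_assigned_peaks, 200, 1400))
      noise <- stats::runif(n_noise_peaks, 100, 1500)
      prev <- if (is_bio[i]) prevalence_biotin else prevalence_other
      present <- stats::runif(length(marker_mzs)) < prev
      planted[i, ] <- present
      mk <- marker_mzs[present] * (1 + stats::rnorm(sum(present), 0, 5e-6))
      mz <- c(assigned, noise, mk)
      intensity <- c(stats::rlnorm(n_assigned_peaks, 5.0, 0.8),
                     stats::rlnorm(n_noise_peaks, 3.5, 0.8),
                     stats::rlnorm(sum(present), 7.0, 0.4))
      o <- order(mz)
      peaklists[[i]] <- list(
        spectrum_id = ids[i],
        precursor_mz = stats::runif(1, 400, 1200),
        mz = mz[o],
        intensity = intensity[o],
        assigned_mz = assigned,
        is_biotinylated = is_bio[i]
      )
    }
    planted <- as.data.frame(planted)
    names(planted) <- sprintf("marker_%.5f", marker_mzs)
    planted <- cbind(data.frame(spectrum_id = ids, stringsAsFactors = FALSE),
                     planted)
    list(peaklists = peaklists, planted = planted)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete proximity-labeling experiment
#'
#' Generates every input the downstream pipeline consumes, with known
#' ground truth: protein sequences, a per-replicate protein quantification
#' table with planted SILAC structure, a biotinylation-site table with
#' planted defects, a PSM table, MS2 peak lists with planted marker ions,
#' a UniProt-style annotation table with topology domains, and TP/FP gene
#' lists.
#'
#' @param config A [sim_config()].
#' @return A list with elements `config`, `proteins` (per-protein metadata
#'   and sequences), `protein_table`, `site_table`, `psm_table`,
#'   `peaklists`, `annotations`, `domains`, `tp_genes`, `fp_genes`, and
#'   `ground_truth` (protein labels, true clean sites, planted markers,
#'   ground-truth domain side per site).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  reps <- paste0("R", seq_len(cfg$n_replicates))

  ## --- proteins -------------------------------------------------------
  n_total <- cfg$n_tp_proteins + cfg$n_fp_proteins + cfg$n_unknown_proteins
  category <- rep(c("TP", "FP", "unknown"),
                  c(cfg$n_tp_proteins, cfg$n_fp_proteins, cfg$n_unknown_proteins))
  proteins <- data.frame(
    accession = sprintf("SP%05d", seq_len(n_total)),
    gene_symbol = sprintf("GN%04d", seq_len(n_total)),
    category = category,
    stringsAsFactors = FALSE
  )
  proteins$is_human <- TRUE
  proteins$is_contaminant <- FALSE
  unk <- which(proteins$category == "unknown")
  if (length(unk) > 0L) {
    proteins$is_human[unk] <- stats::runif(length(unk)) >= cfg$nonhuman_rate
    proteins$is_contaminant[unk] <-
      proteins$is_human[unk] & (stats::runif(length(unk)) < cfg$contaminant_rate)
  }
  proteins$accession[!proteins$is_human] <-
    sub("^SP", "XX_", proteins$accession[!proteins$is_human])
  proteins$sequence <- vapply(seq_len(n_total), function(i)
    random_protein_sequence(cfg$protein_length), character(1))

  tp_genes <- proteins$gene_symbol[proteins$category == "TP"]
  fp_genes <- proteins$gene_symbol[proteins$category == "FP"]

  ## --- protein quantification table (per replicate) -------------------
  pt <- expand.grid(idx = seq_len(n_total), replicate = reps,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  is_tp_row <- proteins$category[pt$idx] == "TP"
  log2_ratio <- ifelse(is_tp_row,
                       stats::rnorm(nrow(pt), cfg$tp_log2_ratio_mean, cfg$tp_log2_ratio_sd),
                       stats::rnorm(nrow(pt), cfg$fp_log2_ratio_mean, cfg$fp_log2_ratio_sd))
  n_pep <- sample(2:12, nrow(pt), replace = TRUE)
  weak <- !is_tp_row & stats::runif(nrow(pt)) < cfg$underpowered_rate
  n_pep[weak] <- 1L
  protein_table <- data.frame(
    accession = proteins$accession[pt$idx],
    gene_symbol = proteins$gene_symbol[pt$idx],
    replicate = pt$replicate,
    hl_ratio = 2^log2_ratio,
    n_distinct_peptides = n_pep,
    n_ratios = pmin(n_pep, sample(2:8, nrow(pt), replace = TRUE)),
    is_contaminant = proteins$is_contaminant[pt$idx],
    is_human = proteins$is_human[pt$idx],
    stringsAsFactors = FALSE
  )

  ## --- true biotinylation sites ---------------------------------------
  site_rows <- list()
  true_sites <- list()
  for (i in seq_len(n_total)) {
    if (!proteins$is_human[i]) next
    ypos <- which(strsplit(proteins$sequence[i], "")[[1]] == "Y")
    if (length(ypos) == 0L) next
    hit <- ypos[stats::runif(length(ypos)) < cfg$biotin_site_rate]
    for (p in hit) {
      seen <- stats::runif(cfg$n_replicates) < cfg$site_detect_rate
      if (!any(seen)) seen[sample.int(cfg$n_replicates, 1L)] <- TRUE
      defect_decoy <- stats::runif(1) < cfg$decoy_rate
      defect_unloc <- stats::runif(1) < cfg$unlocalized_rate
      defect_light <- stats::runif(1) < cfg$light_state_rate
      true_sites[[length(true_sites) + 1L]] <- data.frame(
        accession = proteins$accession[i],
        gene_symbol = proteins$gene_symbol[i],
        position = p,
        n_replicates_observed = sum(seen),
        decoy = defect_decoy, unlocalized = defect_unloc, light = defect_light,
        clean = !(defect_decoy || defect_unloc || defect_light),
        stringsAsFactors = FALSE
      )
      score <- if (defect_decoy) -stats::runif(1, 0.1, 5) else stats::runif(1, 0.5, 15)
      row <- data.frame(
        accession = proteins$accession[i],
        gene_symbol = proteins$gene_symbol[i],
        residue = "Y",
        position = p,
        replicates = paste(reps[seen], collapse = ";"),
        silac_state = if (defect_light) "light" else "heavy",
        best_delta_fwd_rev = score,
        fully_localized = !defect_unloc,
        is_human = TRUE,
        stringsAsFactors = FALSE
      )
      site_rows[[length(site_rows) + 1L]] <- row
      if (stats::runif(1) < cfg$redundant_rate) {
        dup <- row
        dup$best_delta_fwd_rev <- score - stats::runif(1, 0.01, 0.4)
        site_rows[[length(site_rows) + 1L]] <- dup
      }
    }
  }
  site_table <- if (length(site_rows) > 0L) {
    do.call(rbind, site_rows)
  } else {
    data.frame(accession = character(), gene_symbol = character(),
               residue = character(), position = integer(),
               replicates = character(), silac_state = character(),
               best_delta_fwd_rev = numeric(), fully_localized = logical(),
               is_human = logical(), stringsAsFactors = FALSE)
  }
  true_sites <- if (length(true_sites) > 0L) do.call(rbind, true_sites) else
    data.frame(accession = character(), gene_symbol = character(),
               position = integer(), n_replicates_observed = integer(),
               decoy = logical(), unlocalized = logical(), light = logical(),
               clean = logical(), stringsAsFactors = FALSE)

  ## --- PSM table -------------------------------------------------------
  digests <- new.env(parent = emptyenv())
  peptide_for <- function(idx, position = NULL) {
    key <- as.character(idx)
    dg <- digests[[key]]
    if (is.null(dg)) {
      dg <- tryptic_digest(proteins$sequence[idx], max_missed = 2L)
      dg <- dg[nchar(dg$peptide) >= 6 & nchar(dg$peptide) <= 30, , drop = FALSE]
      digests[[key]] <- dg
    }
    if (nrow(dg) == 0L) return(NULL)
    cand <- if (is.null(position)) dg else
      dg[dg$start <= position & dg$end >= position, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[sample.int(nrow(cand), 1L), , drop = FALSE]
  }

  psm_rows <- list()
  make_psm <- function(idx, replicate, silac_state, score, biotin_position) {
    pep <- peptide_for(idx, biotin_position)
    if (is.null(pep)) return(NULL)
    data.frame(
      spectrum_id = NA_character_,
      peptide = pep$peptide,
      accession = proteins$accession[idx],
      gene_symbol = proteins$gene_symbol[idx],
      is_human = proteins$is_human[idx],
      delta_fwd_rev_score = score,
      silac_state = silac_state,
      replicate = replicate,
      is_biotinylated = !is.null(biotin_position),
      mod = if (is.null(biotin_position)) "" else
        sprintf("Y%d:biotin-phenol", biotin_position),
      stringsAsFactors = FALSE
    )
  }
  # one biotinylated PSM per site per replicate in which it was observed
  uniq_sites <- site_table[!duplicated(paste(site_table$accession,
                                             site_table$position)), ,
                           drop = FALSE]
  if (nrow(uniq_sites) > 0L) {
    acc_idx <- match(uniq_sites$accession, proteins$accession)
    for (k in seq_len(nrow(uniq_sites))) {
      for (r in strsplit(uniq_sites$replicates[k], ";")[[1]]) {
        psm <- make_psm(acc_idx[k], r,
                        uniq_sites$silac_state[k],
                        uniq_sites$best_delta_fwd_rev[k],
                        uniq_sites$position[k])
        if (!is.null(psm)) psm_rows[[length(psm_rows) + 1L]] <- psm
      }
    }
  }
  n_biotin_psms <- length(psm_rows)
  # matched number of non-biotinylated PSMs over random proteins
  n_other <- max(n_biotin_psms, 1L)
  other_idx <- sample.int(n_total, n_other, replace = TRUE)
  for (k in seq_len(n_other)) {
    score <- if (stats::runif(1) < cfg$decoy_rate) -stats::runif(1, 0.1, 5) else
      stats::runif(1, 0.5, 15)
    psm <- make_psm(other_idx[k], sample(reps, 1L), "heavy", score, NULL)
    if (!is.null(psm)) psm_rows[[length(psm_rows) + 1L]] <- psm
  }
  psm_table <- do.call(rbind, psm_rows)
  psm_table$spectrum_id <- sprintf("spec%05d", seq_len(nrow(psm_table)))

  ## --- MS2 peak lists --------------------------------------------------
  marker_mzs <- predicted_marker_ions(biotin_phenol_mod())
  bio_flags <- psm_table$is_biotinylated
  sim_spec <- simulate_peaklists(
    n_biotin = sum(bio_flags), n_other = sum(!bio_flags),
    marker_mzs = marker_mzs,
    prevalence_biotin = cfg$marker_prevalence_biotin,
    prevalence_other = cfg$marker_prevalence_other,
    n_noise_peaks = cfg$n_noise_peaks,
    n_assigned_peaks = cfg$n_assigned_peaks,
    ids = c(psm_table$spectrum_id[bio_flags], psm_table$spectrum_id[!bio_flags])
  )

  ## --- annotations and topology domains --------------------------------
  ann_rows <- list()
  dom_rows <- list()
  for (i in seq_len(n_total)) {
    if (!proteins$is_human[i]) next
    cat_i <- proteins$category[i]
    is_tm <- FALSE
    if (cat_i == "TP") {
      ann_text <- sample(c("Mitochondrion matrix.",
                           "Mitochondrion inner membrane.",
                           "Mitochondrion."), 1L)
      is_tm <- stats::runif(1) < cfg$tm_fraction
    } else {
      ann_text <- sample(c("Cytoplasm.", "Nucleus.", "Endoplasmic reticulum.",
                           "Chondrocyte mitosis regulator."), 1L,
                         prob = c(0.4, 0.4, 0.15, 0.05))
    }
    tm_text <- ""
    topo_text <- ""
    tmhmm <- FALSE
    if (is_tm) {
      # annotate via text or via the TMHMM evidence flag only
      if (stats::runif(1) < 0.8) tm_text <- "TRANSMEM 81..101; TRANSMEM 182..202"
      else tmhmm <- TRUE
      topo_text <- "TOPO_DOM 1..80 Mitochondrial matrix; TOPO_DOM 102..181 Mitochondrial intermembrane"
      L <- nchar(proteins$sequence[i])
      dom <- data.frame(
        accession = proteins$accession[i],
        start = c(1L, 81L, 102L, 182L, 203L),
        end = c(80L, 101L, 181L, 202L, L),
        side = c("matrix", "membrane", "intermembrane", "membrane", "matrix"),
        stringsAsFactors = FALSE
      )
      dom <- dom[dom$start <= L, , drop = FALSE]
      dom$end <- pmin(dom$end, L)
      dom_rows[[length(dom_rows) + 1L]] <- dom
    }
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      accession = proteins$accession[i],
      gene_name = proteins$gene_symbol[i],
      annotation_text = ann_text,
      transmembrane_text = tm_text,
      topology_text = topo_text,
      in_mito_list_a = cat_i == "TP" && stats::runif(1) < 0.5,
      in_mito_list_b = cat_i == "TP" && stats::runif(1) < 0.3,
      tmhmm_evidence = tmhmm,
      stringsAsFactors = FALSE
    )
  }
  annotations <- do.call(rbind, ann_rows)
  domains <- if (length(dom_rows) > 0L) do.call(rbind, dom_rows) else
    data.frame(accession = character(), start = integer(), end = integer(),
               side = character(), stringsAsFactors = FALSE)

  ## ground-truth domain side for every true site
  gt_side <- rep("unknown", nrow(true_sites))
  if (nrow(true_sites) > 0L && nrow(domains) > 0L) {
    for (k in seq_len(nrow(true_sites))) {
      d <- domains[domains$accession == true_sites$accession[k], , drop = FALSE]
      hit <- which(d$start <= true_sites$position[k] &
                   d$end >= true_sites$position[k])
      if (length(hit) == 1L) gt_side[k] <- d$side[hit]
    }
  }
  true_sites$domain_side <- gt_side

  list(
    config = cfg,
    proteins = proteins,
    protein_table = protein_table,
    site_table = site_table,
    psm_table = psm_table,
    peaklists = sim_spec$peaklists,
    annotations = annotations,
    domains = domains,
    tp_genes = tp_genes,
    fp_genes = fp_genes,
    ground_truth = list(
      protein_labels = proteins[, c("accession", "gene_symbol", "category",
                                    "is_human", "is_contaminant")],
      true_sites = true_sites,
      planted_markers = sim_spec$planted,
      marker_mzs = marker_mzs
    )
  )
}
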