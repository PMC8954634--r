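#!/usr/bin/env Rscript
# Stage 2: discover diagnostic marker ions from the MS2 peak lists.
#
# Contrasts the binned frequencies of unassigned fragment masses between
# biotinylated and non-biotinylated spectra and screens for bins that are
# frequent in the former and rare in the latter. The three biotin-phenol
# marker ions predicted from mass chemistry should top the ranking.

suppressPackageStartupMessages(library(biotinsites))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

run_pipeline(sim_config(seed = seed), out_dir = "results/pipeline",
             stages = "markers")
cand <- read_tsv_table("results/pipeline/marker_candidates.tsv")
cat("screened marker-ion candidates (top 5):\n")
print(utils::head(cand, 5))
cat("\npredicted biotin-phenol marker m/z:\n")
print(round(predicted_marker_ions(biotin_phenol_mod()), 5))
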