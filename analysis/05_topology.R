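#!/usr/bin/env Rscript
# Stage 5: mitochondrial membrane topology mapping.
#
# Each filtered biotinylation site is annotated with its protein's
# mitochondrial evidence (annotation substring "mitoch", curated lists,
# or TP list), transmembrane evidence (TRANSMEM text or TMHMM flag), and
# -- for proteins with known topology domains -- the compartment side
# (matrix / membrane / intermembrane) the site maps to.

suppressPackageStartupMessages(library(biotinsites))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

run_pipeline(sim_config(seed = seed), out_dir = "results/pipeline",
             stages = "topology")
topo <- read_tsv_table("results/pipeline/topology_sites.tsv")
cat(sprintf("sites with mitochondrial evidence: %d / %d\n",
            sum(topo$mito_evidence), nrow(topo)))
cat(sprintf("sites on transmembrane proteins: %d\n", sum(topo$transmembrane)))
summ <- jsonlite::read_json("results/pipeline/topology_summary.json")
cat("sites on known-topology proteins, by compartment side:\n")
print(unlist(summ$side_counts))
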