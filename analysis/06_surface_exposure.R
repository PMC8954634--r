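#!/usr/bin/env Rscript
# Stage 6: tyrosine surface-exposure scoring.
#
# Computes Shrake-Rupley accessible surface area for the hydroxyl/ipso/
# ortho atom subset of every tyrosine in the toy structure and applies the
# composite false-positive scoring: 10 points per tagged tyrosine below
# the 5 A^2 burial threshold, 1 point per tagged tyrosine above it but
# below the smallest untagged tyrosine; untagged tyrosines far more
# exposed than any tagged one are flagged as false negatives.

suppressPackageStartupMessages(library(biotinsites))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

run_pipeline(sim_config(seed = seed), out_dir = "results/pipeline",
             stages = "exposure")
asa <- read_tsv_table("results/pipeline/exposure_asa.tsv")
print(asa)
sc <- jsonlite::read_json("results/pipeline/exposure_score.json")
cat(sprintf("composite false-positive score: %d (final FP set: %s)\n",
            sc$fp_score, sc$is_false_positive))
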