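#!/usr/bin/env Rscript
# Stage 7: compare the two enrichment branches at protein level.
#
# The protein-level (streptavidin-style) branch yields proteins above the
# SILAC ROC cutoff; the site-level (anti-biotin) branch yields proteins
# carrying filtered biotinylation sites in >= 2 replicates. Their overlap
# and differences are reported.

suppressPackageStartupMessages(library(biotinsites))

protein_set <- readLines("results/pipeline/enriched_proteins.txt")
overlap_sets <- jsonlite::read_json("results/pipeline/site_overlap_sets.json",
                                    simplifyVector = TRUE)
site_proteins <- unique(sub("@.*$", "", overlap_sets$min_2))

cmp <- compare_branches(protein_set, site_proteins)
print(cmp$counts)
jsonlite::write_json(cmp, "results/pipeline/branch_comparison.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/pipeline/branch_comparison.json\n")
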