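Package: biotinsites
Title: Biotinylation-Site Analysis for APEX Proximity-Labeling Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of anti-biotin antibody / APEX2
    proximity-labeling proteomics experiments. Implements monoisotopic mass
    arithmetic for biotin and biotin-phenol modifications and their diagnostic
    marker ions, discovery of diagnostic marker ions from MS/MS peak lists,
    SILAC heavy/light ratio enrichment analysis with ROC-based cutoff
    selection and replicate crossing, filtering cascades for peptide-,
    protein- and biotinylation-site reports, mitochondrial membrane topology
    mapping of biotinylation sites, and Shrake-Rupley accessible-surface-area
    scoring of tyrosine surface exposure. A synthetic-data generator with
    known ground truth exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
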