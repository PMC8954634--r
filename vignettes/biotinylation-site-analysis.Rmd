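---
title: "Methods: biotinylation-site analysis for APEX proximity labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biotinylation-site analysis for APEX proximity labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biotinsites)
```

## The problem

APEX2 proximity labeling deposits a biotin-phenol adduct on tyrosines of
proteins near the peroxidase. Two complementary mass-spectrometry readouts
exist: enriching biotinylated *proteins* (streptavidin) and quantifying them
by SILAC heavy/light ratios, or enriching biotinylated *peptides*
(anti-biotin antibodies) and localizing the modification to individual
residues. This package implements the downstream computational analysis for
both branches — the mass chemistry, the statistics, and the filtering — and
a synthetic-data generator with known ground truth that exercises every
stage, so the methods can be validated without access to raw spectra.

## Mass chemistry

Modifications are elemental-composition gains. Monoisotopic masses are sums
of most-abundant-isotope element masses (C 12, H 1.00782503, N 14.00307401,
O 15.99491462, S 31.97207117; proton 1.00727646), which makes composition
arithmetic and mass arithmetic mutually consistent and exactly additive.
The biotin adduct is +C10H14N2O2S (226.0776 Da, lysine and peptide N
termini); the biotin-phenol adduct is +C18H23N3O3S (361.14601 Da,
tyrosine). Diagnostic marker ions are modeled as neutral losses from the
singly protonated, fully modified residue:

```{r markers}
predicted_marker_ions(biotin_phenol_mod())
```

A tolerance of 5e-4 Da is used whenever computed masses are compared to
values quoted at four to five decimals. The biotin-on-lysine marker ion
conventionally quoted at 329.1 m/z does not follow the same immonium-style
arithmetic (which gives 327.185); it is kept as a documented constant and
is never derived.

## Synthetic data: what it emulates, and what it does not

The generator (`sim_config()`, `simulate_experiment()`) is a first-class,
tested component. Its defaults define the study conditions used throughout
the tests:

* **SILAC structure.** 50 true-positive (TP), 100 false-positive (FP) and
  100 unknown proteins over three replicates. TP proteins draw
  log2(H/L) from N(2.0, 0.7) independently per replicate; FP and unknown
  proteins draw from N(0, 0.5). These values make the ROC separation
  strong but imperfect, so cutoff selection is actually exercised.
* **Sequences.** Proteins are i.i.d. random sequences (length 300) with
  lysine/arginine frequencies boosted so tryptic peptides mostly fall in
  the 7–30 residue range, and tyrosine at a typical proteome frequency.
  Digestion uses "trypsin allow P" specificity (cleavage after every K/R,
  even before proline) with up to four missed cleavages.
* **Sites.** Each tyrosine of a human protein carries a planted
  biotin-phenol site with probability 0.3; each site is observed per
  replicate with probability 0.8 (at least one replicate always). Defects
  are planted at site level at rate 0.1 each: decoy-favored score
  (negative delta forward-reverse), ambiguous localization, SILAC
  light-state identification; 10% of rows are duplicated with a lower
  score to exercise redundancy removal. Because defects are site-level
  properties, the filter cascade must recover exactly the defect-free
  site set — an exact, not statistical, acceptance check.
* **Spectra.** Every biotinylated PSM gets an MS2 peak list with 8
  "assigned" canonical fragments, 20 unassigned noise peaks, and each of
  the three marker ions planted with probability 0.8 (0.02 in
  non-biotinylated spectra), with N(0, 5 ppm) relative m/z jitter and a
  high intensity draw. Intensities are log-normal.
* **Structures.** Toy tyrosines are idealized side chains (hexagonal ring
  plus hydroxyl) spaced 60 Å apart; buried ones are enclosed in two
  concentric Fibonacci shells of carbon blockers (radii 4.3 and 6.5 Å)
  dense enough that all atom-subset exposures fall well below the burial
  threshold.

What the generator does **not** emulate: realistic b/y fragment ladders,
retention time, chimeric spectra, correlated replicate noise, shared
peptides between proteins, or real annotation text. Passing tests
therefore demonstrate that the *algorithms* are correct under controlled
conditions, not that the pipeline's statistical performance transfers
quantitatively to real instrument data.

## Marker-ion discovery

Following the screen's logic, the 25 most abundant fragments per spectrum
are kept (ties to the lower m/z), fragments within 0.01 Da of an assigned
canonical ion are removed, and the remainder are binned on a fixed 0.01 Da
grid anchored at zero. Frequencies are spectrum-level presence fractions
(a spectrum counts once per bin), hence exact rationals and bit-for-bit
reproducible. No canonical binning rule or screening thresholds exist for
this procedure, so: the bin width (0.01 Da) was chosen below instrument
accuracy at these m/z; the screen defaults
(`min_freq_biotin = 0.5`, `max_freq_other = 0.05`) are deliberately
permissive and configurable. One numerical consequence of a fixed grid:
the 497.2217 marker lies 0.0018 Da above a bin edge, so 5 ppm jitter sends
roughly a quarter of its occurrences into the neighboring bin. Its
dominant bin still contains the predicted m/z and outranks noise by two
orders of magnitude, but prevalence-recovery checks measure presence in a
±0.01 Da window around the predicted m/z rather than single-bin counts.
Chemical identification of candidate masses is out of scope; candidates
are annotated against the mass-chemistry predictions instead.

## Protein-level enrichment statistics

Per replicate: contaminants, non-human entries, proteins with fewer than
two distinct peptides, and (by default) fewer than two observed SILAC
ratios are removed; proteins are labeled TP/FP by gene-symbol match; every
H/L ratio is divided by the median FP ratio (midpoint convention for even
counts) and log2-transformed, centering nonspecific binders at 0; proteins
are ranked descending and the cutoff set at the maximum of TPR − FPR.
Decisions the procedure's description leaves open, resolved here as
package defaults:

* **Boundary equality.** "Above cutoff" is a closed threshold
  (ratio ≥ cutoff), so the reported cutoff value is itself reusable.
* **Ranking ties.** A tied ratio is only eligible as a cutoff at the last
  rank of its tie group (so the closed threshold reproduces the walk),
  and a tie in the maximum TPR − FPR is broken toward the higher ratio —
  the more stringent cutoff.
* **Unknown-label proteins** occupy ranks and are eligible for the final
  set but never move TPR or FPR.
* **Degeneracy.** If no rank achieves TPR − FPR > 0 the result is flagged
  degenerate rather than silently returned.

The final set crosses replicates: proteins above cutoff in at least two
of three. The implementation is verified against a brute-force
per-threshold recount on random instances, including tied ratios.

## Site filtering and replicate overlap

The site cascade applies, in order: non-human removal; negative
best-delta-forward-reverse removal (zero is retained, matching a strict
"< 0" rule); localization requirement; SILAC light-state removal; and
redundancy removal on the (accession, position) key. Whether redundancy
removal should keep the best-scoring or the first row is not specified
anywhere; the best-scoring row is kept, as the documented default. All
filters are idempotent and order-preserving, and replicate-overlap sets
are nested by construction. Sites carry their replicate membership as a
set, so replicate multiplicity is represented without duplicating rows —
row duplication is reserved for the redundant-entry defect the cascade is
supposed to remove.

## Topology mapping

Mitochondrial evidence is the OR of three independently reported
categories: the substring "mitoch" in the annotation text (matched by
accession or gene name), membership in a supplied mitochondrial list, and
membership in the TP list. Transmembrane evidence is the substring
"TRANSMEM" or a precomputed TMHMM flag. Substring matching is
case-insensitive — the annotation text mixes cases and an exact-case rule
is not recoverable. Site-to-domain mapping is 1-based inclusive interval
containment; overlapping domains are an input error, and a site outside
all domains maps to "unknown". The manual curation step of deciding which
proteins have "known" topology is not guessed at: any protein with domain
rows counts as known topology, and the per-site labels are exposed for
review.

## Surface exposure

No specific ASA algorithm is canonical for this scoring, so the package
uses Shrake–Rupley point sampling with a deterministic Fibonacci lattice
(default 960 points, probe 1.4 Å, Bondi radii C 1.70 / N 1.55 / O 1.52 /
S 1.80 Å). The lattice is oriented per atom in a local frame derived from
its nearest-neighbor geometry, which makes the computed areas exactly
invariant under rigid motions of the structure while staying fully
deterministic; accuracy is validated against the closed-form two-sphere
solution and a dense random-direction oracle (1% tolerance), and
convergence by doubling the point count (< 0.5% change).

Because the labeling radical reacts with the tyrosine ring and hydroxyl,
exposure is computed for atom subsets — hydroxyl only; hydroxyl + ipso +
ortho carbons (the default); or the full ring — always in the context of
all structure atoms. Which subset the burial threshold was historically
applied to is not stated, so the subset is an explicit required parameter.
Multiple structures of one protein are aggregated by maximum exposure
(crystal packing can artificially bury a surface residue); sites resolved
in no structure are excluded from scoring rather than imputed.

Scoring: each tagged tyrosine with ASA below 5 Å² scores 10; each tagged
tyrosine at or above the threshold but below the smallest untagged
tyrosine scores 1 (skipped when no untagged tyrosines exist, since the
minimum is undefined); proteins with a composite score above 10 form the
final false-positive set. The false-negative rule ("untagged
significantly more exposed than tagged") has no stated magnitude; it is
formalized as a configurable margin, default 3× the largest tagged ASA,
and explicitly documented as a stand-in.

## Pipeline determinism and problem sizes

`run_pipeline()` executes the stages in dependency order, each stage
reading the files the previous one wrote, and writes a run report whose
per-stage counts reconcile (out = in − removed, with per-rule removal
tallies for the site cascade). All randomness flows from the single
configuration seed through isolated RNG scopes, so two runs under one
seed produce byte-identical output files; for that reason wall-clock time
lives only in the in-memory report, never in the serialized JSON.

The default synthetic experiment (250 proteins, ~1,000 planted sites,
~4,500 spectra) runs a full pipeline pass in well under a minute; the
validation suite uses this size for the statistical checks (10 seeds) and
a smaller 65-protein configuration for structural and I/O checks. These
sizes were chosen as the smallest at which the statistical acceptance
bounds (≥90% TP recall, ≤10% FP admixture; top-3 marker ranking) are
comfortably non-trivial.

## Known limitations

* The ASA implementation targets the small structures this analysis
  scores (hundreds to a few thousand atoms); it is O(n · k) per structure
  in atoms × neighbors and not tuned for whole-proteome PDB sweeps.
* Peptide-to-structure position mapping, biological-assembly generation
  and homology modeling are out of scope; site positions must arrive
  pre-mapped to structure numbering.
* FDR-style autovalidation, localization scoring and search-engine
  re-scoring with marker ions are consumed as inputs (flags and scores),
  never recomputed.
* TP/FP gene lists are file inputs; the synthetic lists stand in for
  curated lists and are labeled as synthetic throughout.
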