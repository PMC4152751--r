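---
title: "Novel miRNA discovery from replicated serum small-RNA libraries"
author: "mirnovel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Novel miRNA discovery from replicated serum small-RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnovel)
```

# Overview

`mirnovel` implements the complete computational path from raw serum
small-RNA sequencing reads to novel miRNA candidates and biomarker
statistics, for a two-group design (cancer pools C1..C3 vs healthy
pools H1..H3). This vignette is the methods account: the models and
rules each stage applies, the tunable parameters and their defaults, the
design choices made where the method leaves room, what the synthetic
data emulate, and the limits of what the included checks demonstrate.

# Read cleaning and unique tags

Raw reads are the 5' insert followed by the 3' sequencing adapter.
`clean_reads()` locates the adapter as the *earliest* position where a
prefix of the adapter matches with at most one mismatch and at least
6 nt of overlap — a common small-RNA convention; the cleaning criteria
of published serum studies are rarely stated exactly, so ours are
declared rather than inferred. After trimming, a read is discarded when

* the insert is shorter than 18 nt with the adapter present (adapter
  dimers, the one contaminant class modelled),
* it is longer than 30 nt (including untrimmed reads with no adapter
  found),
* any base is below Phred 20, or any base is ambiguous (N).

One caveat is documented rather than hidden: partial-overlap matching
with mismatch tolerance is not strictly idempotent. An insert whose 3'
end coincidentally resembles the adapter prefix (probability about
$4^{-6}$ per terminal position) would be trimmed again on a second pass.
The tests assert exact idempotence on adapter-free inserts and that
re-cleaning can only touch reads carrying such coincidental suffixes.

`collapse_to_tags()` reduces libraries to unique tags with per-library
counts; all downstream stages work on tags, with read counts carried
along. Length distributions and shared-tag statistics
(`shared_tag_stats()`) follow: the shared fraction of unique tags is a
Jaccard index × 100, and the shared fraction of total reads uses the
combined clean reads of the pair as denominator — the denominators
differ between published reports, so the convention is stated in the
function documentation and output.

# Mapping and hierarchical annotation

`map_tags()` aligns tags to the genome by exact matching on both strands
(`Biostrings::matchPDict`). Exact matching replaces a seed-based short
read aligner deliberately: tags are 18–30 nt, the toy genome is small,
and a zero-mismatch policy makes the category-partition invariant exact.

`assign_category()` applies a fixed priority hierarchy —
miRNA > rRNA > tRNA > snRNA > snoRNA > scRNA > repeat > exon (sense,
antisense) > intron (sense, antisense) > unannotated — with an overlap
rule of at least 50% of the tag length inside the feature. Published
category tables leave both the priority order and the overlap threshold
implicit; the order above mirrors how such tables remove known classes
before declaring reads unannotated, and 50% is a round default that the
tests pin down. A multi-hit tag is counted once, toward the single
highest-priority category over all of its hits, which keeps the
categories mutually exclusive per tag and makes category counts plus
unmapped tags sum exactly to clean reads.

`summarize_categories()` reports per-library category read counts and
the unannotated percentage of clean reads at two decimals. Fed the
bundled six-library serum count table
(`inst/extdata/serum_library_categories.tsv`), it reproduces the
published percentages for five of the six libraries; the C3 column of
that table is internally inconsistent (its printed unannotated
percentage does not equal its own unannotated/clean ratio), so C3 is
flagged rather than reproduced.

# The folding engine

Candidate calling needs minimum-free-energy secondary structures on a
kcal/mol scale comparable with the classical −20 kcal/mol stability
threshold. `fold()` is a dynamic program over a nearest-neighbour
model:

* stacking free energies for Watson–Crick and GU wobble pairs
  (Turner-style constants at 37 °C, hard-coded as a 6×6 table with the
  strand-flip symmetry checked in the tests);
* hairpin, bulge and internal-loop initiation penalties tabulated for
  small sizes and extrapolated as $1.75\,RT\,\ln(n/n_0)$;
* an internal-loop asymmetry term (0.5 kcal/mol per unpaired-length
  difference, capped at 3);
* an affine multiloop penalty (closing 3.4, per branch 0.4, unpaired
  free);
* hairpin loops of at least 3 nt; two-way loops capped at 30 unpaired
  nucleotides (the standard restriction).

Partition-function ensembles, pseudoknots, dangling ends and temperature
dependence are out of scope. Energies returned are exact minima of this
model: for short sequences the test suite enumerates *every* valid
structure, scores each with `structure_energy()` (an independent
loop-decomposition evaluator), and requires equality with the DP — this
is the oracle for the engine. Equal-energy optima are resolved by a
fixed deterministic traceback order (two-way loops, then multiloops,
then hairpins, with the open chain preferred at external-level ties so a
0 kcal/mol optimum reports the open chain); determinism, not a
particular tie choice, is the property relied upon. The criteria
downstream consume only the MFE and the stem geometry, so an external
thermodynamic folding backend could be substituted without changing any
contract.

`hairpin_geometry()` decomposes a structure into stems (maximal chains
of nested pairs with single branches), reporting each stem's loop span,
arm ranges and the largest unpaired run per arm; structures with
multiloops are reported as non-hairpins.

# Candidate calling

`cluster_unannotated()` groups unannotated tag alignments on the same
strand with gaps ≤ 30 nt; the cluster's mature is its most abundant tag.
`call_candidates()` excises two genomic windows around the mature —
20 nt on one side and 100 nt on the other, in both orientations, so both
arm placements are tried — folds them, and evaluates:

* `arm_ok` — the mature (18–26 nt) lies wholly within one arm, not
  overlapping the terminal loop;
* `geometry_ok` — no unpaired run longer than 4 nt within the
  mature-bearing arm ("no large internal loops or bulges"; the method
  gives no number, 4 nt is a MIREAP-like default);
* `mfe_ok` — precursor MFE strictly below −20 kcal/mol;
* `locus_ok` — the mature locus does not overlap an exon. The
  traditional phrasing of this criterion ("intragenic regions or
  introns") is self-contradictory; it is implemented as *non-exonic*
  (intronic or intergenic), and the flag is reported so users can apply
  a different rule.

The reported precursor is not the whole window-fold stem but the span of
the mature plus its pairing partners (the star side) with a 3-nt pad,
refolded in isolation. This matters: windows carry ~100 nt of flanking
sequence whose incidental base pairs would otherwise dilute the arm
geometry and the triplet features of a genuine hairpin.

# Pseudo-precursor filtering

`triplet_features()` computes the 32 local structure–sequence features
(8 paired/unpaired patterns of three consecutive positions × the middle
nucleotide, frequencies over the L−2 interior triplets).
`train_hairpin_classifier()` fits a linear maximum-margin classifier
(SVM, unit cost, features standardised by training statistics) on
labelled real and pseudo hairpins; the decision score is oriented so
positive margins mean "real", and the verdict threshold is score ≥ 0.
Unit cost and internal standardisation keep the fit deterministic; the
solver is `e1071::svm`, the features and orientation logic are the
package's.

# The funnel

`discover_novel_mirnas()` chains the stages in the order the study
design implies: per-group candidate calling → intersection of accepted
candidates across groups (matched by overlapping mature loci on the same
strand) → known-miRNA exclusion (`exclude_known()`: exact or ≤ 2
mismatches at identical length against the catalog) → replicate
consistency (`replicate_consistency()`: detection = ≥ 1 mapped mature
read; kept when detected in ≥ 2 of 3 replicates of *every* group —
"detected twice" is read as *at least* two) → classifier verdict. Each
stage only removes candidates, so the funnel is monotone; the tests
assert this. Whether low-expression exclusion happens before or after
the consistency rule is not fixed by the method's description; here the
order is discover → consistency → normalize → filter, and the
expression filter applies to the final table.

# Expression statistics

`normalize_rpm()` implements RPM over clean reads with the 0.01
substitution for zero counts, applied *before* fold-change computation
so ratios are always defined. `filter_low_expression()` removes rows
with normalized expression < 1 in both groups; the group statistic is
the group mean (the published rule names no statistic; a per-library
"all" mode is available). `mann_whitney()` computes exact enumeration
p-values for combined n ≤ 12 — correct under ties, which is why the
implementation is not a `wilcox.test` wrapper — and a tie-corrected
normal approximation otherwise. Two-sided tests, α = 0.05; no
multiple-testing correction is applied, mirroring the analysis style the
pipeline reproduces (noted, not endorsed).

# Biomarker evaluation

`ddct()` computes per-subject ΔCt (target − U6-like reference), group
ΔΔCt as the difference of group means (median available), and
`2^{-ΔΔCt}` fold change. `roc_curve()` uses the Mann–Whitney rank
estimator for the AUC (ties count ½), which makes
`AUC = U/(n_1 n_2)` an exact cross-module identity, and the
Hanley–McNeil variance with a normal approximation for the 95% CI (the
CI method behind published serum-miRNA AUCs is typically unstated;
Hanley–McNeil is the conventional choice). Because the novel miRNAs are
*down*-regulated in patients, marker direction is an explicit flag:
with `direction = "down"`, a subject is called a patient when the score
is strictly below the cutoff, and scores at or above it are
control-like. `operating_point()` reports sensitivity/specificity at any
cutoff plus the Youden-optimal one.

# The synthetic-data generator

`simulate_genome()` builds a single-chromosome toy genome (100 kb
default — desk scale, exact mapping stays trivial) with non-overlapping
planted features separated by random background: known miRNA precursors,
novel precursors (validated at generation to satisfy all three criteria
under the package's own engine), "stable" pseudo hairpins
(criteria-passing but with interrupted stems — perfect blocks separated
by 2×2 internal loops whose bases provably cannot pair — giving
pseudo-like triplet composition), "loose" pseudo hairpins (MFE between
−20 and −5), a decoy hairpin whose mature is in the known catalog, other
ncRNA/repeat/exon/intron loci, and intergenic degradation hotspots.

Two generator choices deserve explanation:

* **Background reads.** Published serum category tables show only about
  half of clean reads mapping to the genome at all, so the unannotated
  fraction has two components here: unmappable random-sequence reads
  (with a miRNA-sized length mode, as serum degradation products
  cluster near miRNA size) and mapped reads from discrete intergenic
  hotspot loci. Discrete hotspots, not uniform background, keep
  unannotated clusters sparse on a 100 kb genome — uniform background at
  these depths would fuse into genome-spanning clusters, which is an
  artefact of desk scale, not of serum biology.
* **Abundance model.** Per-feature log-normal means (sdlog 1), a
  per-group fold change of 0.25 for novel miRNAs (the > 2-fold
  down-regulation direction), per-replicate multiplicative log-normal
  noise (sdlog 0.3), multinomial read sampling. This reproduces strong
  within-group replicate correlation of log counts (> 0.9 by
  construction) without modelling library preparation.

Reads are the insert plus the 3' adapter truncated to 36 nt (5' adapters
are not modelled — trimming is exercised by the 3' side alone), with
Phred+33 qualities, planted nuisance classes (adapter dimers, one
sub-threshold base inside the insert, one N) at fixed fractions, and
uniform substitution errors at 0.001 per read. Default library size is
20 000 reads: large enough that planted features receive tens to
thousands of reads and small enough that the full funnel runs in tens of
seconds. All randomness flows from one integer seed; identical seeds
give byte-identical FASTQ output. `simulate_ct_table()` generates qPCR
tables whose group-level `2^{-ΔΔCt}` recovers a designed fold change;
`simulate_hairpin_set()` generates labelled real/pseudo training and
held-out sets for the classifier.

What the synthetic data do *not* emulate: position-dependent sequencing
error and quality profiles, ligation and PCR bias, isomiR 5' end
heterogeneity, cross-mapping between paralogous loci on a real-sized
genome, microbial reads, and any HPV-related content. Passing the
recovery checks therefore demonstrates that the funnel's logic is
correct and its criteria discriminate under the stated generative model
— not that its sensitivity/specificity transfer quantitatively to real
serum libraries.

# Numerical and degenerate-input choices

* Folding: energies in double precision; traceback re-derives decisions
  with a 10⁻⁶ kcal/mol tolerance; sequences too short to close a loop
  return the open chain at exactly 0.
* Cluster mature ties: highest total count, then leftmost start, then
  lexicographic order.
* Candidate windows clipped at genome edges are truncated with a
  warning.
* Empty catalogs pass through `exclude_known()` with a warning; empty
  tag unions make shared-tag percentages `NA`; zero clean reads make the
  unannotated percentage `NA`.
* `mann_whitney()` on identical samples returns U = n₁n₂/2 and p = 1.
* Classifier training refuses single-class input; zero-variance features
  are left unscaled.

# Problem sizes used by the checks

The bundled checks run the default design (6 × 20 000 reads, 100 kb
genome) once and reuse it: planted-novel recovery through the full
funnel is required at recall ≥ 0.8 among novels with true RPM ≥ 10 in
≥ 2 replicates of each group, with zero planted pseudo hairpins
surviving; the folding oracle covers 100 random sequences up to 15 nt;
classifier specificity is measured on a held-out 50 + 50 hairpin set;
ΔΔCt recovery uses 100 subjects per group. These sizes were chosen as
the smallest at which the sampling noise of the checks is comfortably
below the margins being asserted.

# Known limitations

* The energy parameters are a compact Turner-style set, not a complete
  modern table (no terminal AU penalties, special hairpins, or dangles);
  MFE values are comparable to, but not identical with, full
  thermodynamic folders. The −20 kcal/mol criterion is applied within
  one consistent model, which is what matters for the pipeline contract.
* Exact-match mapping cannot place reads carrying sequencing errors or
  polymorphisms; at the simulated error rate this loses ~0.1% of reads.
* With 3 pools per group the exact Mann–Whitney floor is p = 0.1, so
  expression p-values on the simulated design are descriptive, not
  confirmatory — as in any 3-vs-3 pooled design.
* The classifier is trained on generator-produced hairpins; applying
  the pipeline to real data should substitute a training set of real
  annotated precursors and genuine pseudo hairpins.
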