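---
title: "Methods: circRNA expression-landscape analysis with circscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA expression-landscape analysis with circscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circscape)
```

## Scope and model

circscape implements the quantitative core of a circRNA expression-landscape
analysis as used in neural-differentiation studies: back-splice junction
(BSJ) read statistics, abundance filtering and caller harmonization,
differential and coupling statistics, BSJ-targeting knockdown-construct
design with an off-target screen, single-cell cluster-composition bias
calls, and laminar migration quantification. Read alignment, circRNA
calling itself (find_circ / CIRCexplorer internals), negative-binomial GLM
differential testing, droplet barcode processing and clustering are out of
scope; the package starts from junction count tables, cluster-annotated
cell tables and depth profiles.

A circRNA is detected through reads spanning its BSJ. Two per-candidate,
per-sample statistics drive the landscape analysis:

* **RPM** (reads per million): `bsj / library_size * 1e6`, where
  `library_size` is the sample's total read count as supplied in the
  metadata. Whether that total is raw or mapped reads is the caller's
  choice; the package treats it as an opaque per-sample denominator.
* **CTL ratio** (circular-to-linear):
  `bsj / ((donor_linear + acceptor_linear)/2 + pseudocount)`, the BSJ
  count against the average of linear reads spanning the same donor and
  acceptor sites. The pseudocount (default 1) prevents division by zero,
  so a candidate with no linear support has CTL equal to its BSJ count.

High-abundance candidates are those with a mean of at least `min_mean`
(default 5) BSJ reads per sample. The threshold is inclusive: the wording
"at least five on average" and the equivalent "more than 75 in total over
15 samples" conflict at a mean of exactly 5, and we follow the former; the
bound is exposed as `min_mean` for users who prefer the strict reading.

Bulk count normalization uses the median-of-ratios method: the reference
is the per-row geometric mean over rows with all counts positive, the
per-sample size factor is the median count-to-reference ratio over those
rows, and normalized counts are counts divided columnwise by the size
factor. Display matrices (marker heatmaps) use `log2(count + 1)` followed
by row z-scaling with the sample standard deviation; zero-variance rows map
to zero rather than NaN, a convention that only affects a display-only
quantity.

## Differential and coupling statistics

The global expression-shift test compares paired per-candidate expression
between two states. The expression scale is `log2(RPM + 1)` averaged over
replicates within each state; the source analysis does not state its scale,
and the log transform stabilizes the rank statistics without changing the
null distribution of a rank test. A D'Agostino-Pearson omnibus normality
test (K² = Z²skew + Z²kurt against chi-square with 2 df, the standard
transformed-moment z-scores) gates the choice of test: if either vector or
the paired differences fail at `alpha_normality = 0.05`, a Wilcoxon
matched-pairs signed-rank test is used, otherwise a paired t-test. Gating
on the differences as well is the conservative reading of "the data were
not normally distributed"; in practice circRNA expression vectors are
strongly right-skewed and the rank branch is almost always taken.

The signed-rank test drops zero differences, mid-ranks ties, and computes
an exact two-sided p-value for up to 25 nonzero pairs from the full
2^n sign-assignment distribution (evaluated by convolution over doubled
mid-ranks, so ties are exact too); beyond that a normal approximation with
tie and continuity correction is used. The exact branch is validated
against brute-force enumeration in the tests.

Coupling between circular and linear fold changes is summarized by OLS
regression with `r_squared` the squared Pearson correlation and the slope
F-test `F = r²(n−2)/(1−r²)` on (1, n−2) df — algebraically the square of
the slope t-test, which the tests assert.

Fold-change classification is strict ("more than two-fold" excludes exactly
two-fold), as are all DEG threshold filters (`p < 0.05`, `basemean > 10`,
`|log2FC| > 0.5`), matching the printed inequality glyphs. Whether the
fold changes feeding the coupling plots used a pseudocount is unstated in
the source; the pipeline defaults to a pseudocount of 1 on the RPM scale
(the same unit as the CTL pseudocount), exposed as `pseudocount_fc`.
Multiple testing uses Benjamini-Hochberg (the procedure behind generic
"adjusted p-values" in this field).

## Construct design

A BSJ target is the circular join: the last `flank` nt of the donor-side
exon followed by the first `flank` nt of the acceptor-side exon, a
sequence private to the circle. `build_bsj_target()` takes the exons in
order around the junction (donor-side first); a single-exon circle wraps.

`design_shrna_pair()` places two 21-nt windows whose centres sit 3 nt
upstream and downstream of the junction. We read "placed 3 nt
up-/downstream" as a centre shift: both windows must still span the
junction, since a window on one side only would silence the linear host
transcript as well; the alternative edge reading is available through the
`offsets` parameter. Each insert is sense + loop + antisense with one XhoI
site (CTCGAG) and a poly-T pol III terminator appended; design fails
deliberately if a window or loop already contains an XhoI site.

`design_agoshrna()` centres an 18-nt stem window on the junction (≥ 5 nt
per side), builds guide + loop + passenger, forces the first transcribed
base to adenosine (required by the U6 +1 position; a substitution is
recorded when the target does not offer an A), and converts the passenger
base pairing the guide's 5' A to C — the single A-C mismatch "below the
stem" that biases AGO2 processing toward a single guide strand. The
mismatch position, loop and overhangs are parameters with documented
defaults: the exact sequences used in any particular study live in its
supplementary tables, so our defaults are sensible placeholders (a classic
`TTCAAGAGA` loop, `ACCG`/`AAAC` BbsI-style overhangs), not claims. Mature
guide length is a parameter (default 18) standing in for exonucleolytic
trimming of the processed hairpin.

The off-target scan replaces BLASTN with a defined criterion: a hit is an
ungapped full-length alignment of the guide's complement (either strand)
with at most `max_mismatch` mismatches that contains an exact run of at
least `min_word` nucleotides, mirroring short-query BLAST seeding;
model accessions (`XM_`/`XR_`) are excluded by pattern. E-values are not
computed — the hit criterion is the mismatch count. Candidate generation
uses `Biostrings::matchPattern()`, and equivalence with a brute-force
all-positions scan is asserted in the tests.

## Single-cell composition and migration

QC filters follow the strict quoted wording: remove cells with fewer than
200 UMI or more than 5% mitochondrial counts, keep cells expressing more
than 10 genes, remove cells with more than 2500 genes, and (final pass)
remove cells with fewer than 500 UMI; genes must be seen in more than 3
cells. The two UMI stages are parameters of one function rather than
hard-coded passes. DE input cells are those with UMI strictly between
2000 and 4000.

A cluster is condition-specific when more than 75% of its cells derive
from one condition — strict at the boundary, since the rule is "more than
75%"; a 75/25 cluster is shared. With more than two conditions the
maximum-fraction condition is assessed.

Migration is quantified on a 1-D depth profile (depth 0 = ventricular
surface, 1 = pia; per-section normalization is the caller's
responsibility). Ten equal bins are numbered from the pia (bin 1) to the
ventricle (bin 10), so ventricular retention appears in bins 8–10 and the
Ctip2-positive deep layers in the middle bins. Subregions are UL (above
the Ctip2 interval), DL (the interval, inclusive) and VZ (below it).
Boundary mass goes to the pia-ward bin; on continuous profiles that choice
is measure-zero, and the generator evaluates at cell midpoints so no mass
sits on an edge. All outputs are percentages of total signal and are
scale-invariant.

## The synthetic-data generator

Every analysis stage is exercised by generated data with known truth:

* `gen_junction_counts()` draws negative-binomial BSJ counts
  (mean/dispersion parameterization) for `n_circ` candidates across
  ordered states and replicates. Defaults mirror the study design the
  package targets: 417 high-abundance candidates, 5 states × 3 replicates,
  a majority (60%) of candidates monotonically upregulated at 1 log2 unit
  per state step and a small downregulated minority (3%), per-candidate
  baselines log-normal around 20 counts (sdlog 0.8), dispersion 0.2 and
  library sizes uniform on 8–12 million reads. The NB noise model is not
  stated by any source — it is the standard model for RNA-seq junction
  counts. Expected counts scale with library size so RPM has real work to
  do. Half the candidates are host-coupled (linear counts proportional to
  circular; flat CTL ratio), half host-independent (state-constant linear
  counts; rising CTL for rising circles) — the mixture that gives the
  coupling regression both signal and noise.
* `gen_transcriptome()` plants the reverse complement of a guide at a
  recorded position in one uniform-random transcript, optionally with
  mismatches, so the off-target scan has a known answer.
* `gen_cluster_table()` assigns each cell's condition by a fair coin in
  unbiased clusters and with probability `bias_level` toward a preferred
  condition in planted biased clusters, so the >75% rule has exact
  recoverable truth (bias 0.9 at 500 cells per cluster makes recovery
  essentially certain; the power calculation is an exact binomial tail,
  asserted in the tests).
* `gen_depth_profile()` builds piecewise-constant profiles whose noiseless
  subregion masses equal the requested UL/DL/VZ fractions exactly,
  enabling exact round-trip tests such as 94/5/1.

What the generator does **not** emulate: read-level errors, UMI/barcode
structure, batch effects, cross-candidate count correlation beyond shared
library size, ambient RNA, or 2-D tissue geometry. Passing the recovery
tests therefore demonstrates the correctness of the statistics and the
bookkeeping, not robustness to every artifact of real libraries.

Each generator call uses one RNG stream seeded explicitly; identical
parameters and seed give bit-identical output.

## Numerical choices and problem sizes

* Exact signed-rank p-values up to n = 25 nonzero pairs; normal
  approximation with tie and continuity correction above.
* Normality gate requires n ≥ 8 (the transformed-moment z-scores are
  undefined below that); the K² implementation reproduces an independent
  reference implementation to 10 significant digits on frozen fixtures.
* Constant rows z-scale to zero; degenerate shift tests (all differences
  zero) return p = 1 with `n_pairs_used = 0`.
* Median-of-ratios requires at least one all-positive row and works in log
  space for numerical stability; results match the DESeq2 reference
  implementation to 1e-8 on random matrices.
* The null-calibration suite uses 1000 simulated landscapes at the default
  design (417 × 15), a size chosen to bound the Monte-Carlo standard error
  of the type-I estimate near 0.007 while keeping the whole suite fast;
  measured type-I error at nominal 0.05 is ~0.05.
* Strictness conventions (inclusive abundance mean, strict fold-change and
  QC thresholds, strict >75% composition rule) are documented above and
  pinned by tests at the exact boundary values.

## Known limitations

Caller harmonization matches loci by exact coordinate identity (same
convention assumed on both sides); no fuzzy matching of near-identical
junctions. Manual artifact inspection is modeled as an explicit exclusion
list, not an automated heuristic. The off-target scan is ungapped and has
no E-value model. Migration input is 1-D; image segmentation and
registration happen upstream. The pipeline's DE records are consumed, not
produced: fitting NB GLMs is deliberately left to dedicated tools.
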