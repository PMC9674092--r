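---
title: "mitoCilia: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoCilia: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoCilia)
```

`mitoCilia` quantifies activation of a motile-ciliogenesis transcriptional
program — the kind induced in astrocytes by chronic mitochondrial
dysfunction — through four coupled analyses: gene-list/catalog scoring,
promoter motif enrichment, TSS-proximal ChIP-peak enrichment, and cilium
morphometry. This vignette states each model precisely, lists the
parameters that matter with their defaults and rationale, explains what
the synthetic-data generator does and does not emulate, and records the
design decisions taken where the methodology was genuinely open.

## Gene lists and catalog scoring

A differential table holds one row per feature: `log2fc`, `pvalue`,
`qvalue` (Benjamini–Hochberg adjusted) and `mean_expression`. Ingested
q-values are used as-is — they come from the upstream DE fit — though
`recomputeQvalues()` can rebuild them from the p-value column.

Gene lists are threshold filters with strict inequalities: up-regulated =
`log2fc > lfc_min` and significance below the cutoff; down-regulated
symmetric. Defaults follow the field's common practice for bulk
astrocyte RNA-seq: `lfc_min = 0.3`, `q_max = 0.1`. Two stricter adjusted-p
cutoffs (0.05 for the motif gene list, 0.01 for the ChIP gene list) are
exposed through `thresholdPolicy(p_adj_max = ...)`; in these tables the
BH-adjusted p *is* the q-value column, so the two fields differ only in
which cutoff value they carry, and exactly one may be active. Optional
`top_n` truncation keeps the largest-effect genes after sorting by
descending log2FC. Sorting ties are broken by ascending q and then
lexicographic gene id, so outputs are deterministic.

Catalog scoring counts detected/up/down catalog genes per category and
overall and tests over-representation of catalog genes among the
up-regulated set with a hypergeometric upper tail. The universe is the
set of features detected in the table, not the whole genome: detection
limits what the comparison could possibly have found, and using the
genome as universe would overstate enrichment. Gene-id matching is
case-insensitive exact match; alias expansion is deliberately out of
scope (an ingestion concern). "Changed" in the cross-dataset matrix and
in per-class counts means `|log2fc| > 0.3` and `q < 0.1` by default —
the same rule as the up/down lists — and is configurable.

## Promoter motif scanning and central enrichment

Promoter windows are TSS-centered, ±500 bp by default. Windows are
oriented so position 0 is the TSS and negative offsets are upstream in
gene orientation; minus-strand windows are reverse-complemented. With an
even-length window there is no central base: plus-strand windows cover
offsets −500..+499 and extracted minus-strand windows cover −499..+500.
Edge windows are clipped and flagged rather than dropped.

A PWM column j gives base probabilities p_j; scanning scores position i
as Σ_j log2(p_j(b)/bg(b)) on both strands, with ambiguous bases
contributing 0 (background odds — they carry no evidence either way). A
uniform matrix against a uniform background therefore scores exactly 0
everywhere, a property the tests assert. Defaults: pseudocount 0.01 per
cell before normalization (avoids −∞ scores from zero counts without
visibly distorting strong motifs), score threshold 80% of the maximal
attainable log-odds (a common stringent operating point for consensus-like
motifs), background uniform and configurable; for real analyses the
negative-set base composition is the natural background choice. The hit
"center" is floor(width/2) bases from the hit start in window
coordinates on both strands, which makes reported centers
strand-independent and, for even motif widths, makes hit offsets negate
exactly under reverse complementation of the window.

Central enrichment is defined explicitly (the comparison follows the
up-regulated-genes vs 1,000-random-genes design): take the best hit per
gene in both sets; for each candidate central half-width w in a small
grid (default 50, 100, 150, 250 bp), estimate the probability π(w) that
a negative-set gene's best hit lies within ±w using add-one smoothing,
π(w) = (k_neg + 1)/(n_neg + 2); compare the number of target genes with
best hits within ±w to Binomial(n_target, π(w)) by an upper-tail test;
report the minimal p over the grid at its w\*, Bonferroni-corrected for
the grid size. The smoothing keeps p in (0, 1] even when the negative
set has no central hits and slightly offsets the anti-conservatism of
treating an estimated π as known. Genes without any hit count as
non-central in both sets, so a motif absent from the targets cannot be
called enriched; zero target hits returns p = 1 by definition.

Because the corrected minimum-over-w statistic is deliberately
conservative, calibration is checked at the per-w statistic (a
single-element grid): under the no-signal generator at a moderate
threshold (50% of maximum, where best hits are dense and the binomial is
not dominated by discreteness), its empirical type-I error at nominal
0.05 over 200 replicates must sit within two binomial standard
deviations of 0.05 — the suite runs exactly this experiment. At the
stringent default threshold null hits are rare and the test is strongly
conservative; that costs nothing for the intended use (planted or real
signal produces vanishing p-values) but should be remembered when
interpreting near-threshold results.

## TSS-proximal peak enrichment

Peak coordinates are ingested as BED (0-based half-open; in-memory
GRanges are 1-based; rtracklayer handles the conversion), annotations as
GFF3/GTF (1-based) or TSV. Where a gene has several transcripts,
`selectTss()` takes the 5′-most start in gene orientation — the
promoter-proximal choice — and records the policy.

A peak's location is its center, floor((start+end)/2) in 0-based
coordinates: center membership gives every peak one unambiguous signed
distance, where any-overlap membership would double-count peaks
straddling window edges. Distances are signed in gene orientation
(upstream negative, 0 = center exactly at the TSS) and kept within
±10 kb. Distance profiles are histograms over that window; the bin width
must divide it evenly.

The significance of TSS-proximal over-representation is an empirical
resampling test mirroring the negative-set construction: the statistic
is the mean number of peak centers within ±10 kb per target gene; the
null is built by drawing B (default 999) negative gene sets of *matched
size* from the pool (random genome genes, or expressed-but-unchanged
genes), and p = (1 + #{null ≥ observed})/(B + 1), which is exact for
exchangeable draws and never returns 0. Matched-size resampling makes
the statistic scale-free; the raw whole-pool mean is also reported for
fidelity to fixed-1,000-gene-set comparisons. An exhaustive mode
enumerates all subsets on small pools and is tested against a manual
enumeration oracle. Per-gene peak counts are computed once and reused
across resamples, so B is cheap.

## Cilium morphometry

A cilium is an ordered 3D polyline in µm (a declared unit column is
required; mixed-unit files are rejected). Measures: arc length (sum of
segment norms), end-to-end chord, tortuosity = arc/chord (exactly 1 for
straight traces; ∞ for closed shapes), and a length proxy — the longest
edge of a minimal oriented bounding box, matching the
"longest principal axis of a minimal enclosing box" convention of
imaging pipelines.

The box search aligns the points to their principal axes (with an
intrinsic sign convention — the largest-magnitude projection points
positive — so the search landscape is identical for any rigid motion of
the input), then minimizes the regularized volume Π(extent + ε) over
rotations with a 6° Euler grid followed by coordinate pattern search to
below 1e−6 rad, refining the best few grid cells after deduplicating
them by objective level (the grid visits many symmetry copies of each
box). ε = 1e−6 × the largest principal extent makes the objective
meaningful for planar and collinear point sets, where it reduces to
minimal-area and minimal-length boxes; exact volume ties are broken
toward the smaller longest edge. The suite validates the search against
a 0.1° rotation-grid brute force on planar polylines and asserts
rigid-motion invariance to 1e−6 µm. One geometric caveat: the chord can
exceed the longest box edge for strongly bent shapes (an L of two 3 µm
legs has box edge 3 but chord 3√2); the proxy is a length measure for
elongated, moderately bent organelles, not a diameter bound.

Morphology classes replace manual annotation with explicit rules:
straight if tortuosity < t1 (default 1.05), contorted if tortuosity ≥ t2
(default 1.5) *or* two segments at least 1 µm apart along the curve
approach within `loop_radius` (default 0.2 µm; the arc-separation
requirement exists because neighbouring segments of any contiguous curve
are trivially close in space), bent otherwise. Intervals are half-open:
exactly t1 is bent. All thresholds are recorded in the output so
manual-style labels can be reproduced or re-tuned.

Group comparison uses the two-sample Kolmogorov–Smirnov test on
per-cilium lengths (`stats::ks.test`, which applies exact small-sample
p-values where feasible and the asymptotic distribution otherwise; the
implemented D is checked against an exhaustive ECDF-gap oracle) and
one-way ANOVA of length by genotype. Because the appropriate unit of
analysis (cilium vs mouse) is a genuine open question for nested imaging
designs, both are emitted: the cilium-level ANOVA and a mouse-level
ANOVA on per-mouse means.

## The synthetic-data generator

The generator produces every pipeline input with planted, parameterized
truth under one explicit seed recorded in output headers. Defaults state
the intended study conditions: a 3,000-gene genome on 3 chromosomes
(TSSs ≥1.5 kb apart with 10 kb end margins, so ±10 kb windows fit and
±500 bp promoters never overlap), a 92-gene ciliary catalog
(40 motile-specific / 26 primary-specific / 26 pan-ciliary), planted
activation fraction 0.6 with log2FC ~ Normal(2, 0.5), 1,000-gene negative
sets, motif offsets Normal(0, 50 bp), peak excess ~2 extra peaks per
target gene at Normal(0, 2 kb) offsets over a 5e−5/bp background, and
two cilium genotypes of 150 cilia across 5 mice each — control
3.2 ± 0.8 µm at near-zero curvature, mutant 4.8 ± 1.2 µm at high
curvature — chosen to emulate a clear length shift with a contorted
mutant population.

Null p-values are Uniform(0,1); planted p-values are Beta(a, 1) with
a = 0.001 by default, i.e. planted genes are essentially always
BH-significant at q < 0.1 in tables of this size, emulating strong
program activation. A larger `planted_beta_a` produces partial
penetrance when weaker signal is wanted. The motif planter inserts the
PWM *consensus* (on a random strand, centered at the drawn offset);
background bases are i.i.d. from the configured composition, uniform by
default.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: correlated gene-gene expression,
composition-biased promoters and CpG islands, degenerate motif instances
(only the consensus is planted), ChIP fragment-size structure and peak
clustering, multi-TSS genes, and imaging noise on traces. The tests show
the statistics are correct and calibrated under their stated models, not
that real astrocyte data satisfy those models.

## Numerical and policy choices

* PWM columns must sum to 1 within 1e−9 after pseudocount
  normalization; validity is enforced on construction.
* The scanner's integer encoding scores `N` (and any non-ACGT symbol)
  as 0 contribution; an all-ambiguous window yields no positive-score
  hits.
* Best-hit ties are broken by smaller |offset|, then smaller offset,
  then + strand.
* The negative gene draw excludes the target genes by default (the
  overlap question is not settled in common practice; exclusion avoids
  diluting the null with signal and is configurable by passing any pool).
* Empirical p-values use the (1 + count)/(B + 1) convention, so they are
  never 0 and are exactly uniform under exchangeability.
* Zero-variance rows Z-score to zeros with a warning rather than NaN.
* Degenerate traces (all points coincident) are errors; repeated
  consecutive points (digitization artifacts) are dropped silently.
* Pipeline stage seeds are derived from the master seed by fixed small
  offsets, so stages are individually reproducible.
* For proteomics tables, where the exact published "upregulated"
  criterion is ambiguous, both q < 0.01 and threshold-policy rules are
  available via `thresholdPolicy`; the choice is the caller's and is
  echoed in outputs.

## Problem sizes used by the shipped checks

The test suite and acceptance script run at deliberately chosen desk
scales: 1,000 random tables for the gene-list oracle; universes ≤ 12 for
exhaustive hypergeometric enumeration; 200 replicates for type-I
calibration of both enrichment tests (200 target / 1,000 negative genes
for the motif test); 500 random windows for the scan oracle; 200 seeds
at 92 catalog genes for activation-fraction recovery; ≤ 50 points per
group for the exhaustive KS oracle. These sizes give the oracles exact
or near-exact resolution while keeping a full run in minutes on one CPU.

## Known limitations

The central-enrichment binomial treats π(w) as known; with 1,000
negative genes the extra variance is small and partially offset by the
smoothing, but very small negative sets would make the test
anti-conservative. The OBB search is an approximation with strong
empirical guarantees on the shapes tested, not a certified global
optimizer. KS on length proxies inherits ties from discretized traces;
`ks.test` then falls back to the asymptotic p. The pipeline ingests DE
statistics rather than estimating them: garbage q-values in, garbage
program calls out.
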