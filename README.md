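# mitoCilia

Astrocytes normally carry a single immotile primary cilium. Under chronic
mitochondrial stress (mtDNA depletion), they anomalously switch on a
*motile*-ciliogenesis gene-expression program — RFX/FOXJ1-driven induction
of dynein arms, radial spokes, the central pair and multiciliated-cell
differentiation factors — and their cilia elongate and become contorted.
`mitoCilia` packages the computational analyses needed to detect and
quantify such a program from bulk differential-expression data, promoter
sequence, ChIP-seq peak coordinates and segmented 3D cilium traces, for
anyone studying stress-induced ciliary remodeling in astrocytes or other
differentiated cell types.

## What it computes

* **Gene lists and program scores.** From a differential table
  (log2FC, p, BH q per gene), up/down lists under explicit threshold
  policies (default `log2FC > 0.3`, `q < 0.1`, optional top-*N*
  truncation sorted by log2FC), and catalog scores: for a curated gene
  catalog *C* inside a detected universe of *N* genes with *n* up-regulated,
  the over-representation p-value is the hypergeometric upper tail

  P(X ≥ k), X ~ Hypergeom(N, |C∩universe|, n),

  reported per category (motile-specific / primary-specific /
  pan-ciliary) and overall, plus cross-dataset "fraction changed"
  matrices and row Z-scoring for heatmaps.

* **Promoter motif enrichment.** TSS-centered ±500 bp windows are scanned
  with a PWM on both strands; position score
  s(i) = Σ_j log2(p_j(base) / bg(base)). Central enrichment compares the
  fraction of target genes whose best hit falls within ±w of the TSS to
  the same fraction π(w) in a 1,000-gene random negative set via an
  upper-tail binomial test, minimized over a grid of w with Bonferroni
  correction.

* **TSS-proximal peak enrichment.** Signed distances (upstream negative)
  from each gene's TSS to every ChIP-peak center within ±10 kb, binned
  distance profiles, and an empirical resampling test: observed mean
  peaks-per-gene vs B matched-size draws from a negative pool (random
  genome genes or expressed-but-unchanged genes),
  p = (1 + #{null ≥ obs}) / (B + 1).

* **Cilium morphometry.** Per-cilium arc length, chord, tortuosity
  (arc/chord ≥ 1), the minimal-oriented-bounding-box longest edge as a
  length proxy, explicit straight/bent/contorted rules (tortuosity
  thresholds + self-proximity loop detection), and group comparison by
  two-sample Kolmogorov–Smirnov and one-way ANOVA at both cilium and
  mouse level.

* **Synthetic data with planted truth.** Every input can be generated
  with controlled signal — planted up-regulated catalogs, planted motif
  offsets, planted TSS-proximal peak excess, two cilium populations —
  so each stage has a ground-truth recovery and calibration test.

## Worked example

```r
library(mitoCilia)
gm <- makeGenome(600, n_chroms = 2, chrom_len = 2e6, seed = 1)
catalog <- GeneCatalog(geneIds(gm)[1:92],
                       rep(c("motile-specific", "primary-specific",
                             "pan-ciliary"), c(40, 26, 26)),
                       name = "ciliary")
de <- makeDifferentialTable(gm, catalog, planted_fraction = 0.6, seed = 2)
lists <- buildGeneLists(de, thresholdPolicy())
scoreCatalog(lists, de, catalog)
#>           category n_total n_detected n_up n_down n_changed  p_hyper
#> 1  motile-specific      40         40   23      0        23 5.34e-16
#> 2 primary-specific      26         26   15      0        15 1.96e-10
#> 3      pan-ciliary      26         26   18      0        18 1.62e-14
#> 4          overall      92         92   56      0        56 1.25e-54
```

56 of the 92 catalog genes pass the up filter (0.6 × 92 ≈ 55 were
planted), and the hypergeometric tail is overwhelming. The ChIP overlay
recovers the planted TSS-proximal peak excess:

```r
pk <- makePeaks(gm, attr(deRecords(de), "planted"), seed = 3)
pool <- sampleNegativeGenes("genome_random", gm, n = 400,
                            exclude = lists$up, seed = 4)
positionalEnrichmentTest(lists$up, pool, pk, gm, B = 999, seed = 5)
#> Positional TSS-peak enrichment (resample)
#>   observed mean peaks/gene : 5.6964 (n = 56 genes, +/- 10000 bp)
#>   null mean (sd)           : 1.1314 (0.1587), B = 999
#>   empirical p              : 0.001
```

Target genes carry ~5.7 peaks within ±10 kb of their TSS versus ~1.1 for
matched random gene sets; no resampled null reached the observed value,
so the empirical p is at its floor 1/(B+1). Morphometry separates the two
simulated genotypes:

```r
tr <- makeCilia(150, list(
  ctrl   = list(length_mean = 3.2, length_sd = 0.8, curvature = 0.05),
  mutant = list(length_mean = 4.8, length_sd = 1.2, curvature = 0.6)),
  seed = 6)
compareCiliaGroups(classifyMorphology(measureCilia(tr)))
#> Cilia group comparison on length_proxy
#>   KS (ctrl vs mutant): D = 0.4267, p = 2.77e-12
#>   one-way ANOVA (cilium level): F = 43.474, p = 1.95e-10
#>   one-way ANOVA (mouse level) : F = 64.546, p = 4.24e-05
#>   morphology proportions:
#>          straight  bent contorted
#>   ctrl      1.000 0.000     0.000
#>   mutant    0.000 0.127     0.873
```

The whole pipeline (simulate → DE programs → motif → peaks → cilia →
JSON report with checksums and parameter echo) runs via
`runPipeline(defaultRunConfig(outdir, seed))` or the thin CLI wrapper in
`inst/exec/ciliapipe.R`.

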