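# piRNAhybrids

Diagnostics for piRNA-pathway collapse in interspecific *Drosophila*
hybrids, built as a reusable, fully tested R pipeline.

In the germline, the Piwi-interacting RNA (piRNA) pathway silences
transposable elements (TEs): 23–29 nt piRNAs loaded on Piwi-clade
Argonautes guide transcriptional and post-transcriptional repression,
and the Aub/Ago3 "ping-pong" cycle amplifies them from piRNA-cluster
precursors. When two species' pathway components meet in an F1 hybrid,
that machinery can fail: TE families become derepressed, the small-RNA
pool loses its piRNA-sized class, cluster output departs from the
additive (mid-parent) expectation, and ping-pong amplification decays.
`piRNAhybrids` implements the computational side of that diagnosis for
ovarian small-RNA and mRNA sequencing of a hybrid and its two parents,
together with a seeded synthetic-data generator that produces all
inputs with known ground truth, so every statistic is testable against
planted values.

## The statistics at the core

* **Dual-parent derepression call.** A family is *derepressed* iff its
  depth-normalized hybrid abundance satisfies log2FC ≥ 1 against *both*
  parents with BH-adjusted q < 0.05 against both (exact conditional
  binomial on the raw counts; normalization is count × 10⁹ /
  (library size × consensus length)).
* **Ping-pong fraction.** For a TE family, the probability that a
  randomly sampled piRNA (sampling by abundance) has an opposite-strand
  partner whose 5′ ends overlap by exactly 10 nt — the Aub/Ago3 slicer
  geometry. Reporting keeps families with > 50 reads and fraction > 0.1
  in at least one library.
* **Cluster inheritance.** Per-cluster piRNA frequencies under three
  multimapper schemes (unique / weighted by 1/n_locations / all);
  relative expression = hybrid frequency over the parental average,
  with ≥ 2 over-dominant and ≤ 0.5 under-dominant.
* **Size-class and strand profiling.** 18–30 nt histograms, the ≥ 23 nt
  piRNA share, per-family RPM and antisense fractions, and ≥ 2-fold
  interspecific differential-abundance categories.
* **Species-of-origin partition.** Zero-mismatch placement on both
  parental genomes classifies each read as genome-A-unique,
  genome-B-unique, or shared, supporting per-origin fold changes.
* **Comparative statistics.** G-test (no Williams correction), Pearson
  chi-square, Wilcoxon rank-sum, pooled-variance t, Pearson and partial
  correlations with a 10,000-permutation empirical null.

Read placement is an exact / k-mismatch search over both strands of a
consensus or genome database, keeping all best-stratum hits; it is
deliberately self-contained so the test suite can verify it against an
exhaustive sliding-window oracle.

## Worked example

```r
library(piRNAhybrids)

# The published derepression contrast: 32/265 TE families vs 38/8,442 genes
gTest2x2(32, 233, 38, 8404)
#> StatResult: G = 132.958, df = 1, p = 9.235e-31, n = 8707

# One seeded end-to-end run: simulate two diverged parental genomes and
# three small-RNA libraries (hybrid in the mutant-like regime), map,
# profile, and classify
cfg <- pipelineConfig(seed = 1, n_reads = 8000, n_families = 15,
                      n_derepressed = 5)
res <- runPipeline(cfg, "demo_run")

res$summary$derepressed_families
#> [1] "TE01" "TE02" "TE03" "TE04" "TE05"     # exactly the planted 4-fold families
round(res$summary$pirna_share, 3)
#> parentA parentB  hybrid
#>   0.605   0.599   0.206
res$summary$cluster_classes
#>       additive  overexpressed underexpressed
#>              8              4              3
```

The parents keep ~60% of reads in the piRNA size class while the hybrid
collapses to ~21% — the mutant-like regime the generator plants (0.6 vs
0.2). All five planted derepressed families are recovered with no false
calls. Cluster classes approximate the planted 5/5/5
over/additive/under split; clusters with few reads at this depth can
fall on the wrong side of the 2.0/0.5 boundaries. The filtered
ping-pong table (`res$summary$pingpong`) shows per-family fractions,
e.g. family TE02: parentA 0.226, parentB 0.229, hybrid 0.065 — the
hybrid's amplification loop is off.

## Layout

* `R/` — S4 classes (`TEFamilySet`, `GenomeAnnotation`, `StatResult`)
  and the module functions (mapping, simulation, profiling, ping-pong,
  expression, clusters, statistics, pipeline).
* `vignettes/hybrid-piRNA-collapse.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations.
* `tests/testthat/` — oracle-backed unit, property, and acceptance
  suites.
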