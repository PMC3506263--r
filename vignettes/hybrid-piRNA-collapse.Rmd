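---
title: "Diagnosing piRNA-pathway collapse in interspecific hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing piRNA-pathway collapse in interspecific hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piRNAhybrids)
```

## The biological question and the analysis model

Interspecific F1 hybrids inherit one piRNA pathway's worth of effector
proteins from each parent species, plus a maternally deposited piRNA
pool. If those components have diverged, germline transposon silencing
can fail in ways that resemble piRNA-effector-protein mutants rather
than classic intraspecific hybrid dysgenesis. The signature of that
failure is computable from two sequencing assays per genotype (two
parents and their hybrid): ovarian mRNA-seq quantified against TE
consensus sequences, and ovarian small RNAs (18–30 nt) placed on the
consensus database and on both parental genomes.

This package implements the full computation and pairs it with a
synthetic-data generator, so each statistic can be validated against
planted ground truth before being applied to real libraries.

### Derepression calling

Per TE family (or gene), raw weighted counts are normalized as
count × 10⁹ / (library size × consensus length). A family is called
**derepressed** when its hybrid abundance is at least 2-fold above
*both* parents (log2FC ≥ 1, formed on depth-scaled counts with a 0.5
pseudocount) *and* significant against both (q < 0.05, BH across
families within each comparison). Requiring both parents is the
conservative choice: with additive inheritance a hybrid is expected to
exceed its lower-expressing parent, so single-parent excesses are
uninformative about silencing failure. A fold-only call is emitted in
parallel, since the abundance analyses are also run without the
significance gate.

The significance test is an exact conditional binomial: with one
library per genotype, under equal underlying abundance the hybrid count
given the two-library total is Binomial(total, N_H/(N_H+N_P)). That is
the correct sampling model at the Poisson limit, and the package states
this assumption plainly: with biological overdispersion between
libraries the binomial test is anticonservative. A negative-binomial
exact test with a caller-supplied dispersion (via edgeR) is available
behind the `test = "nb"` flag. We verify type-I calibration of the
default test at its own sampling model (Poisson simulations), and
verify planted-fold recovery and empirical FDR at the generator's
default dispersion.

### Small-RNA profiling

Reads are partitioned into the 23–29 nt piRNA class and the 18–22 nt
miRNA/endo-siRNA background. Both window bounds are arguments; 23/29
are the defaults throughout, and the "piRNA share" of a library uses
the ≥ 23 nt rule. Per-family abundances use the tie policy under which
a read hitting k distinct families contributes copies/k to each
(a unique-mappers-only flag exists); RPM normalizes by total library
reads. The antisense fraction is antisense weight over total weight and
is reported as missing — never as 0 — for families without reads.
Interspecific differential-abundance categories use an inclusive
≥ 2-fold rule on RPM; zero RPM values are floored at half a read's RPM
for ratio formation only, so reported tables stay raw while fold
changes stay finite.

### The ping-pong fraction

Aub/Ago3 slicing cuts 10 nt from the 5′ end of the guide, so reciprocal
amplification leaves sense/antisense read pairs whose 5′ ends overlap
by exactly 10 nt. On a single plus-strand coordinate axis — with an
antisense read's 5′ end defined as the highest coordinate it covers —
a sense read with 5′ end p pairs with any antisense 5′ end at p + 9.
The ping-pong fraction of a family is the weighted share of its piRNAs
that have at least one such partner. Weights are collapsed copy counts
(sampling by abundance); a `distinct` flag weights each distinct
sequence once instead, since either convention is defensible. Reads
hitting several families count fully in each (the pair search is per
family and self-contained; this deliberately differs from the
fractional tie policy of abundance tables). Reporting retains families
with > 50 weighted reads and fraction > 0.1 in at least one of the
libraries; both thresholds are arguments. The overlap spectrum
generalizes the rule to overlaps 1..25 as a diagnostic; its entry at 10
equals the participating weight of the fraction statistic.

### Cluster activity and inheritance

piRNA clusters are annotated on one genome only (the annotated-genome
asymmetry of real assemblies: the second parent's clusters are absent
or incompletely assembled, so all libraries are tallied against the
first parent's annotation). A read belongs to a cluster when its
genomic 5′ coordinate falls inside the half-open interval —
unambiguous for edge-straddling reads. Three schemes: *unique* counts
only single-placement reads; *weighted* gives copies ×
(in-cluster placements / total placements); *all* counts any read with
an in-cluster placement, so unique ≤ weighted ≤ all per cluster.
Frequencies denominate over the library's total mappable piRNA-class
copies. The hybrid's additive expectation is the mean of the parental
frequencies; relative expression ≥ 2 is over-dominant and ≤ 0.5
under-dominant (both inclusive), with a zero expectation flagged
undefined rather than classified. When one parent is unmeasurable its
contribution is taken as zero, and the expectation reduces to half the
measured parent.

### Read placement

Mapping is an exact/k-mismatch substring search over both strands of
the target database, re-implemented rather than delegated to an
external aligner so that an exhaustive sliding-window oracle can verify
it exactly at test scale. Identical sequences are collapsed first
(copies preserved); each collapsed read keeps *all* placements of its
lowest achievable mismatch stratum, and `n_locations` counts them. The
default mismatch ceiling is 0 — the setting that defines the
species-of-origin partition — and is configurable to 3 for robustness
studies. The zero-mismatch path is a hash join of the read set against
all target substrings of each read length; k ≥ 1 falls back to a
per-read scan and is intended for small inputs. Coordinates are 0-based
half-open everywhere; BED files are native, FASTA/GRanges conversions
happen at the boundary.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not sequencing realism.

**Genomes.** Each TE family gets one allele per genome — the consensus
substituted at rate `divergence` per site (default 0.02, of the order
of silent-site divergence between close sibling species), with at least
one diagnostic substitution forced when divergence is positive. All
copies within a genome share the allele; a separate `copy_divergence`
knob (default 0) adds per-copy jitter. Genome-consistent alleles are
what make species-diagnostic sites, and hence the origin-partition
truth, well defined. Families are present full-length in both genomes,
genome A only, or neither (probabilities 0.6/0.25/0.15). Clusters are
planted on genome A as concatenations of fragmented antisense copies.

**Small-RNA libraries.** Reads split into a piRNA class (share
`pirna_fraction`, default 0.6 wild-type; lengths normal around 26 ± 1.5
truncated to 23–29) and an 18–22 nt background. TE-derived piRNAs are
positioned on the consensus axis and lifted to a randomly chosen copy
of the genotype's genome(s), so emitted sequences carry genome alleles
and map back to their genome exactly. A fraction π of each family's
piRNAs is planted as exact 10-nt-overlap pairs. Unpaired reads are
rejection-sampled away from accidental 10-nt overlaps: without this,
accidental pairing adds roughly (1 − π) × (opposite-strand 5′ density)
to the measured fraction, which at realistic densities exceeds the
binomial noise band and would make the planted π unrecoverable by any
estimator. Pair partners falling outside the consensus are resampled
and counted. Singleton strand choice compensates the pairs' forced
50/50 strand split so the family's overall antisense fraction meets its
target when feasible (infeasible combinations, e.g. antisense fraction
0.8 with π = 0.5, are clipped). Cluster-derived reads are drawn from
the annotated genome's cluster intervals with configured per-cluster
weights.

**The mutant-like hybrid preset** drops the piRNA share from 0.6 to
0.2, scales π by 0.3, and sets hybrid cluster weights to the parental
average times planted multipliers (default 2.5/1.0/0.3 in thirds,
safely away from the 2.0/0.5 class boundaries). These are
configuration, not constants.

**mRNA counts** are negative binomial with log-uniform base means
(default 100–1000, "high counts") shared by the parents; the hybrid
mean is the parental average times 2^planted-log2FC. The default
dispersion is 0.01 — the scale of technical variation between deeply
sequenced single libraries, consistent with the caller's single-library
binomial test; it is an argument, and 0 gives the Poisson limit used
for calibration checks.

**What the generator does not emulate:** sequencing error and quality
scores, PCR duplicates, adapter artifacts, isoforms, nested/truncated
TE copies beyond cluster fragments, and real piRNA biogenesis biases
(1U/10A nucleotide preferences, phasing). Passing tests therefore
demonstrate correctness of the statistics under the stated model, not
robustness to every artifact of real libraries.

## Numerical and design choices

* All "≥ 2-fold"-style thresholds are inclusive; a strict-greater flag
  exists on the expression caller.
* Fold changes use a 0.5 pseudocount on raw counts only; reported
  tables are never floored.
* The ping-pong recovery checks run the generator in consensus-axis
  mode. With diverged genome alleles and zero-mismatch consensus
  mapping, a pair is lost whenever either mate overlaps a substituted
  site, deflating the measured fraction below the planted π by a known
  mapping-attrition factor; recovery of the statistic itself is
  assessed without that orthogonal effect, which the pipeline tests
  exercise instead.
* The permutation null for partial correlations shuffles each column's
  rows independently (one reference column fixed), destroying all
  dependence while keeping marginals; significance is one-sided against
  the 95th percentile of each focal pair's own permuted distribution,
  and results are seed-reproducible.
* The likelihood-ratio G and Pearson X² both scale exactly linearly
  when a table is scaled, so their relative difference is governed by
  effect size, not count depth; the suite tests their agreement in the
  weak-association regime accordingly.
* Degenerate inputs are contracts, not crashes: empty libraries error
  ("no reads in range"), zero-read families report missing antisense
  fractions, zero cluster expectations are flagged unclassified, zero
  margins error in contingency tests, and the category-level chi-square
  is skipped when no (or every) family is derepressed.
* Problem sizes in the tests and acceptance script — 10,000-read
  libraries for recovery checks, 15,000-read pipeline runs, 20
  replicate count tables, 100–200 permutation replicates at 300
  permutations — were chosen so the whole suite runs in a few minutes
  on one core while keeping binomial tolerance bands tight.

## Known limitations

* With a single library per genotype, the default binomial q-values
  inherit the Poisson assumption; under biological overdispersion use
  the NB flag with an externally estimated dispersion.
* Cluster inheritance classes for clusters receiving few reads are
  noisy around the 2.0/0.5 boundaries at moderate depth; the planted
  5/5/5 split is recovered approximately, not exactly, in
  15,000-read demonstrations.
* Consensus mapping at zero mismatches undercounts families whose
  genomic copies are diverged from the consensus; raising the mismatch
  ceiling trades that against cross-family misassignment.
* The statistics reported from published work that require the original
  read data (correlations with specific mutant fold-change tables) are
  computable by the functions here but not reproducible from synthetic
  data; they are consumed as input tables when available.
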