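---
title: "Methods and design notes for k4gauge"
author: "k4gauge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for k4gauge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k4gauge)
```

# Scope

`k4gauge` implements the downstream, post-alignment computations of a
spike-in ChIP-seq + RNA-seq comparison of histone H3K4 methylation
(me1/me2/me3) across genotypes — wild type and mutants of the SET/MLL
scaffolding subunits WDR-5 and RBBP-5 in *C. elegans* embryos. Alignment,
duplicate removal, GC-bias correction, peak calling and the
negative-binomial differential test itself are upstream tools whose outputs
(binned coverage, broadPeak tables, per-gene result tables with Cook's
distances) this package consumes. A seeded synthetic-data generator emulates
every input, so the full pipeline runs and is tested without any download.

# Spike-in normalisation

## The composition model

A fixed fraction $s$ of foreign (*Drosophila*) chromatin is added to each
sample before immunoprecipitation, and the foreign material is pulled down
by an antibody against a foreign-specific histone variant. The
immunoprecipitated pool is therefore target-marked worm chromatin, whose
amount scales with the genotype's true mark retention $d \in [0,1]$, plus a
constant foreign pulldown. Sequenced reads split by composition, so the
expected spike-read share is

$$\Pr(\text{spike}) = \frac{s}{(1-s)\,d + s}.$$

A sample whose mark is depleted yields proportionally more spike reads at
equal depth: at $s = 0.05$, halving the mark multiplies the spike share by
1.905 (the factor tends to $2$ as $s \to 0$). `simulate_spikein_counts()`
draws binomial reads from this composition; `expected_spike_share()` gives
the analytic expectation used in the tests. The default $s = 0.05$ reflects
the usual practice of adding about 5% foreign chromatin.

## Scaling factors and downsampling

`compute_scaling_factors()` scales every sample *down* to the sample with
the fewest spike reads within its antibody (mark) group:
$f_s = \min_t(\text{spike}_t) / \text{spike}_s$, so factors lie in $(0,1]$
and the reference sample gets 1. Factors are derived within each mark
because immunoprecipitation efficiency is antibody-specific; no cross-mark
comparability is claimed. Downsampling is binomial thinning
(`downsample_counts()`), chosen over deterministic rounding because it
preserves count statistics exactly and is reproducible under a seed.

## Why the composed pipeline uses a common CPM denominator

`cpm_normalise()` implements the usual per-sample counts-per-million
scaling. However, composing "downsample by $f_s$, then CPM per sample"
would cancel the spike factors exactly: CPM divides by the
post-downsampling total, which carries $f_s$. Per-sample CPM is precisely
the naive normalisation that a spike-in exists to correct — it can never
reveal a global loss of signal. `normalise_experiment()` therefore
downsamples each sample by its factor and then expresses all tracks of a
mark group in CPM units of that group's *reference* library (the factor-1
sample). This preserves the between-sample scaling encoded by the spike-in
while keeping familiar CPM units. The package demonstrates the difference
with `spikein_recovery_experiment()`: under a simulated true retention of
0.1 with a two-fold sequencing-depth imbalance, the spike-normalised
mutant/wild-type feature-signal ratio recovers 0.1 within a few percent,
while the per-sample-CPM control sits near 1.0 and is blind to the loss.

# Peak post-filtering, classification and annotation

Broad peaks are post-filtered with mark-specific thresholds: H3K4me1/me2
peaks need length $\ge$ 2 kb, H3K4me3 peaks length $\ge$ 0.5 kb, and all
peaks need fold enrichment (signalValue) $\ge$ 3 and $q \le 0.005$. The
broadPeak file stores $-\log_{10} q$ in column 9, so the q threshold is
compared as column $\ge -\log_{10}(0.005) \approx 2.301$; every boundary is
inclusive.

Each retained peak falls into exactly one of four categories by
any-shared-base overlap: `Promoter_only` (overlaps a TSS ± 1 kb window but
no enhancer), `Enhancer_only`, `Promoter_Enhancer` (both) and `Other`
(neither). Promoter windows are half-open, $[p-1000, p+1000)$, giving every
window exactly 2000 bp; overlapping windows are merged before counting,
which cannot change any peak's category. Per (genotype, mark, category) the
package reports peak counts, cumulative signal and cumulative area
(signal × width), the peak-burden summaries used to compare genotypes.

The six-feature annotation (promoter-TSS, TTS, Exon(UTR), CDS, intron,
intergenic) assigns each peak by the location of its midpoint under a fixed
precedence ladder, promoter-TSS > TTS > Exon(UTR) > CDS > intron >
intergenic. Annotation tools imply a precedence without printing one; a
midpoint rule with an explicit ladder was chosen because it is unambiguous,
single-label by construction and configurable. The TTS window half-width
defaults to 1 kb, mirroring the promoter window, as no width is standard.

# Signal metaprofiles and High/Low clustering

`extract_matrix()` computes, for every anchor (TSS, enhancer midpoint or
peak summit), the mean signal in fixed-width bins across
$[\text{anchor}-\text{flank}, \text{anchor}+\text{flank})$. The matrix bin
grid is anchored at the region (as metaprofile tools do), not at the genome
grid; where matrix bins straddle track bins the overlap-weighted mean is
used, which is exact because the track is piecewise-constant. Rows of
minus-strand anchors are reversed so downstream is always right.
Out-of-bounds bins are missing (`NA`), never zero, to avoid edge artefacts
in aggregate profiles; aggregation is missing-aware.

`kmeans_high_low()` splits regions into "me3 High" and "me3 Low" with
$k = 2$ k-means on the raw binned row vectors (best of 10 restarts,
seeded). Clustering operates on raw rather than row-normalised signal
because the split is by *level*; a mean-signal-only mode is available
(`on_rows = "mean"`) for users who prefer a one-dimensional split. The
cluster with the larger mean row sum is labelled High, which makes the
orientation stable across seeds on separable data. With exactly two rows,
each row is its own cluster; an all-identical matrix returns a single Low
cluster with a warning rather than an arbitrary split.

# Chromosome-level statistics

Input-chromatin uniformity is assessed on per-chromosome totals with a
goodness-of-fit statistic whose expected counts are proportional to
chromosome length ($E_i = N\,L_i/\sum L$), i.e. chromosome-size weighting
in the standard sense, with $\chi^2$ upper-tail p on $n-1$ degrees of
freedom. The test assumes counts; real-valued coverage (e.g. RPGC) is
converted to effective counts by dividing by a per-read bin-value scale
(`value_scale`), and the conversion used is recorded in the result object.
Per-chromosome $\log_2(\text{observed}/\text{expected})$ shares and the
$\log_2$ ratio of chrX mean signal to the length-weighted autosomal mean
complete the summary. Zero-signal chromosomes yield $-\infty$ with a
warning, never an error, so degenerate tracks remain inspectable.

# Transcriptome summaries

**DEG calling.** "Fold change > 2" is interpreted as strict
$|\log_2 FC| > 1$ and "adjusted p < 0.05" as strict, the reporting
convention of differential-expression tables; boundary genes are excluded.
The detected universe applies the expression floor of 50 to the
per-condition normalised means as *either/or* (`baseMeanA >= 50` OR
`baseMeanB >= 50`), so genes silenced in one genotype but expressed in the
other stay in the universe. Genes with missing adjusted p are unchanged.

**Net transcriptome change percent.** Over the called DEG,
$100 \times \sum \text{baseMean}\cdot\log_2FC \,/\, \sum \text{baseMean}$ —
a baseMean-weighted mean of fold changes, negative for net down-regulation
and not bounded by ±100. It is invariant to gene order and to rescaling all
expression values by a constant.

**Rank tests.** Wild-type baseline expression (`baseMeanA`) of the
down/up/unchanged categories is compared with a two-sided Mann–Whitney U
test on $\log_2(\text{baseMeanA} + 1)$; the pseudocount only admits zeros,
since the rank test is invariant to monotone transforms. For group sizes up
to 8 the null is enumerated exactly over all assignments (correct under
ties); larger groups use the normal approximation with tie and continuity
corrections. The two-sided exact p doubles the smaller tail, capped at 1.

**Chromosome enrichment.** Per chromosome and direction, observed DEG
counts are compared with the universe's chromosome composition:
$\log_2(\text{obs}/\text{exp})$, a Wilson 95% interval of the observed
proportion mapped to the log2 scale, a two-sided exact binomial p, and
Benjamini–Hochberg FDR across the six chromosomes. A chromosome is flagged
only when FDR $\le 0.01$ *and* the enrichment magnitude is at least 20%
($|\log_2(\text{obs}/\text{exp})| \ge \log_2 1.2 \approx 0.263$). Wilson
was chosen over Wald for its behaviour at small counts; the exact binomial
and BH are the standard choices where no method is dictated.

**Set logic.** Overlaps between DEG sets use the upper-tail hypergeometric
test on the shared universe (the standard Venn-significance choice).
"Restored" genes are those differentially expressed in a single mutant but
unchanged in the double mutant, reported with the restored fraction of the
single-mutant DEG count.

**Cook's-distance sensitivity.** Following the replicate-influence
analysis, this filter uses the expression floor in *both* conditions
(`> 50` in each), selects genes whose Cook's distance in the named
replicate exceeds 1, and counts how many meet the standard
($|\log_2FC| > 1$, padj < 0.05) and relaxed ($> 0.75$, $< 0.1$) criteria;
the relaxed count can never be smaller.

**ΔΔCt.** Relative qPCR quantification normalises target Ct to a reference
gene per condition, subtracts the control condition's ΔCt and reports
$2^{-\Delta\Delta Ct}$; per-replicate SEMs of the mean Ct propagate in
quadrature through both subtractions into a fold-change interval.

# The synthetic-data generator

Every stage draws from a named RNG stream derived from one master seed
(`stream_seed()`), so adding or reordering stages never perturbs another
stage's draws, and identical configurations produce byte-identical fixture
files.

The default toy genome is six 1-Mb chromosomes (I–V, X): large enough for
±5 kb windows with a 6-kb edge margin, small enough for sub-second tests.
Coverage is Poisson counts over a 10-bp bin grid: uniform background plus
Gaussian-mixture enrichment at features — a double peak flanking the TSS
for me3, broad TSS enrichment for me2, a TSS valley with flanking bumps and
a strong central enhancer peak for me1. Genotype effects are multiplicative
factors per (genotype, mark, feature class): the `rbbp5` defaults are 0 for
every mark (loss of all methylation), the `wdr5` defaults reduce me3
(0.2), redistribute me2 from TSS (0.5) toward enhancers (1.8) and elevate
me1 (1.5–1.6). Enhancers default to 400 bp; no standard width exists, so
it is a configuration knob rather than a claim.

The differential-expression generator draws lognormal baselines
(meanlog $\log 200$, sdlog 1.2) and assigns up/down labels with defaults
`frac_up = 0.15`, `frac_down = 0.07` — more up- than down-regulated genes,
the observed structure for these mutants — and `x_gene_fraction = 0.15`,
roughly the chrX share of *C. elegans* genes. Down-regulated genes are
drawn with a higher baseline (meanlog shift +3). The shift is deliberately
expressed on the *baseMean* scale outcome: because
$\text{baseMean} = \text{baseMeanA}(1 + 2^{\log_2FC})/2$, up-regulation
itself inflates baseMean by roughly $(1+2^{|lfc|})/2$ while down-regulation
deflates it, so a shift large enough to dominate that mechanical factor is
required for down genes to be the high-expression class in baseMean terms —
the structure in which the net change statistic is negative even with an
excess of up-regulated genes. Designated DEG have $|\log_2FC|$ drawn from a
normal truncated below 1 and adjusted p uniform below 0.05; null genes have
fold changes within ±1 and adjusted p uniform on (0.05, 1]. Per-condition
means satisfy `baseMeanB = baseMeanA * 2^lfc` and
`baseMean = (A + B)/2` exactly.

What the generator does **not** emulate: fragment-length and GC effects,
read-level sequences, mappability, replicate covariance structure,
peak-shape heterogeneity and the long-range correlation of real chromatin.
Passing tests therefore demonstrate the correctness of the computations and
their behaviour under the assumed statistical structure, not the biological
fidelity of any particular dataset.

# Numerical choices and problem sizes

* All on-disk and in-memory coordinates are 0-based half-open; conversion
  to 1-based closed intervals happens only at the `GenomicRanges` boundary.
* Inclusive thresholds throughout the peak filter; strict thresholds in DEG
  calling (see above).
* Simulation sizes used in the test-suite and acceptance computations were
  chosen for statistical stability at interactive runtimes: 100 seeded
  tables for the net-change sign, 20 seeds × (depth 1e5, 6 × 200 kb genome)
  for depletion recovery, 2000 multinomial draws for the goodness-of-fit
  type-I rate, 200 simulations each for the enrichment null and power, and
  20 random instances of up to 1000 peaks × 1000 features for the
  classification oracle. The end-to-end smoke run uses the full 6 × 1 Mb
  toy genome.

# Known limitations

* The scaling-factor convention (scale to the fewest spike reads) is a
  declared convention; vendors do not publish a unique formula.
* The six-feature midpoint rule and the TTS window width are decisions,
  not inferences; both are configurable arguments.
* `weighted_chisq_uniformity()` inherits the usual $\chi^2$ caveats for
  small expected counts; with chromosome-scale totals this is immaterial.
* Plot rendering is out of scope: the package returns tidy summaries
  (profiles, percentages, enrichment tables) ready for any plotting layer.
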