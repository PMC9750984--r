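---
title: "Quantitative spike-in ChIP analysis with ChIPRx: models and methods"
author: "ChIPRx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative spike-in ChIP analysis with ChIPRx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChIPRx)
```

# The quantification problem

Per-library normalisation makes ChIP-seq insensitive to global changes in a
histone mark: if a mutant loses half its H3K36me3 everywhere, reads-per-
million tracks for mutant and wild type are indistinguishable. Spiking a
fixed exogenous chromatin fraction (here modelled after a *Drosophila*
admixture at 20% of the target cell count) into every sample before
immunoprecipitation provides an internal standard. Reads are split by
genome of origin into four tallies per sample — target IP (`H_IP`),
spike-in IP (`D_IP`), target input (`H_in`), spike-in input (`D_in`) — and
everything quantitative in this package derives from them.

# Spike-in scaling

The default initial scaling factor for sample $i$ is $C / D_{IP,i}$: a
sample that captured more exogenous signal is scaled down proportionally.
The input-corrected variant,
$C \cdot (H_{in,i}/D_{in,i}) \cdot (H_{IP,i}/D_{IP,i})$, first normalises
the IP spike-in fraction by the input spike-in fraction, absorbing
sample-to-sample differences in admixture; the two variants coincide
whenever input spike-in fractions are equal. The constant $C$ is cosmetic:
factors are then *max-adjusted* — divided by the group maximum within one
ChIP antibody — so the largest factor is exactly 1 and every factor is a
usable downsampling fraction in $(0, 1]$. Max-adjustment is idempotent and
the grouping key (the antibody) is the caller's responsibility, since
designs differ in whether inputs are shared across genotypes; the package
accepts per-sample inputs.

Scaling is *applied* by per-fragment Bernoulli downsampling under a caller
seed (`downsampleFragments`). We chose independent Bernoulli thinning over
exact without-replacement subsampling because it composes cleanly (the
expected tally after thinning is exactly `fraction` times the tally
before), it is the behaviour contract of the standard downsampling tools,
and it is reproducible: a seed plus input determines the kept set
bit-for-bit. Track values are never multiplied by the factor — scaling
happens once, at the fragment level.

The global mark level
$(H_{IP}/D_{IP}) \,/\, (H_{in}/D_{in})$
is a depth-invariant occupancy estimate: multiplying all four tallies of a
sample by any constant leaves it unchanged, which the tests verify on 1000
random count vectors.

# Windowed negative-binomial differential testing

Reads are resolved to assignment points: stranded entries are extended to
the fragment length (default 300 bp) from their 5′ end and represented by
the extended fragment's midpoint; unstranded entries are treated as
complete fragments and their midpoint is used directly. Points are counted
into windows tiling each chromosome from position 0 — window 300 bp for
histone marks, 250 bp for tagged-histone binding, sliding step 100 bp by
default (the step is exposed because only the window size is canonical;
`step = window` gives a non-overlapping tiling).

Counts are assumed to be on a common scale already (spike-in downsampling
upstream); no further library normalisation is applied. Per window, the
two group means are compared by a likelihood-ratio test of equal
negative-binomial means with a shared dispersion, referred to
$\chi^2_1$. The dispersion $\alpha$ in
$\mathrm{Var} = \mu + \alpha\mu^2$ is estimated by method of moments —
pooled within-group variance per window — then stabilised by pooling
across windows of similar mean (20 quantile bins of the pooled mean, one
moment estimate per bin, floored at $10^{-4}$). At 2–3 replicates a
per-window estimate is hopeless; the binned estimator averages hundreds of
windows and empirically restores calibration: on 5000 null windows
(mean 50, dispersion 0.1, 3 vs 3) the fraction of $p < 0.05$ lands near
0.05 (the acceptance suite asserts $[0.03, 0.07]$).

Fold change is $\log_2((m_2 + c)/(m_1 + c))$ with pseudocount $c = 1$ to
avoid infinities at zero counts. All-zero windows report $p = 1$ and fold
change 0. Benjamini–Hochberg adjustment is computed at window level
(the adjustment procedure is the field default; nothing in the method
depends on it beyond monotonicity), significant windows are split by
direction, and overlapping or abutting same-direction windows merge into
differential regions carrying the minimum window $p$ and adjusted $p$, the
count-weighted mean fold change, and their window support. Two preset
modes mirror the two ways the test is used: `marks` selects windows at
adjusted $p < 0.05$; `ha` calls windows at raw $p < 0.001$ and then
filters regions at adjusted $p < 0.05$ and $\log_2\mathrm{FC} > 0$. All
filter cutoffs are strict inequalities.

# Interval algebra

Replicate consensus is *base-level*: the consensus of $n$ replicate peak
sets at support $k$ is the set of maximal intervals covered by at least
$k$ replicates ($k=1$ is the merged union, $k=n$ the $n$-way
intersection). We chose base-level coverage over peak-level voting because
it reproduces the intersected-regions semantics exactly and admits a
trivial independent oracle (a per-base boolean mask), against which the
implementation is checked on 1000 random instances.

Two distinct overlap rules coexist deliberately. Enhancer-style
intersections keep only intersected pieces *strictly longer than 50 bp*
(a 50-bp piece is dropped; 51 bp is kept); adjacent pieces arising from
book-ended peak pairs are merged in the output. Exclusive differential
peaks use the opposite extreme: a differential region of one pairwise
comparison is exclusive only if it shares *not a single base* with any
differential region of the other two comparisons. The post-hoc
disjointness of the three exclusive sets is asserted in the tests.

Feature assignment takes each peak's midpoint with precedence
promoter > exon > intron > distal; the promoter is TSS ± 2000 bp by
default (configurable — no canonical definition exists). Nearest-gene
assignment minimises |TSS − midpoint|, breaking exact ties toward the
lower-coordinate TSS; distances are signed in gene orientation.

# Motif scanning and enrichment

Position probability matrices become log-odds scores
$\log_2((p + \varepsilon)/b)$ against the background $b$, discretised onto
a uniform grid of 1/1000 of the score range per unit. On the integer
grid, the exact distribution of the total score of a random background
k-mer is computed by dynamic-programming convolution of the per-position
score distributions; window p-values are exact tail probabilities of that
distribution, and the test suite verifies them against exhaustive
enumeration of all $4^k$ k-mers for $k \le 6$. Zero probabilities at zero
pseudocount are mapped far below every finite score so they can never
reach a finite threshold. Both strands are scanned (the minus strand via
the reverse-complemented matrix with its own exact null distribution);
windows containing non-ACGT characters are skipped.

Known-motif enrichment resizes target and background regions to a fixed
300-bp width centred on their midpoints, extracts sequences, and counts a
sequence as hit if it contains at least one occurrence at the scanning
threshold (ZOOPS). Over-representation is a one-sided hypergeometric tail
on the pooled target-plus-background universe; the cited discovery tools
do not document a single canonical statistic, so the choice is recorded in
the output columns, and a cumulative-binomial user can substitute their
own from the reported counts. The enrichment heatmap collects the union
of each peak list's top-20 motifs by ascending p (ties broken by name)
and fills absent cells with exactly 1.

# ChIP-qPCR

Percent input corrects the input Ct for its dilution
($\log_2(1/f)$ cycles at input fraction $f$, default 1%):
$\%input = 100 \cdot 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$,
and mark enrichment is normalised by the total-H3 percent input of the
same region and sample.

# What the simulators emulate — and what they do not

Every generator is a pure function of (seed, parameters); reruns are
bit-identical, and each records its ground truth (true occupancies,
planted regions and folds, planted motif offsets) so downstream scoring
needs no access to generator internals.

- `simulateSpikeInExperiment` draws the four tallies as Poisson with
  target IP mean `depth × occupancy`, spike-in means `depth × 0.20`
  (mirroring the 20% admixture), inputs occupancy-independent. This
  emulates admixture and IP efficiency, not mappability, duplication or
  chromatin accessibility structure.
- `simulateDifferentialTags` draws per-window NB counts (default mean 50,
  dispersion 0.1 — a mid-coverage, moderately overdispersed regime typical
  of 2–3-replicate histone ChIP) and multiplies the second group's mean by
  the planted fold inside planted regions. Fragments are emitted as
  fixed-length 300-bp records with midpoints uniform in their window, so
  extension and counting round-trip the simulated counts exactly. Planted
  regions default to a few percent of windows in the validation runs
  (100 regions of 900 bp on a 3-Mb chromosome), the desk-scale analogue of
  thousands of differential enhancers genome-wide; region-level error
  rates depend on that true fraction, which is why it is part of the
  stated conditions. Real data additionally have peak-shaped (non-uniform)
  signal, GC and mappability trends and unequal library sizes — passing
  these tests demonstrates the statistics, not robustness to those
  artefacts.
- `simulateGenome` is i.i.d. at a stated GC; it has no repeats, so motif
  false-positive structure in real genomes is not represented.
  GC-matched backgrounds for enrichment are obtained by construction
  (target and background drawn from the same generator) rather than by
  re-weighting.

# Numerical choices and degenerate inputs

Coordinates are BED 0-based half-open at every file boundary and 1-based
closed GRanges inside, converted only in the readers and writers
(round-trips are bit-identical). Chromosome names match by exact string
equality; no aliasing is attempted. Points beyond the recorded chromosome
length are clamped into the last window with a warning. Zero spike-in IP
counts, empty scaling groups, empty peak sets where a distribution is
requested, and missing total-H3 rows are errors naming the offending
sample or region; empty fragment tables, sequences shorter than a motif,
and all-N sequences are quietly empty results. Dispersion estimates are
floored at $10^{-4}$; the score-grid granularity bounds the discretisation
error of any window score by one grid unit.

# Problem sizes used in validation

The bundled validation runs use a 1.5-Mb chromosome (5000 windows) for
null calibration, a 3-Mb chromosome with 100 planted 4-fold regions for
recovery, 1000 random 10-kb instances for the interval-algebra oracle,
motifs of width ≤ 6 for exhaustive enumeration, and 200 sequences of
300 bp for planted-motif recovery — sizes chosen so the full suite
exercises every code path at meaningful statistical resolution while
remaining a routine desk-scale run.

# Known limitations

No GLM covariates, paired designs or input-subtraction testing modes; no
BigWig output (bedGraph only); no de novo motif discovery; fragment-level
input is required (alignment, duplicate marking and quality filtering are
upstream of this package's contract).
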