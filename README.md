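# ChIPRx

Quantitative, spike-in normalised differential histone-mark analysis in R.

Conventional ChIP-seq is blind to global shifts in a histone modification:
every sample is sequenced to an arbitrary depth, so a cell line that loses
half of its H3K36me3 genome-wide can look identical to its parental line
after per-library normalisation. ChIP-Rx solves this by mixing a fixed
proportion of exogenous chromatin (e.g. *Drosophila* S2 cells, 20% of the
human cell count) into every sample before immunoprecipitation. Reads from
the exogenous genome act as an internal standard: they calibrate samples
onto a common quantitative scale and make global differences measurable.

`ChIPRx` implements the downstream analysis for experiments of this design,
for epigenomics analysts who have already aligned and filtered their reads:

- **Spike-in scaling** — per-sample scaling factors from spike-in IP read
  counts (optionally corrected by the input spike-in fraction), max-adjusted
  so the largest factor is exactly 1, applied by seeded Bernoulli
  downsampling.
- **Global mark level** — the depth-invariant ratio of ratios

  ```
  global level = (H_IP / D_IP) / (H_in / D_in)
  ```

  where `H` and `D` count target-genome and spike-in reads in the IP and
  input libraries.
- **Windowed differential testing** — fragment extension, sliding-window
  counting, a negative-binomial likelihood-ratio test per window with
  moment-estimated, mean-binned dispersion, Benjamini–Hochberg correction,
  merging of significant windows into directional differential regions, and
  filtering at `padj < 0.05` and `log2FC > 0`.
- **Peak-set algebra** — base-level replicate consensus (`>= k of n`
  replicates), intersections keeping only overlaps longer than 50 bp,
  exclusive differential peaks (no shared base with the other two pairwise
  comparisons of a three-genotype design), genomic feature distribution and
  nearest-TSS annotation.
- **Coverage tracks and TSS profiles** — per-base bedGraph tracks of scaled
  samples and strand-aware binned tag-density profiles around TSS.
- **Motif machinery** — PWM log-odds scanning with *exact*
  dynamic-programming p-values, ZOOPS hypergeometric known-motif enrichment
  of target vs background regions (regions resized to 300 bp), and the
  union-of-top-20 enrichment heatmap (missing p-values set to 1).
- **ChIP-qPCR** — percent-input enrichment normalised to total H3.
- **Synthetic data** — seeded generators for genomes, two-genome spike-in
  read populations, replicate fragment sets with planted differential
  regions, enhancer interval sets, and planted motif occurrences, each with
  recorded ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(ChIPRx)

# spike-in counts for two samples; the second has lost half its mark
sim <- simulateSpikeInExperiment(424, c(full = 1, half = 0.5), depth = 1e5)
globalMarkLevel(sim$counts)
#>      full      half
#> 0.9915839 0.4921474

scalingFactors(sim$counts, inputCorrect = TRUE)
#> ScalingFactors for 2 sample(s)
#>   sample initial_sf adjusted_sf
#> 1   full   25.44499   1.0000000
#> 2   half   12.49803   0.4911784
```

The global level recovers the simulated truth (1 vs 0.5), and the adjusted
factors say: keep every fragment of `full`, keep ~49% of `half`'s fragments
to place both on the same per-spike-in scale.

```r
# differential regions between two genotypes, 3 replicates each
sl <- c(chr1 = 3e6)
planted <- GenomicRanges::GRanges("chr1", IRanges::IRanges(60001, 60900))
planted$fold <- 4
sim <- simulateDifferentialTags(11, sl, window = 300,
                                groups = c(wt = 3, mut = 3),
                                baseMean = 50, dispersion = 0.1,
                                planted = planted)
wc <- countWindows(extendFragments(sim$fragments, 300),
                   tileWindows(sl, 300, 300), group = sim$samples)
diffWindows(wc, mode = "marks", direction = "up")$filtered
#> GRanges object with 1 range and 5 metadata columns:
#>       seqnames      ranges strand |   direction log2FoldChange     pvalue
#>   [1]     chr1 60001-60900      * |          up        2.02115 1.9562e-07
#>             padj  nWindows
#>   [1] 0.00142632         3
```

The single planted 4-fold region (true log2FC = 2) is recovered exactly,
with no false calls elsewhere on the 3-Mb chromosome.

A thin command-line front end over the same functions is installed at
`system.file("scripts", "chiprx.R", package = "ChIPRx")` with subcommands
`simulate`, `scale`, `qpcr`, `track`, `diffwindows`, `consensus`,
`intersect`, `exclusive`, `annotate`, `motifscan`, `motifenrich` and
`heatmap`; every randomised stage takes `--seed` and reruns are
byte-identical.

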