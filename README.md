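# cohloop

Chromatin-loop, virtual 4C, A/B-compartment and somatic-variant analysis
for Hi-C and whole-exome data, as used in studies of cohesin
haploinsufficiency in germinal-center B-cell lymphoma. The package is
aimed at computational biologists who have *filtered* Hi-C read pairs and
per-caller somatic variant tables and want the downstream statistics —
loop calling, differential enhancer–promoter loop analysis, viewpoint
tracks, compartment scores, consensus variant filtering — as tested,
reusable R functions rather than a pipeline of one-off scripts. A seeded
synthetic-data generator with known ground truth makes every stage
verifiable end to end without any downloads.

## The statistics at the core

**Loop calling.** Contacts are binned into a sparse matrix at 20 kb. For
each diagonal *d* (all pixels at genomic distance *d*), background moments
(mean *m*, variance *s²*) are fitted over every pixel at that distance —
structural zeros included, with extreme outlier pixels masked and the fit
repeated so loops do not inflate their own background. Pixel counts are
tested against NB(*r*, *p*) with the method-of-moments size
*r* = *m*²/(*s*² − *m*) (Poisson when *s*² ≤ *m*); p-values are inclusive
upper tails P(X ≥ x), corrected genome-wide by Benjamini–Hochberg.
Significant loops satisfy **FDR < 0.1 and CPM > 30**, where
CPM = count × 10⁶ / total depth. Differential loop strength over the
cross-sample union is log₂((CPMₐ + 1)/(CPM_b + 1)). Aggregate peak
analysis averages distance-normalized windows around loops and scores the
center against the lower-left background corner.

**Virtual 4C.** Pairs with exactly one mate within ±10 kb of a viewpoint
add a count to every 20 kb window (stepping 1 kb, 95% overlap between
neighbors) containing the distal mate; window counts are reported as CPM.

**Compartments.** At 100 kb, the observed/expected matrix (diagonal-mean
normalized, lightly box-smoothed) is correlated bin-by-bin; the leading
eigenvector of the correlation of that correlation matrix, scaled to
[−1, 1] and sign-oriented so that H3K27ac-rich bins score positive, gives
the per-bin compartment score (A > 0 > B). Sample comparisons use per-bin
delta scores and Pearson track correlations.

**Somatic filters.** Variants reported by ≥ 2 of Strelka2/MuTect/VarScan
are kept, then filtered: depth ≥ 30, alt reads ≥ 5, tumor VAF ≥ 10%,
germline VAF ≤ 1%, not in dbSNP, consequence in {missense, synonymous,
stop-gained, frameshift, splice-region, NMD-transcript}. Percent genome
altered sums copy-number segment lengths with |log₂ ratio| > 0.1 over the
genome size; per-gene tallies count mutated samples per cohort group.

## Worked example

Simulate a 20 Mb chromosome with three loops planted at an 8× (condition
A) versus 4× (condition B) contact enrichment, call loops, classify them,
and quantify the differential signal:

```r
library(cohloop)
loops <- data.frame(chrom = "chr1", bin1 = c(150L, 420L, 700L),
                    bin2 = c(154L, 424L, 703L), A = 8, B = 4)
cfg  <- sim_config(chrom_sizes = c(chr1 = 2e7), depth = 1e6,
                   planted_loops = loops, seed = 7)
simA <- simulate_contacts(cfg, "A", seed = 7)
simB <- simulate_contacts(cfg, "B", seed = 8)
matA <- bin_pairs(simA$pairs, cfg$chrom_sizes, cfg$resolution, "tumor_A")
matB <- bin_pairs(simB$pairs, cfg$chrom_sizes, cfg$resolution, "tumor_B")

loopsA <- call_loops(matA)
loopsA
#> loop_set 'tumor_A': 3 significant loop(s) at 20000 bp (93951 pixels tested; FDR<0.1, CPM>30)
#>     chrom  bin1  bin2 count   cpm       pvalue          fdr
#> 1:   chr1   150   154   245   245 3.401020e-26 1.065098e-21
#> 2:   chr1   420   424   318   318 9.554392e-38 4.488223e-33
#> 3:   chr1   700   703   543   543 9.361061e-55 8.794811e-50

ann <- simulate_annotations(simA$truth, loops_covered = 1)
table(classify_loops(loopsA, ann$promoters, ann$enhancers)$class)
#> P-E
#>   3

dl <- differential_loops(union_loops(loopsA, call_loops(matB)), matA, matB)
dl[, .(chrom, bin1, bin2, cpm_a, cpm_b, log2fc = round(log2fc, 2))]
#>     chrom  bin1  bin2 cpm_a cpm_b log2fc
#> 1:   chr1   150   154   245   175   0.48
#> 2:   chr1   420   424   318   152   1.06
#> 3:   chr1   700   703   543   222   1.29
```

All three planted pixels — and nothing else among ~94,000 tested — come
back significant, every loop is classified promoter–enhancer (the
simulated annotations cover all planted loops), and the per-loop log₂
fold-changes scatter around the planted log₂(2) = 1 (per-pixel sampling
noise moves individual loops; the mean here is 0.94).

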