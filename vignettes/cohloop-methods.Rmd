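---
title: "Methods: loop calling, virtual 4C, compartments and somatic filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop calling, virtual 4C, compartments and somatic filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohloop)
```

cohloop implements the 3D-chromatin and somatic-variant computations used in
cohesin-haploinsufficiency lymphoma studies: chromatin-loop calling from
Hi-C contact matrices, differential enhancer–promoter loop analysis,
virtual 4C viewpoint tracks, A/B compartment scoring, and consensus
somatic-variant filtering. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices where several
reasonable options existed. Every number quoted here is computed by the
package's own tests or the acceptance script; nothing is asserted that the
code does not verify.

## Input model and coordinates

The package starts from *filtered* Hi-C read pairs: four columns
(chrom1, pos1, chrom2, pos2), positions 0-based bp. Alignment-level
filtering (multi-mapped, duplicated, self-ligated reads) is assumed to have
happened upstream; cohloop neither emits nor consumes FASTQ/BAM. All
intervals are 0-based half-open internally; 1-based coordinates appear only
where users paste browser coordinates (`parse_viewpoint("chr3:133,544,706")`
subtracts 1 on ingestion).

`bin_pairs()` builds a per-chromosome sparse upper-triangular contact
matrix at a fixed resolution (20 kb for loop analyses, 100 kb for
compartments). Bin `k` covers `[k*res, (k+1)*res)` clipped at the
chromosome end. Inter-chromosomal pairs are counted into `total_depth` but
not stored: every downstream analysis here is cis. CPM normalization
divides by the *total* sequencing depth of the sample (intra + inter),
matching how virtual 4C tracks are depth-normalized; an intra-only
denominator can be obtained by constructing the matrix from intra pairs
only. No matrix balancing (ICE/KR) is applied — the loop test below
operates on raw counts within each diagonal, which conditions out
bin-level coverage differences to first order, and balancing would break
the count model.

## Loop calling: a negative-binomial test per diagonal

Contact frequency decays steeply with genomic distance, so pixel
significance is always judged against distance-matched background. For
each distance `d` (in bins) we pool all pixels at that distance across
chromosomes — the background is defined per *diagonal*, not per
chromosome — and fit moments over **all** pixels at that distance,
including structural zeros inside the tested range; omitting zeros would
inflate the background mean. With mean `m` and variance `s²`, the
negative binomial size is the method-of-moments `r = m² / (s² − m)`; when
`s² ≤ m` the diagonal falls back to Poisson. The p-value of a pixel with
count `x` is the inclusive upper tail `P(X ≥ x)`; `x = 0` gives exactly 1.

Method-of-moments is deliberately simple: it is deterministic, closed-form
and directly testable against brute-force tail sums (the test suite checks
agreement to 1e−9 for counts up to 500 across a parameter grid).

**Outlier-masked refitting.** Focal enrichments — the loops being looked
for — sit inside the diagonals used to estimate their own background, and
a handful of strong loop pixels can inflate the moment variance enough to
halve power. `fit_diagonals()` therefore iterates (twice by default):
pixels that are extreme under the current fit (per-diagonal Bonferroni at
`mask_alpha = 0.01`) are removed and the moments refitted. On loop-free
matrices the masking almost never triggers (expected masked pixels per
diagonal ≈ 0.01), so the null fit is essentially unchanged; `refit = 0`
restores the single-pass estimator.

**Multiple testing.** Benjamini–Hochberg is applied once across all tested
pixels genome-wide — one family, the more conservative reading; a
per-diagonal family is available via `bh_scope = "diagonal"`. Structural
zeros have p-value exactly 1, so the step-up is computed on the non-zero
pixels with the family size set to the full pixel count — algebraically
identical to materializing the zeros. Ties are resolved by a stable sort
on (p, chrom, anchors).

**Retention.** A pixel becomes a loop iff `FDR < 0.1` **and**
`CPM > 30` — both thresholds configurable; both conditions are necessary,
so a pixel at FDR 0.01 with CPM 10 is rejected. The default tested range
is 2–100 bins (40 kb – 2 Mb at 20 kb): distance 1 is dominated by
unresolved fragment-level structure and beyond ~2 Mb focal loops are
rare and the counts too sparse for per-diagonal moments.

**Differential loops.** The union of significant loops from either sample
(exact pixel matching) is re-quantified in both matrices — including in
the sample that did not call the loop — and reported as
`log2((cpm_a + c) / (cpm_b + c))` with pseudocount `c = 1` CPM.
The implementation computes `log2(cpm_a + c) − log2(cpm_b + c)`, which is
bitwise antisymmetric under swapping the samples; the log-of-ratio form is
not, in floating point. Retention thresholds apply at calling time per
sample; the union keeps anything retained in at least one sample.

**Aggregate peak analysis.** For each loop, a `(2w+1)²` window (default
`w = 5`) of distance-normalized values (pixel count ÷ empirical diagonal
mean) is extracted and averaged across loops; the enrichment score is the
center value over the mean of the `w×w` lower-left corner (the
shorter-distance background quadrant). Eligibility requires anchors at
least `w` bins from the matrix edges, at least `w` bins above the minimum
tested distance, and loop distance `d ≥ 2w + 1` — the last condition keeps
the background corner (which reaches distance `d − 2w`) off the diagonal.

## Loop classification

An anchor *holds* a feature iff the feature interval overlaps the 1-bin
anchor interval by at least 1 bp — no flanking extension, no minimum
overlap fraction, since neither is dictated by the biology at 20 kb
anchors. A loop is promoter–enhancer (P-E) iff one anchor holds a
protein-coding gene promoter and the other holds an enhancer (H3K27ac
peak), in either orientation. Anchors can hold both feature types;
ambiguity is resolved by the fixed precedence
P-E > P-P > E-E > P-other > E-other > other, so class counts always
partition the loop set. Promoters are consumed as given intervals; the
package does not reconstruct TSS windows or filter by strand.

## Virtual 4C

Given a viewpoint (default ±10 kb flank), a read pair qualifies iff
*exactly one* mate lies inside the viewpoint interval; pairs with both
mates inside are discarded as self-interactions carrying no distal
information. The viewpoint chromosome is tiled with windows of 20 kb
stepping 1 kb — adjacent windows overlap by 95% of their length — anchored
at coordinate 0, with the final partial window clipped. Each qualifying
pair adds one count to *every* window containing its distal mate: an
interior point lies in exactly `window/step = 20` windows. Window counts
are CPM-normalized by the sample's total depth. Because of the distance
decay, the global maximum of any v4c track sits immediately beside the
viewpoint; interactions of interest are read from the profile beyond the
near-viewpoint decay, and the test suite checks that a strongly planted
viewpoint-anchored loop is the maximum among distal windows.
Per-window log2 fold-changes between conditions use the same
pseudocount-and-log-difference form as differential loops.

## A/B compartments

At 100 kb resolution, each chromosome's matrix is transformed to
observed/expected by dividing each pixel by its diagonal mean (computed
over unmasked bins), which removes the distance decay. Bins with zero
marginal counts are masked before any correlation; chromosomes with fewer
than 10 usable bins are masked entirely with a warning.

The O/E matrix is then box-smoothed over ±2 bins (±200 kb): compartment
structure is megabase-scale, so this pooling suppresses pixel shot noise
without blurring blocks. The per-bin score is the leading eigenvector of
the correlation of the bin–bin Pearson correlation matrix — PCA on the
correlation matrix, where the compartment checkerboard is sharpest —
rescaled by its maximum absolute entry into [−1, 1]. Both refinements are
plain averaging operations, deterministic, and exposed as parameters
(`oe_smooth = 0`, `second_order = FALSE` restore the textbook
single-correlation eigenvector). The published likelihood-based c-score
tool is intentionally not reimplemented: every downstream quantity (delta
scores, track correlations, A/B labels against H3K27ac) depends only on a
signed per-bin score, and the package's tests validate recovery of planted
truth rather than agreement with any external binary.

The eigenvector's sign is arbitrary, so it is oriented with reference
information: bins in the top quartile of an H3K27ac-like per-bin signal
(peak-overlap counts from `bin_reference_peaks()`; a signal-mean variant
can be supplied equally) must average positive, defining A = active.
Repeated runs on the same input are bitwise identical: `eigen()` on a
fixed symmetric matrix is deterministic and the orientation rule breaks
the sign ambiguity. Labels are A for score > 0, B for score < 0, NA for
masked bins. `delta_cscore()` is the per-bin difference on jointly scored
bins, and `track_correlation()` the Pearson correlation over them (also
applicable to two delta tracks).

## Somatic variant filtering

Per-caller tables (Strelka2, MuTect, VarScan — the callers themselves are
never run; the module consumes their tabulated output) are merged by the
key (sample, chrom, pos, ref, alt). One record per alt allele is assumed.
Only variants reported by at least two callers survive; numeric fields
come from the first reporting caller in a declared priority order
(alphabetical by default). The hard filters then apply, in fixed order for
reporting: total depth, supporting reads, tumor VAF, germline VAF, dbSNP
membership, consequence class. The exclusion rules are phrased strictly
(depth < 30, alt reads < 5, tumor VAF < 10%, germline VAF > 1%), so
retention is inclusive at each boundary: depth ≥ 30, alt ≥ 5,
VAF ≥ 0.10, gVAF ≤ 0.01. Zero depth makes the tumor VAF undefined and
fails the depth rule. The retained consequence set is
{missense, synonymous, stop_gained, frameshift, splice_region,
NMD_transcript} — "silent" mapped to synonymous and "truncating" expanded
to the stop-gained/frameshift/splice-region/NMD classes — and is
configurable. Each variant's verdict records the *first* failing rule, so
the per-rule counts plus the retained count always partition the input.

Percent genome altered sums the lengths of copy-number segments with
log2 ratio strictly above 0.1 (gain) or strictly below −0.1 (loss),
divided by the genome size; segments at exactly ±0.1 count as unaltered.
Overlapping segments within a sample are rejected. The statistic is
additive over chromosomes and invariant to splitting a segment at the
same log2 value. `gene_mutation_tally()` counts, per panel gene and
cohort group, the samples carrying at least one retained variant (set
semantics — a sample with five hits in a gene counts once), reporting
zero rows for genes absent from all samples.

## The synthetic-data generator

Every stage above is validated against simulated data with known truth,
generated by `simulate_contacts()`, `simulate_annotations()` and
`simulate_variant_tables()`.

Read pairs are drawn by inverse-CDF sampling over the intra-chromosomal
pixel universe (distances 1 to n−1 bins) with unnormalized weight
`d^(−α) × checkerboard factor × loop enrichment`, then scattered uniformly
within each bin. This gives closed-form expected pixel means
(`depth × weight / total weight`, available as `expected_pixel_count()`)
so recovery tests can compare against analytic truth. Overdispersion
enters through per-pixel gamma rate multipliers with mean 1 and variance
equal to the `dispersion` parameter, producing negative-binomial marginals
— the model the loop caller assumes. Defaults, chosen once as realistic
study-scale conditions:

* toy genome of two 20 Mb chromosomes at 20 kb (1,000 bins each) —
  large enough for ~190,000 tested pixels, small enough for
  minutes-scale test runs (the test suite and acceptance script run the
  full pipeline dozens of times in under a minute);
* decay exponent α = 1, the canonical Hi-C contact-probability regime;
* dispersion 0.05 — mild overdispersion typical of deep libraries; real
  per-diagonal dispersion is not published for these data, so the value
  is a parameter, not an assertion;
* checkerboard via alternating A/B blocks with a same-label contact
  boost ≥ 1 (1.5 in the compartment tests);
* H3K27ac-like 1 kb reference peaks emitted per bin with probability
  0.6 in A blocks and 0.05 in B blocks;
* no diagonal (d = 0) pixels: self-ligation products are filtered
  upstream of this package's inputs (`bin_pairs()` still accepts them).

What the generator does *not* emulate: fragment-level biases (GC,
mappability, restriction-site density), trans contacts, TADs and
insulation structure, copy-number-driven coverage waves, and duplicated
reads. Passing tests therefore demonstrate correctness of the statistical
machinery under a clean generative model matching its assumptions — not
robustness to every artifact of real libraries. The absence of bias
structure is also why no matrix balancing is needed on simulated data.

Annotation simulation places a promoter inside one anchor and an enhancer
inside the other for a requested fraction of planted loops, plus uniform
random decoys. Variant simulation stratifies 200-variant tables across
every filter dimension (caller count, depth, alt reads, tumor and
germline VAF, dbSNP, consequence) with a deterministic 13-row boundary
grid — each rule at, just below and just above its threshold — exposed as
`boundary_variant_fixture()`; truth labels are computed from the rule
definitions at generation time.

## Numerical choices and degenerate inputs

* NB tail probabilities come from `pnbinom(x−1, lower.tail = FALSE)`;
  counts of 0 give p = 1 exactly.
* Diagonals with fewer than `min_pixels` (default 20) pixels, or with
  zero mean, are skipped and no loops called there.
* Log2 fold-changes are computed as differences of logs so that swapping
  samples negates results bitwise; pseudocount 1 CPM keeps them finite.
* Empty matrices, empty loop sets, viewpoints with no qualifying pairs,
  and fully masked chromosomes return empty/NA results with warnings
  rather than errors, so pipelines degrade gracefully.
* All stochastic operations take a single integer seed; identical seeds
  give byte-identical outputs.

## Problem sizes used in validation

The acceptance checks run: 20 loop-free simulations (2 × 20 Mb, 2 × 10⁵
pairs) for false-discovery control; 50 planted loops at enrichment 4 and 8
(depth 10⁶, expected loop CPM 51–307) for recall; a 25-point NB parameter
grid × 501 counts against brute-force tail sums; 10⁴ random pairs against
a brute-force window recount for virtual 4C; two same-truth compartment
replicates (5 × 10⁵ pairs at 100 kb, 2 Mb blocks, 1.5× boost); ten loops
planted at a 2:1 enrichment ratio for differential recovery; 20 planted
vs 20 random anchors for APA; and 200 stratified variants plus the
boundary grid for the filters. These sizes were chosen so the entire
validation completes in about a minute on one CPU while leaving
comfortable statistical margins.

## Known limitations

* The loop background is fitted per diagonal genome-wide; strong
  chromosome-specific coverage differences would call for per-chromosome
  backgrounds (not needed under the generator, which has none).
* The compartment score is an eigenvector surrogate with its own scale;
  it is comparable between samples processed by this package but not
  numerically interchangeable with published c-score outputs.
* Consequence strings are matched verbatim against the configured
  retained set; harmonizing heterogeneous annotation vocabularies (e.g.
  full VEP terms) is the caller's responsibility.
* The v4c track reports raw overlapping-window counts; neighboring
  windows share 95% of their reads and are therefore strongly
  autocorrelated by construction — fold-change profiles should be read
  accordingly.
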