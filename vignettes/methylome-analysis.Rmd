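---
title: "Calling, comparing and interpreting social-insect methylomes with methCaste"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, comparing and interpreting social-insect methylomes with methCaste}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methCaste)
library(GenomicRanges)
library(SummarizedExperiment)
```

## The analysis problem

Whole-genome bisulfite sequencing of a social insect colony yields, for
every CpG dyad and every library, a pair of counts: reads in which the
cytosine survived bisulfite conversion (evidence of methylation) and reads
in which it converted. The design this package targets is the classic
caste-and-sex layout: four phenotypes — alate (winged reproductive) and
worker, each in male and female form — with two bisulfite replicates each
(8 methylomes) and three stranded transcriptome replicates each (12
libraries). The questions it answers are the ones such studies ask: which
sites and genes are methylated at all; what the methylome looks like along
genes, around promoters and repeats; which 200-bp windows differ between
castes or sexes; whether those differences exceed what replicate shuffling
produces by chance; how methylation relates to expression level, expression
noise and antisense transcription; and which regulatory motifs concentrate
around differentially methylated cytosines.

Plus- and minus-strand cytosines of one dyad are combined into a single
site keyed by the plus-strand C, reflecting the symmetric-methylation
assumption of CpG methylation. All genomic data live in the standard
Bioconductor containers: the genome is a `DNAStringSet`, annotations are
`GRanges`/`GRangesList` inside a `GeneAnnotation` object, and counts are a
`BSCounts`, a `RangedSummarizedExperiment` subclass with assays `M` and
`U`.

## Methylation calling with spike-in calibration

Truly unmethylated cytosines still produce "methylated" reads at the
bisulfite conversion-error (deamination) rate. That rate is estimated from
an unmethylated lambda spike-in as unconverted reads over total read
cytosines (`estimateConversionError()`), optionally cross-checked against
non-genic non-CpG cytosines with a warning when the two estimates disagree
by more than two-fold. The estimate is floored at a configurable minimum
(default `1e-6`) so that a perfectly converted control still yields a
usable success probability.

Per sample, each site with coverage of at least 4 reads — the strict
reading of "more than three reads" — is tested with the upper-tail
binomial probability of its unconverted count under the error rate,
`P(X >= m | n = cov, p = err)`. P-values are Benjamini–Hochberg adjusted
*within each sample over its testable sites* (per-library calling matches
per-library sequencing), and a site is called methylated below FDR 0.01.
Pooling across samples always means summing raw counts before testing,
never averaging fractions, so deep pooled data gain power exactly as a
merged library would. Fractional methylation is `m/(m+u)` per site, and a
feature's fraction is the count-weighted `sum(m)/sum(m+u)` over its CpGs
(the unweighted mean of site fractions is emitted alongside for
comparison); features with no covered CpG are `NA`, never 0.

Gene-level status is "methylated" when at least one exon CpG is methylated
in the pooled calls; an exon+intron variant is available through
`geneMode`, since reasonable definitions differ and both are useful.

## Methylome geography

`metageneProfile()` bins CpG fractions into 40 length-normalised gene-body
bins plus 20 fixed-width flank bins per side (2 kb), strand-flipped to run
5'→3'; an absolute mode profiles the first and last 4 kb instead. The bin
counts are a granularity choice — fine enough to show intragenic trends,
coarse enough that a few hundred genes fill every bin.
`junctionProfile()` aggregates fractions by bp offset around internal
exon–intron boundaries, exon side negative, truncating (never padding)
when a feature is shorter than the span. `cpgObsExp()` computes the CpG
depletion measure `N_CG * L / (N_C * N_G)`; the `L` (not `L-1`) numerator
is stated explicitly because both variants circulate. Deciles of gene-body
methylation are equal-sized by rank with ties broken by stable gene-id
order. Repeat methylation is compared per class (exon-intersecting,
intron-intersecting, non-genic) against the containing feature excluding
the repeat's own CpGs, or a ±2 kb flank purged of repeat and gene bp for
non-genic repeats — the flank width is our choice of "surrounding
region"; repeats need at least 3 covered CpGs to enter. Cross-species
ortholog methylation classes are a straight 8-way partition of complete
1-to-1 triplets.

## Differential methylation

Windows are fixed 200-bp tiles (terminal remainder kept). For a caste
test the four alate libraries (both sexes) face the four worker libraries;
for a sex test the grouping is analogous. A window is testable when at
least 3 of 4 samples per side have window-summed coverage of at least 5
reads (">4 reads") *and* the window contains a CpG methylated in at least
half of all 8 samples. Whether the "methylated in half" rule should apply
per window or per constituent CpG is genuinely open; we apply it as "at
least one member CpG methylated in ≥ 4 of 8 samples", which keeps sparse
but consistently methylated windows testable.

The test models replicate counts as beta-binomial with group mean `pi` and
precision `theta` (`alpha = pi*theta`, `beta = (1-pi)*theta`). Group
proportions are fitted by bounded one-dimensional likelihood search; the
statistic is the likelihood-ratio `2(l_alt - l_null)` referred to
chi-square with 1 df. The reference pipeline for such window tests uses an
approximate-df test whose details are unpublished; we use the chi-square(1)
LRT and validate calibration by simulation instead — on null
beta-binomial data the p-values are uniform (KS p > 0.1 at 5,000 windows)
and the significant fraction stays below the nominal level.

`theta` is estimated by method of moments from the standardized squared
deviations of replicate fractions around their coverage-weighted cell
means, pooled over the window and its two flanking tiles (the "local
dispersion" idea: 200 bp of context on each side stabilises the estimate);
a finite-replicate correction is applied, the estimate is clamped to
`[1, 1e6]`, and identical replicates sit at the ceiling (no
overdispersion). With no flanking data the window-only estimate is used.
Simulations with true `theta = 15` recover a median estimate near 15
(inside [10, 22] over 100 runs of 50 windows).

Significance combines FDR < 0.05 (BH within each comparison — caste and
sex are distinct families) with an absolute difference above 15 percentage
points; the confident single-CpG (DMC) set uses FDR < 0.01 and > 20
points. A q-value of 1e-6 with a 14-point difference is deliberately not
significant. Adjacent significant windows with the same direction merge
into DMRs; each DMR is assigned the feature type of maximal bp overlap
with ties resolved exon > promoter > intron > downstream-2kb > intergenic,
and the gene whose territory (body + promoter + 2 kb downstream) it
overlaps most. A conservative gene list intersects the two constituent
pairwise comparisons and requires direction consistency.

## The permutation null

With 8 samples in balanced 4-vs-4 groups there are C(8,4)/2 = 35
unordered relabelings, 34 of them distinct from the true one.
`shuffleReplicates()` enumerates them and samples without replacement; the
100-iteration t-test procedure therefore samples schemes *with*
replacement, re-seeded per iteration — the only way to run 100 shuffles in
this scheme space. Shuffled runs go through the identical filtering and
significance path as the observed run (one shared internal function), in
either of two modes: the Welch two-sample t on per-replicate window
fractions (untransformed; an arcsine-sqrt variant was considered and
rejected as an undocumented extra knob) with the same BH + effect-size
filters, or the full beta-binomial test. The summary is the empirical
p-value `(1 + #{null >= obs}) / (1 + n)` and the fold of the observed
count over the null mean (floored at 1 so an all-zero null still yields a
finite fold).

## Expression and antisense integration

FPKM is `count * 1e9 / (length * library_total)`. Per gene we report the
within-morph replicate CV (sd/mean of FPKM, averaged over morphs; missing
when a morph mean is 0), the between-morph absolute difference of
`log2(FPKM+1)` morph means, and expression specificity. The source
analyses report a "specificity" without a formula; we use the tau index —
0 for uniform, 1 for exclusive expression — because it is the
field-standard choice, and it is isolated behind one function so it can be
swapped.

The antisense procedure excludes genes overlapping more than half of
another gene, estimates each library's global antisense read proportion
over the included loci only, tests every locus-library pair with the
upper-tail binomial against that proportion, BH-adjusts within the
library, and flags a gene when significant in more than a third of
libraries; the continuous metric is the mean antisense proportion across a
sample type's replicates. Methylation–expression association uses
Spearman correlations and an OLS fit of rank-transformed methylation on
standardized rank-transformed predictors, dropping zero-variance and
perfectly collinear predictors with warnings. Differential-expression and
differential-splicing calls are consumed as external tables; the package
only cross-tabulates them (rank-sum tests of CV and expression difference,
Fisher exact tests of the DMG-by-spliced table, DMR-to-spliced-exon
distances).

## Motif enrichment around DMCs

Test sequences are 150-bp windows centered on confident DMCs — 75 bp left
and 74 bp right of the anchor, one reading of "150 bp of genomic sequence
surrounding"; the width is a parameter for anyone preferring ±150.
Controls are built identically around methylated (> 30%) non-differential
cytosines within 1.5 kb of a test anchor whose windows do not overlap any
test window, which matches the controls' CpG-centered composition to the
tests'.

Scanning is FIMO-like: every position on both strands is scored with the
log2 likelihood ratio of the motif against the background, the per-position
p-value comes from the *exact* distribution of that score under the
background (a dynamic program over motif columns that merges equal score
values; enumeration over all k-mers confirms it exactly for motifs up to 8
bp), p-values are BH-adjusted over all scanned positions of a motif-set
pair, and a hit is q < 0.1. Background letter frequencies are estimated
from the pooled control sequences by default (uniform available by flag).
Mature miRNAs become near-point-mass PWMs (pseudocount 0.01) after U→T;
scanning both strands covers the target-site complement convention, and the
5' and 3' mature products of one hairpin are separate motifs.

Enrichment per motif is a one-sided Fisher exact test of
sequences-with-a-hit versus without, test against control, BH over motifs
— the simplest faithful surrogate for rank-based enrichment testing, and a
deliberate simplification. The headline fold statistic is size-normalised
hit counts, `(pos/n_pos) / (max(neg,1)/n_neg)`; the floor of the control
count at 1 is exactly what reproduces published values for motifs with
zero control hits. Phenotype specificity re-runs the Fisher test with the
other phenotype's test set as control and labels motifs caste/sex/ns.

## The synthetic-data generator

`simulationDesign()` encodes the study conditions: 4 phenotypes × 2
bisulfite replicates, 3 transcriptome replicates, bimodal gene-body
methylation (half the genes at `pi = 0.85`, the rest at 0 — in real data
"unmethylated" genes sit at the conversion-error floor, which the error
model supplies), spatial clustering of methylated genes (gaps between
adjacent methylated genes shrink with the cluster factor; factor 0 gives a
uniform multiset permutation of labels), conversion error 0.5%, and 20x
mean coverage. Planted caste/sex regions override `pi` per phenotype over
designated methylated gene bodies with a default contrast of 0.30.
Coverage is Poisson and methylated reads are binomial given coverage with
success `pi + (1-pi)*err` — deliberately the caller's own model, so
calibration tests probe the inference, not model mismatch. Expression is
negative binomial with log-normal morph effects; antisense counts are
binomial given library totals, elevated at designated loci. Each output
stream (sample, control, library) has its own RNG stream seeded from the
master seed and the stream name, so adding samples never reshuffles
existing ones and identical configurations reproduce byte-identical files.

What the generator does *not* emulate: read-level data (no FASTQ, no
mapping artefacts), sequence-composition biases, non-CpG methylation,
linked-site correlation beyond the gene-level block structure, and real
between-replicate overdispersion at unplanted sites (binomial given
coverage means `theta` is effectively infinite under the null). Passing
tests therefore demonstrate correctness of the statistical machinery under
its stated assumptions, not robustness to everything real libraries do.

## Numerical choices and test scale

Likelihood maximisation uses `optimize()` on `[1e-6, 1 - 1e-6]` with
tolerance 1e-7 (verified against a 1e-4-grid brute-force oracle to 1e-3).
The PWM-score dynamic program merges scores rounded to 9 decimals and
coarsens only if a support exceeds 2e5 points; tail look-ups use a 1e-6
absolute tolerance so rounding never drops the top score. Degenerate
Fisher margins return p = 1; Welch t-tests with zero pooled variance
return p = 1 when means agree and 0 when they differ.

The test and acceptance runs use desk-scale problems chosen to finish in a
few minutes while keeping every assertion well-powered: genomes of 1–2
scaffolds × 40–100 kb (3–25 k CpGs), 8–40 genes, 100-simulation batches
for calibration claims, 5,000 windows for null-uniformity checks, and 100
replicate shuffles for the permutation analyses. Dataset-scale headline
numbers (genome-wide methylation percentages, absolute DMG counts)
require the original sequencing data and are outside what synthetic
re-analysis can certify; the package instead certifies the properties that
make those numbers trustworthy: caller calibration, oracle agreement,
power and false-positive control on planted truth, permutation behaviour,
and byte-level reproducibility.

## Known limitations

Single-threaded throughout; the beta-binomial fit loops over windows in R,
fine at 10^4–10^5 windows but not tuned for mammalian-scale genomes.
5mC and 5hmC are indistinguishable in bisulfite data and no correction is
attempted. Methylation "blocks" are not called as discrete objects. The
antisense test conditions on a single library-wide rate and will be
conservative if antisense propensity varies systematically with expression
level.
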