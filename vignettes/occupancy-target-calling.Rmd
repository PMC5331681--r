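---
title: "Occupancy scoring and direct-target calling: models and methods"
author: "groscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy scoring and direct-target calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groscore)
```

# The scientific problem

Groucho (Gro) is a transcriptional corepressor: it binds no DNA itself but
is recruited by sequence-specific repressors, and it can repress promoters
from sites thousands of base pairs away. ChIP-seq of a corepressor
therefore yields binding sites whose regulatory target is ambiguous, and
differential expression after perturbing the corepressor is dominated by
indirect effects. `groscore` implements a reusable pipeline for the
integration step that resolves both ambiguities: quantify each gene's
binding evidence with a distance-weighted occupancy score, then ask at
which score stringency the set of bound genes becomes visibly enriched for
genes that respond to the perturbation, against baselines built from
random gene sets.

# Reproducible peaks and temporal dynamics

Peak calls from two replicates of one timepoint are combined by grouping
the pooled peaks into maximal mutually touching clusters (overlap of at
least 1 bp; half-open abutment is zero overlap and never suffices) and
keeping each cluster that contains at least one peak from both replicates.
The reported region is the merged union span of the supporting cluster:
the union preserves the full extent of the binding evidence for the width
and assignment analyses downstream, while the jointly covered
intersection span is available via `span = "intersection"`.

Temporal dynamics are classified on the union of the three timepoints'
reproducible sets: a region's membership is the subset of timepoints with
a peak overlapping it by at least 1 bp, giving seven non-empty classes
that partition the region universe, and the derived unique-to-one and
constitutive fractions.

Each peak is assigned to its closest gene: distance 0 for overlap with the
gene span, otherwise the gap between closest edges, with the base adjacent
to the gene at distance 1. Ties are broken by the smaller gap to the TSS
and then by lexicographic `gene_id` — the data give no reason to prefer
either neighbour, so the rule only has to be deterministic. Signed
distances are negative upstream of the TSS relative to gene strand.

## The Monte Carlo peaks-per-gene null

Clustering of peaks around genes is tested by comparing the observed mean
number of peaks per associated gene with the same statistic under random
placement: each iteration re-places the observed width multiset uniformly
(chromosome drawn with probability proportional to its length, start
uniform so the interval fits, overlaps allowed, no mappability mask unless
an exclusion set is supplied) and reassigns nearest genes. The empirical
p-value uses the add-one estimator `(r + 1)/(n + 1)`, which never reports
zero. Each iteration derives an independent RNG stream from
`(seed, operation, iteration)`, and the caller's RNG state is restored on
exit.

One calibration subtlety is worth recording. The statistic
`peaks / distinct genes hit` is a ratio of small integers; on a tiny
instance it takes few distinct values, observation and null draws tie
often, and the `>=`-counting add-one estimator becomes conservative —
a uniformity check would then reject for a reason that has nothing to do
with the placement model. The packaged calibration check therefore uses an
instance (200 genes, 150 peaks) on which ties are rare; at that resolution
the p-values are uniform (KS test at alpha = 0.01 over 200 repetitions of
99 iterations).

# The occupancy score

For a gene g and a peak P, every base b of P is weighted:

* weight 1 if b lies within the gene span;
* weight `1 / (1 + exp(0.0005 * (d - 15)))` otherwise, where `d` is the
  distance in bp from b to the nearest end of the gene.

The peak's score is the mean weight over its bases, and the gene's
occupancy score is the sum of its peaks' scores. The logistic is shallow
(weight 0.5 at 15 bp, still about 0.27 at 2 kb, below 0.01 only beyond
about 9.2 kb), deliberately allowing distant binding sites to contribute —
the appropriate shape for a long-range corepressor.

Numerical and convention choices:

* **Distance origin.** "Distance between the basepair and the nearest end
  of the gene" needs a convention for the adjacent base; the default sets
  it to `d = 1` (`d0 = 1`), with the `d0 = 0` variant available. All
  analyses use one convention throughout; the difference is a one-base
  shift of the logistic.
* **Exact summation.** Peak means are computed by evaluating the logistic
  over the run of integer distances each flank spans — no sampling, no
  approximation; agreement with a naive per-base loop at 1e-12 relative
  tolerance is part of the test suite.
* **Inclusion radius.** Peaks whose nearest edge lies beyond
  `max_distance = offset + ln((1 - eps)/eps)/steepness` (about 9,205 bp at
  defaults, `eps = 0.01`) contribute less than `eps` per base and are
  skipped; this changes any gene score by less than `n_peaks * eps` and
  makes the all-genes scan subquadratic. `eps = 0` forces every
  same-chromosome peak in.
* **Non-exclusive scoring.** A peak may contribute to several nearby
  genes; the score is defined per gene over peaks, and distance weighting
  (not exclusive assignment) is what encodes locality.
* **Gene span, not exon union,** defines "overlapping the gene" — the
  simplest reading, since nascent transcription covers introns.

# Target calling

Genes are classified as differentially expressed when the adjusted
p-value is strictly below 0.05 and |log2 fold-change| is at least 0.5
(inclusive); genes with a missing adjusted p-value are excluded. The
usable direction is down-regulation under corepressor overexpression:
up-regulated and loss-of-function curves are expected to track their
randomized controls, and the pipeline declares "none detected" for them.

The response curve evaluates, at every distinct positive score taken as a
cutoff of decreasing stringency, how many genes meet the cutoff
(`n_above`) and how many of those are DE (`n_de_above`). The baseline
repeats the count on random gene sets of the same size drawn uniformly
without replacement from the scored universe — 100 repetitions by default,
reported as per-cutoff mean and SD. The universe is the scored gene table
the caller supplies, conventionally the genes expressed in the
corresponding condition pair. Its per-cutoff mean converges to the
hypergeometric expectation `set_size * n_above / N`, which the tests check
at 10,000 repetitions within three per-draw hypergeometric SDs and within
2% relative.

The threshold is the inflection of the experimental curve, found by
fitting a continuous two-segment piecewise-linear model with exhaustive
breakpoint search (at least three points per segment). The fit's abscissa
is the number of genes meeting the cutoff — the axis on which such curves
are plotted and judged. This choice matters: under score-independent DE
labels the expected DE count is exactly proportional to the number of
genes above threshold, so the null curve is a straight line in this space;
against the bare cutoff rank, ties in the score distribution bend the null
curve and systematically reward the two-segment model. A threshold is
declared only when the change in slope is clearly evident, encoded by two
guards: the two-segment fit must improve the single-line SSE by at least
20%, and the experimental DE count at the breakpoint must be at least
twice the baseline mean there. Otherwise the result is "none detected" —
a first-class outcome, not an error. The final high-confidence set is the
union over timepoints of genes at or above that timepoint's threshold that
are DE in the stated direction there.

# Pausing analysis

Chromatin-associated RNA coverage proxies Pol II positioning. For each
gene the promoter-proximal window is the first 300 bp downstream of the
TSS (strand-aware; the conventional pausing-region scale — the window,
body definition and 600 bp minimum gene length are all configurable), the
body is the remainder of the span, and the pausing statistic is the ratio
of the two densities. Genes with zero body density have an undefined ratio
and are excluded from set comparisons rather than folded in as infinities.

Set enrichment uses two tests, chosen to avoid distributional assumptions:
a permutation test on the difference of median log ratios (add-one
p-value, gene labels permuted) for continuous comparisons, and a one-sided
hypergeometric test for categorical Pol II classes, including top-quartile
vs rest classes derived from a numeric pausing index. Metagene profiles
length-normalize each gene's strand-oriented coverage to a fixed number of
bins by exact area-preserving binning (linear interpolation of the
cumulative coverage, which is exact for per-bp step functions) and
normalize each gene's profile to sum to one before averaging, so highly
expressed genes do not dominate; a global, depth-weighted variant is the
obvious alternative and per-gene normalization is the default.

# The synthetic-data generator

Because no deposited accessions accompany the analysis, every input is
emulated with known ground truth. The default preset defines the study
conditions used by the tests and the acceptance script:

* 2,000 non-overlapping genes (log-normal lengths, median 2 kb, clamped to
  0.7–20 kb; 2–5 exons; strands balanced) on four 2.5 Mb chromosomes;
* 50 true repression targets, each carrying `1 + Poisson(1.5)` planted
  binding regions (mean 2.5) centered near the gene 5' end or a random
  interior anchor (Normal jitter, SD 500 bp, half/half) so both the
  overlap branch and the logistic branch of the score are exercised;
  400 noise regions placed uniformly;
* peak widths log-normal with median 600 bp (clamped 50–5,000 bp);
  every region emitted into both replicates with independent edge jitter
  (SD 10 bp), so replicate intersection recovers planted regions;
* temporal membership of every region drawn from class weights that put
  58% of sites in a single timepoint and 9% in all three, the site-level
  dynamics pattern of a transiently binding corepressor;
* DE tables with targets at log2 fold-change Normal(-1.5, 0.4) and
  Beta(1, 100) adjusted p-values at the timepoints where they are bound,
  and a 5% spurious DE rate among null genes (realized exactly:
  accidentally significant non-selected genes are pushed back above the
  alpha threshold, so the configured rate is the observed rate);
* stranded coverage with a proximal/body ratio of 5 for targets vs 1 for
  background, scaled to one million reads, with optional per-50-bp
  Poisson noise (off, the configured ratios are recovered exactly).

Planted regions are mutually non-overlapping by rejection sampling, which
keeps every ledger count exact. The `tiny` preset (100 genes, one 0.5 Mb
chromosome, 10 targets) runs the full pipeline in seconds and backs most
unit tests; `genome_scale` approaches fly-genome dimensions.

What passing tests on these data do **not** show: the generator plants
independent, non-overlapping, rejection-spaced peaks and noiseless
log-normal score geometry; real ChIP-seq peaks have correlated widths and
enrichments, mappability holes, copy-number artifacts and antibody
batch effects, and real DE tables have correlated errors across genes.
Recovery of planted targets (mean sensitivity and precision at or above
0.8 over 20 seeds) validates the statistical machinery, not performance
on any particular real dataset.

# Problem sizes and runtime choices

The test suite and acceptance script size their simulations as follows:
formula-exactness checks on 200 random peak/gene instances; interval
oracles on 100 instances of up to 500 intervals; Monte Carlo calibration
at 200 repetitions of 99 iterations (200 genes x 150 peaks) plus a
1,000-iteration run on the clustered default preset; baselines at 10,000
repetitions on a 500-gene instance; recovery over 20 seeds of the default
preset and 100 null-label runs. Nearest-gene assignment is implemented as
a vectorized plain-numeric scan per chromosome (with an explicit tie-rule
fallback) precisely so these Monte Carlo loops stay fast; its equivalence
to an exhaustive quadratic oracle is itself under test.

# Known limitations

* The score treats all peaks equally; enrichment-weighted variants are out
  of scope by design.
* The breakpoint model fits exactly one slope change; curves with two
  regimes of enrichment would be truncated at the stronger break.
* The placement null has no mappability model beyond an optional exclusion
  set.
* Absolute genome-scale counts (total binding sites per timepoint, the
  size of a real high-confidence target list) depend on the genome
  annotation and sequencing data of a real experiment and are not
  reproducible from synthetic inputs; all validation here is
  property-based.
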