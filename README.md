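# groscore

Identifying the direct repression targets of the *Drosophila* corepressor
Groucho (Gro) by integrating temporally staged ChIP-seq binding data with
differential expression under corepressor perturbation. The package is
aimed at regulatory genomicists who have peak calls (BED6/narrowPeak),
gene models (GTF/BED12) and DESeq2-style differential-expression tables,
and need the bespoke integration statistics rather than another peak
caller or DE engine.

## The model

A corepressor recruited by many different DNA-binding repressors acts at a
distance, so a bound site does not identify its target gene, and most
expression changes after perturbing it are indirect. The pipeline's core
statistic is the per-gene **occupancy score**: every base of a ChIP-seq
peak overlapping the gene span scores 1, every non-overlapping base scores
the logistic distance decay

&nbsp;&nbsp;&nbsp;&nbsp; w(d) = 1 / (1 + e^(0.0005 (d − 15)))

with *d* the distance in bp to the nearest end of the gene; per-peak means
are summed over a gene's peaks. The shallow decay (w = 0.5 at 15 bp, below
0.01 only beyond ~9.2 kb) lets distal sites contribute, as expected for a
long-range corepressor.

Genes ranked by score are intersected with the genes down-regulated upon
corepressor overexpression (|log2FC| ≥ 0.5, adjusted p < 0.05): for score
cutoffs of decreasing stringency, the number of DE genes among genes above
cutoff is compared with the average over 100 random gene sets of matched
size. A continuous two-segment piecewise-linear fit (exhaustive breakpoint
search, in the space of DE count vs number of genes above cutoff) locates
the inflection; the threshold is accepted only when the fit improves a
single line by ≥ 20% and the curve sits ≥ 2× above its randomized
baseline — otherwise "none detected". High-confidence targets are the
union over timepoints of genes above threshold and DE there.

Around this the package provides replicate-reproducible peak derivation
(≥ 1 bp overlap between replicates), temporal dynamics classes, nearest
gene assignment, a Monte Carlo placement null for peak clustering per
gene, promoter-proximal pausing analysis of chromatin-associated RNA
coverage (proximal/body density ratios, metagene profiles, permutation
and hypergeometric enrichment), and a synthetic-data generator with
ground truth that makes the whole pipeline testable offline.

## Worked example

A complete synthetic dataset (tiny preset: 100 genes, 10 planted targets
on one 0.5 Mb chromosome) stands in for real inputs; `read_peaks()`,
`read_genes()`, `read_de_table()` and `read_coverage()` load the same
structures from files.

```r
library(groscore)

sim <- simulate_dataset(sim_config("tiny", seed = 42))
reproducible <- lapply(sim$peaks, function(x)
  intersect_replicates(x$rep1, x$rep2))

classify_temporal(reproducible)
#> Temporal peak classes over 54 regions
#>       t1       t2       t3    t1,t2    t1,t3    t2,t3 t1,t2,t3
#>        6       16        3        0        0       25        4
#> unique-to-one fraction: 0.463, constitutive fraction: 0.074

peaks_per_gene(assign_nearest_gene(reproducible$t2, sim$genes))
#> 45 peaks over 31 associated genes; mean 1.452 peaks/gene, 35.5% of genes with >= 2 peaks

peaks_per_gene_null(reproducible$t2, sim$genes, sim$chrom_sizes,
                    iterations = 999, seed = 42)
#> observed mean peaks/gene 1.452 vs null mean 1.292 (999 iterations): empirical p = 0.067

res <- run_pipeline(sim)    # scores genes, calls targets per timepoint
res$call
#> high-confidence targets (down-regulated): 10 genes across 3 timepoints
#>   t1: threshold score 0.2451 at cutoff rank 13 (SSE improvement 95.0%, separation 5.49x): 5 targets
#>   t2: threshold score 1.458 at cutoff rank 11 (SSE improvement 98.3%, separation 9.18x): 9 targets
#>   t3: threshold score 1.393 at cutoff rank 8 (SSE improvement 94.4%, separation 8.86x): 7 targets
res$recovery[c("sensitivity", "precision")]
#> $sensitivity [1] 0.9
#> $precision   [1] 0.9

pr <- pausing_ratio(sim$genes, sim$coverage)
compare_sets(pr, sim$truth$true_targets,
             setdiff(pr$gene_id, sim$truth$true_targets),
             n_perm = 999, seed = 42)
#> permutation test (999 perms): median log-ratio difference 1.618, p = 0.001
```

Reading the output: at this small scale most binding regions are
transient (46% single-timepoint, 7% constitutive), bound genes carry 1.45
peaks on average, and the placement null shows that with only 45 peaks the
clustering excess is not yet significant (p = 0.067; at the default
2,000-gene preset the same test reaches the minimal p of 1/1001). All
three timepoints show clear response-curve inflections, recovering 9 of
the 10 planted targets with one false call, and the called targets'
promoter-proximal transcript density exceeds the background at the
minimal permutation p — the paused-polymerase-like signature planted in
the coverage.

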