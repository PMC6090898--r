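# bactx

Coverage-based operon reconstruction, differential expression and cre-site
prediction for bacterial transcriptomes.

`bactx` implements the computational core of a comparative bacterial RNA-seq
study design: two strains (or conditions) sequenced with strand-specific
RNA-seq, compared for differential expression, functional-category
enrichment and carbon-catabolite regulation. Every stage is also covered by
a synthetic-data generator with full ground truth, so the whole pipeline is
testable end to end without any external sequencing data.

## What it computes

**Operon reconstruction from per-base coverage.** Adjacent same-strand genes
are merged into one operon when (i) the absolute log2 ratio of their mean
coverages is below a multiple (default 1) of the genome-wide standard
deviation of neighbor-pair log ratios, and (ii) no intergenic base between
them has zero coverage. Genes with mean coverage below 2 are excluded
entirely and break adjacency. Transcript edges (TSS/TTS) are found by
walking outward from the first/last gene while per-base coverage stays at
or above `edge_fraction` (default 0.5) of the flanking gene's mean and
above zero, up to `max_extension` (default 500 bp); the walked distances
are the 5′ and 3′ UTR lengths.

**Differential expression.** Counts are normalized as RPKM
(c·10⁹ / (L·N), with L the gene length in bp and N the library size).
Per-gene negative-binomial dispersions are estimated by method of moments
and shrunk toward a trimmed-mean common value (prior weight 10 residual
df). The test is an exact conditional NB test: counts are scaled to the
geometric-mean library size, group sums are compared conditionally on
their total, and the two-sided p-value is the probability of all outcomes
no more likely than the observed one. Fold changes are signed ratios of
pseudo-count-augmented RPKM group means (|FC| ≥ 1 always; a negative sign
means lower in the first condition). A gene is called DE when |FC| ≥ 2 and
p < 0.05.

**Category enrichment by resampling.** For the DE set of size n, 10,000
random sets of n genes are drawn without replacement from the gene
universe. A category with k observed DE genes gets an empirical p-value
equal to the fraction of resamples with at least k random genes in the
category, and is called enriched when that fraction is below 0.05.
`hypergeometric_tail()` provides the analytic reference.

**cre-site scanning.** A degenerate IUPAC consensus is converted to a PWM
(by default with extra weight on the consensus base of each position, so
that a perfect site is statistically distinguishable), scored as log2
odds against a 0-order background over every window on both strands, and
each score is converted to an exact p-value by dynamic programming over a
discretized score lattice (distribution scores rounded up, query scores
down, so reported p-values never underestimate). Hits below 10⁻⁶ are
reported and assigned to the nearest downstream gene 5′ end within 300 bp
on each strand.

**Synthetic data.** `simulate_dataset()` plants operons (sizes drawn from
a weight vector), log-uniform expression levels, lognormal per-base
coverage noise, NB counts with planted signed fold changes (2–9 fold) in a
DE fraction of genes, a functional category with boosted DE odds, and cre
consensus sites in a fraction of promoters — all recorded in a `truth`
object, which the pipeline scores itself against.

## Worked example

```r
library(bactx)

cfg <- sim_config(n_genes = 300, seed = 42)
ds  <- simulate_dataset(cfg)

cov <- gene_mean_coverage(ds$track, ds$ann)
ops <- reconstruct_transcripts(cov, ds$ann, ds$track)
head(operon_table(ops), 4)
#>     operon_id   contig strand                                             genes
#> 1 operon_0001 contig_1      + gene_0001,gene_0002,gene_0003,gene_0004,gene_0005
#> 2 operon_0002 contig_1      + gene_0006,gene_0007,gene_0008,gene_0009,gene_0010
#> 3 operon_0003 contig_1      -                                         gene_0011
#> 4 operon_0004 contig_1      +           gene_0012,gene_0013,gene_0014,gene_0015
#>   n_genes   tss   tts utr5_len utr3_len
#> 1       5   450  7886       50       50
#> 2       5  7939 14929       50       50
#> 3       1 17347 15180       50       50
#> 4       4 17400 22540       50       50

de <- de_analysis(ds$counts, ds$ann)
head(de[order(de$pvalue), ], 4)
#>             gene_id        fc       pvalue is_de direction
#> gene_0293 gene_0293 -9.850429 1.007224e-20  TRUE      down
#> gene_0176 gene_0176  9.521302 3.350312e-20  TRUE        up
#> gene_0284 gene_0284 -9.969113 3.548542e-19  TRUE      down
#> gene_0215 gene_0215  9.894417 7.508964e-17  TRUE        up
sum(de$is_de)                  # 49 called; 44 were planted
#> [1] 49

set.seed(7)
enr <- resample_enrichment(ds$truth$category_map, de$gene_id[de$is_de],
                           n_resamples = 10000)
subset(enr, significant)
#>        category   N  K  n  k fraction significant
#> 2 Carbohydrates 300 39 49 18        0        TRUE

hits <- scan_motifs(cre_pwm(), ds$seqs)
head(hits[, c("contig", "start", "end", "strand", "score", "pvalue")], 3)
#>     contig start   end strand    score       pvalue
#> 1 contig_1   435   451      - 16.53877 6.405590e-07
#> 2 contig_1   435   451      + 21.56587 9.370233e-10
#> 3 contig_1 53334 53350      - 21.56587 9.370233e-10
nrow(hits)                     # 52 hits; 26 sites were planted
#> [1] 52
```

All 125 true operons are recovered exactly, the planted "Carbohydrates"
enrichment is found at an empirical fraction of 0, and every planted cre
site is detected (a perfect site scores highly on both strands, hence
52 = 2 × 26 hits).

The same analysis is available as a one-shot pipeline with on-disk
outputs (GFF3, bedGraph, TSV, BED, YAML summary, MD5 manifest):

```r
run_pipeline("out_dir", pipeline_config(sim = sim_config(seed = 1)))
```

or from the shell via `inst/scripts/run_pipeline.R`.

## Documentation

Function documentation is in roxygen comments alongside the code. The
methods vignette (`vignettes/bactx-methods.Rmd`) describes the generative
model, every parameter's default and units, the numerical design choices
(score-lattice p-values, consensus weighting, conditional NB law) and the
package's limitations.
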