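---
title: "Methods: coverage-based operon reconstruction, exact-test DE and cre-site scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based operon reconstruction, exact-test DE and cre-site scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactx)
```

`bactx` packages the analysis stack of a two-condition, strand-specific
bacterial RNA-seq comparison. This vignette documents the statistical
model behind each stage, the meaning and defaults of every tuning
parameter, and the numerical design decisions, so that results can be
interpreted — and the implementation audited — without reading the code.

## 1. Data model and coordinate conventions

All genomic intervals are **0-based, half-open** internally; GFF3 input
and output converts to/from the format's 1-based closed convention, and
bedGraph/BED share the half-open convention directly. Coverage is a pair
of per-base numeric vectors (plus/minus strand) per contig
(`coverage_track()`), counts are an integer matrix with explicit library
sizes and condition labels (`count_matrix()`), and gene models are a
validated data frame (`genome_annotation()`) that forbids duplicate ids,
inverted intervals and same-strand overlaps.

## 2. Operon reconstruction

Let `cov[g]` be the arithmetic mean per-base coverage of gene `g` on its
own strand. For every pair of *directly adjacent* genes on the same
contig and strand with positive coverage, define the neighbor log ratio
`r = log2(cov[left]/cov[right])`. The population standard deviation
`sigma_r` of all such ratios genome-wide calibrates what a "typical"
within-genome expression step looks like. Two adjacent genes join one
operon iff:

1. same strand, directly adjacent in the full gene order;
2. `|r| < sd_multiplier * sigma_r` (default multiplier 1);
3. no base of the intergenic span has zero coverage on that strand;
4. both genes have `cov >= min_gene_coverage` (default 2); genes below
   the floor are excluded from all operons and break adjacency.

Genes not merged with either neighbor form singleton operons.

Because `sigma_r` is estimated from the genome-wide ratio population,
the rule is only meaningful when that population mixes within-operon
pairs (small `|r|`) and cross-operon pairs (large `|r|`). On very small
genomes with no same-strand cross-operon pairs, `sigma_r` collapses to
the noise floor and true operons are split; the test suite therefore
calibrates on genomes of 40+ genes.

**Transcript boundaries.** From the strand-aware first gene of an
operon, the 5′ UTR is the number of bases one can walk upstream while
per-base coverage stays `>= edge_fraction * cov[first gene]` (default
0.5) *and* above zero, capped at `max_extension` (default 500 bp); the
3′ side mirrors this against the last gene. TSS/TTS are the outermost
transcribed bases in transcript orientation.

```{r operons, eval = FALSE}
cov <- gene_mean_coverage(track, ann)
ops <- reconstruct_transcripts(cov, ann, track)   # boundary_params() defaults
operon_table(ops)
```

## 3. Differential expression

**RPKM.** `compute_rpkm()` implements `c * 1e9 / (L * N)` exactly, with
`c` the raw count, `L` the gene length in bp and `N` the stated library
size (not the column sum). It is invariant under joint scaling of counts
and library sizes.

**Dispersion.** On counts normalized to a common library size, the
method-of-moments estimate per gene is
`phi = max(0, (s^2 - m) / m^2)` pooled across conditions by residual
degrees of freedom. The common dispersion is a 10%-trimmed mean across
genes, and tagwise values shrink the per-gene estimate toward it with a
prior weight of `prior_df = 10` residual df. With no replication the
estimator falls back to `phi = 0.1` with a warning.

**Exact test.** Counts are rescaled to the geometric mean of the library
sizes and rounded. Under the null the two group sums `Y_A`, `Y_B` are
sums of i.i.d. NB variables with the gene's dispersion; conditioning on
`T = Y_A + Y_B` removes the unknown mean, and the conditional law of
`Y_A` depends only on the replicate counts and `phi` (it reduces to
Binomial(`T`, `n_A/(n_A+n_B)`) as `phi -> 0`). The two-sided p-value sums
the probabilities of all outcomes no more likely than the observed one
(ties included with a 1e-12 relative tolerance). No multiple-testing
correction is applied; the DE call is `|FC| >= 2` and `p < 0.05`.

**Signed fold change.** With pseudo-RPKM 0.1 added to each group mean,
`FC = +m1/m2` if `m1 >= m2` else `-m2/m1`, where group 1 is the
lexicographically first condition label. `|FC| >= 1` always.

## 4. Category enrichment by resampling

The DE set of size `n` is compared against `n_resamples = 10000` random
draws of `n` genes without replacement from the whole annotated
universe. For each category the reported `fraction` is the proportion of
resamples whose category count reaches the observed `k`; `fraction <
0.05` calls enrichment. One shared set of resamples serves all
categories, so the per-category fractions are dependent — intended, as
each category's test is marginally valid. The analytic counterpart is
the hypergeometric upper tail (`hypergeometric_tail()`, computed by
direct binomial-coefficient summation); at 10,000 resamples the Monte
Carlo standard error at `p ≈ 0.05` is about 0.002, and `fraction = 0`
should be read as `p < 1e-4`.

## 5. PWM scanning with exact p-values

`pwm_from_iupac()` turns a degenerate IUPAC string into per-position
probabilities: allowed bases share `1 - gamma` (default `gamma = 0.04`),
disallowed bases share `gamma`; `N` stays uniform. For highly degenerate
consensi this alone caps how small a p-value any window can reach (for a
16-position consensus with many 2–4-fold degenerate positions, the best
attainable p-value is only ~3e-3), so `cre_pwm()` additionally gives the
consensus base of each degenerate position a `consensus_weight = 0.7`
share of the allowed mass. This keeps degenerate matches scoring well
while making a perfect site statistically identifiable (consensus
p ≈ 2.3e-10).

Scores are log2 odds against a 0-order background (the scanned genome's
mononucleotide frequencies by default); minus-strand scores reuse the
plus-strand machinery via the reverse-complemented matrix. Windows
containing `N` score `NA` and never become hits.

**Exact p-values.** The null score distribution is computed by dynamic
programming over an integer lattice of `lattice_bins = 1000` steps
spanning the score range: each position's four scores are discretized,
positions are convolved under the background, and the survival function
is tabulated. Distribution scores are rounded **up** to lattice points
and query scores **down**, so a reported p-value can never underestimate
the true one; the conservatism is bounded by the motif width times the
lattice step and shrinks as `lattice_bins` grows (the accuracy tests use
1e5 bins to hold relative error under 1% against exhaustive 4^w
enumeration). Hits with `p < 1e-6` are reported and assigned to the
nearest gene 5′ end within `promoter_window = 300` bp downstream of the
hit on each strand; a hit between divergent genes can serve both.

## 6. The synthetic generator

`sim_config()` defaults describe a realistic small bacterial
transcriptome experiment and are the sizes used throughout:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1900 | protein-coding genes |
| `operon_size_weights` | .45/.2/.15/.1/.06/.04 | P(operon has 1..6 genes) |
| `gene_length_range` | 300–2400 bp | uniform gene lengths |
| `intergenic_within_operon` | 5–40 bp | covered gaps inside operons |
| `intergenic_between_operons` | 150–400 bp | zero-coverage gaps |
| `utr5_len`, `utr3_len` | 50 bp | planted UTR plateaus |
| `expression_level_range` | 5–500 | log-uniform per-operon coverage |
| `coverage_noise_cv` | 0.1 | lognormal per-base noise |
| `nb_dispersion` | 0.1 | count overdispersion |
| `n_replicates` | 3 | per condition (2 conditions) |
| `de_fraction` | 0.07 | genes with planted folds |
| `de_fold_range` | 2–9 | planted |FC|, random sign |
| `enriched_category_boost` | 10 | DE odds multiplier in one category |
| `motif_plant_fraction` | 0.2 | promoters receiving a cre consensus |
| `total_lib_size` | 2e6 | reads per condition, lognormal split |

Realism and limits: coverage is a piecewise-constant plateau with
multiplicative noise — no fragment-level read model, no 3′ bias, no
antisense transcription; counts and coverage are generated consistently
from the same expression levels but independently noised; operon strands
are i.i.d. per operon. These simplifications keep every stage's ground
truth exact, which is the generator's purpose: all planted structure
(operon partition, folds, enriched category, site positions) is returned
in a machine-readable `truth` object and written as YAML by the
pipeline.

## 7. Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → operons → DE → enrichment → motif,
writing FASTA/GFF3/bedGraph/TSV/BED/YAML outputs plus a run log and an
MD5 manifest ending in a `complete`/`incomplete` status row. All
randomness derives from the single configured seed (the generator uses
fixed offsets per sub-stage), there are no timestamps, and floating
point is serialized at full precision (`%.17g`), so runs are
byte-reproducible. A default-scale run (~1900 genes, ~2.4 Mb genome)
takes well under a minute on one CPU; the test suite uses 40–300 gene
genomes and completes in about two minutes.

## 8. Limitations

- The exact test is unadjusted for multiple testing by design; at 1900
  genes and α = 0.05 tens of false positives are expected, which the
  |FC| ≥ 2 requirement largely absorbs.
- `sigma_r` calibration assumes a genome large enough to populate the
  neighbor-ratio distribution (Section 2).
- The scanner's 0-order background ignores dinucleotide composition;
  p-values on strongly skewed genomes should be interpreted with that
  in mind.
- Enrichment fractions are granular at 1/`n_resamples`; categories with
  `fraction = 0` are bounded, not estimated.
- The variant utilities (`count_substitutions()`, `list_mismatches()`)
  operate on pre-computed alignments; no aligner is included.
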