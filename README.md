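# smarmseq

Computational toolkit for low-input profiling of rRNA 2′-O-methylation
from read 5′-end frequencies, together with the single-embryo RNA-seq
computations that accompany such a study: ERCC spike-in absolute
quantification, intron-retention scoring, expression-based genotype
calling, and Mendelian segregation tests. It is aimed at groups applying
small-RNA template-switching library construction (SMARM-seq style
RiboMeth-seq) to tiny inputs such as pooled preimplantation mouse embryos,
and at anyone analysing spiked single-embryo / single-blastomere
transcriptomes.

Every estimator ships with a synthetic-data generator that records its
ground truth, so the whole pipeline can be validated end to end on data
with known answers.

## The model

Alkaline hydrolysis cleaves RNA at each internucleotide bond — except that
a 2′-O-methylated ribose at base *i* protects the bond 3′ of it. A cleavage
at the bond after base *i* creates a sequencing-read 5′ end at position
*i* + 1, so methylation at *i* depletes read starts at *i* + 1. With
*n<sub>j</sub>* the count of reads whose 5′-most aligned base is position
*j*, the per-base score is

> S<sub>i</sub> = 1 − n<sub>i+1</sub> / F<sub>i</sub>, clipped to [0, 1],

where *F<sub>i</sub>* is a weighted mean of *n* over the 2·k flanking
positions around *i* + 1 (defaults: k = 2, nearest-first weights 2:1).
S estimates the methylated fraction *m<sub>i</sub>*: flat coverage gives
S ≈ 0, complete protection gives S = 1. Scores are undefined where the
flank coverage falls below `cov_min` (default 10).

For spiked cohorts, a constant amount of ERCC RNA per embryo means the
per-sample spike total tracks capture efficiency; dividing any quantity by
`f_s = spike_total_s / median(spike totals)` puts samples on an absolute,
per-embryo scale. Intron retention uses the rule that a read is an
*effective intron read* only if a single aligned block shares **more than
3 contiguous bases** with a single annotated intron.

## Worked example

```r
library(smarmseq)

## ground truth: 20 methylated sites on a 2 kb rDNA-like reference
profile <- gen_methylation_profile(ref_length = 2000, n_sites = 20,
                                   fraction_low = 0.2, fraction_high = 1,
                                   min_spacing = 20, seed = 7)
track  <- simulate_end_counts(profile, depth = 300, seed = 8)
scores <- ribometh_score(track, k_flank = 2, weights = c(2, 1), cov_min = 10)
calls  <- call_methylated_sites(scores, score_min = 0.4, cov_min = 10)
head(calls, 4)
#>   position     score mean_flank_coverage called
#> 1      257 0.6456559            293.5000   TRUE
#> 2      327 0.6548223            295.5000   TRUE
#> 3      555 0.9712460            313.0000   TRUE
#> 4      670 0.4694362            280.8333   TRUE
```

The score column estimates the methylated fraction at each called
position; `mean_flank_coverage` is the local read-start level the
depletion was measured against. Comparing against the recorded truth for
the first sites (`position`, true `m`, estimated `S`): site 187 with
m = 0.25 scores 0.22 (below the 0.4 calling threshold), while sites 257,
327 and 555 with m = 0.70, 0.59 and 0.98 score 0.65, 0.65 and 0.97.

```r
## a spiked knockout-vs-control embryo cohort with recorded truth
design <- cohort_design(stages = "E3.0", n_null = 6, n_control = 6, seed = 1)
sim <- simulate_embryo_cohort(design)
f   <- ercc_scale_factors(sim$counts)
round(tapply(total_rna_abundance(sim$counts, f), sim$meta$genotype, mean))
#> control    null
#>   19129    6147

## genotype from deleted-region read counts: exact separation
calls <- call_genotype(setNames(sim$meta$region_count, sim$meta$sample_id),
                       mode = "region")
table(calls$label, sim$meta$genotype)
#>           control null
#>   control       6    0
#>   null          0    6

mendelian_chi_square(c(9, 18, 0), c(1, 2, 1))[c("statistic", "df", "p.value")]
#> $statistic 9   $df 2   $p.value 0.011109
```

The null embryos carry roughly a third of the control total RNA — the
per-biotype down-regulation written into the default cohort design — and
the spike normalization recovers it despite per-sample capture-efficiency
noise.

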