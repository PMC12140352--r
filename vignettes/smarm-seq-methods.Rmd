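---
title: "Scoring rRNA 2′-O-methylation and quantifying spiked single-embryo RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rRNA 2′-O-methylation and quantifying spiked single-embryo RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smarmseq)
```

This vignette documents the models implemented in `smarmseq`, the
parameters that matter, what the synthetic-data generators emulate (and
deliberately do not), and the numerical and design decisions a maintainer
should know about.

# The protection model behind the RiboMeth score

Alkaline hydrolysis cuts RNA at essentially every internucleotide bond.
A 2′-O-methylated ribose at base $i$ shields the phosphodiester bond on
its 3′ side, and a cut at the bond after base $i$ is what produces a
sequencing read whose 5′ end is position $i+1$. In a library built from
hydrolysed rRNA, the count $n_{i+1}$ of read starts immediately 3′ of a
methylated base is therefore depleted in proportion to the methylated
fraction $m_i$ of the molecules.

`ribometh_score()` turns this into a per-base statistic:

$$S_i \;=\; \mathrm{clip}_{[0,1]}\!\left(1 - \frac{n_{i+1}}{F_i}\right),
\qquad
F_i \;=\; \frac{\sum_{d=1}^{k} w_d\,(n_{i+1-d} + n_{i+1+d})}
               {2\sum_{d=1}^{k} w_d},$$

where $F_i$ is the weighted mean of the read-start counts over the $2k$
positions flanking $i+1$ (position $i+1$ itself is excluded). Under the
protection model $E[n_{i+1}] \approx (1-m_i)\,E[F_i]$, so $S_i$ estimates
$m_i$ directly: flat coverage gives $S \approx 0$ and complete protection
gives $S = 1$.

Several score variants of this depletion family exist in the literature,
differing in flank width and weighting. We fix one concrete, fully
testable variant and expose its knobs:

| parameter | default | meaning |
|---|---|---|
| `k_flank` | 2 | flank half-width in positions |
| `weights` | `c(2, 1)` | nearest-first flank weights |
| `cov_min` | 10 | minimum flank mean for a defined score |
| `score_min` | 0.4 | calling threshold in `call_methylated_sites()` |

The nearest positions are up-weighted because local coverage varies
smoothly; a wider flank buys variance reduction at the cost of bias next
to neighbouring methylated sites. With sites at least 20 bases apart
(the generator's default spacing) the windows never collide.

Two conventions are load-bearing and used consistently everywhere:

* **Offset convention.** Methylation at base $i$ is read out at
  start-count position $i+1$, because the protected bond is the one 3′ of
  the methylated ribose and the assay counts 5′ ends only.
* **Coordinates.** Everything internal is 0-based half-open; SAM
  (1-based) and GTF (1-based inclusive) are converted exactly once, at
  parse/write time. The biological 5′ end of a minus-strand read is the
  last base of its last aligned block, not its leftmost coordinate.

Site calling is deliberately plain thresholding ($S_i \ge$ `score_min`
with adequate flank coverage): at rRNA-scale coverage the score
separates methylated from unmethylated positions by a wide margin, and a
transparent rule is easier to audit than a model-based caller.
`compare_methylation()` treats replicate libraries as the unit of
replication and applies a per-position two-sample t-test; pooling reads
across replicates would overstate certainty.

# What the simulators emulate

Two simulators share the single protection model above, at different
levels of mechanism:

* `simulate_end_counts()` (*Poisson mode*) draws
  $n_j \sim \text{Poisson}(d\,(1-m_{j-1}))$ independently per position at
  depth $d$. This gives clean analytic expectations
  ($E[S_i] \to m_i$ as $d \to \infty$) and is what the recovery and
  bias checks use.
* `simulate_hydrolysis_reads()` (*fragmentation mode*) hydrolyses whole
  molecules bond by bond (bond after base $i$ cut with probability
  $p_\text{cut}(1-m_i)$), size-selects fragments to 20–60 nt — a
  small-RNA library regime — and appends a 10-base poly-A tail to each
  fragment, emulating the poly-adenylation step of template-switching
  library construction. It exercises the whole downstream path:
  `trim_polya()` (leftmost adapter occurrence at a 10% mismatch rate,
  exact matches taking precedence), `place_reads_exact()` (a k-mer
  lookup placement that stands in for an aligner at desk scale),
  5′-end counting and scoring.

The generators do **not** model sequencing errors, GC or ligation bias,
UMIs, or incomplete hydrolysis, and placement is exact-match only. A pass
on simulated data therefore demonstrates that the estimators are correct
under the stated model, not that the model captures every artefact of
real libraries. The Poisson independence assumption also ignores the
negative correlation between neighbouring fragment counts that true
fragmentation induces; the fragmentation mode covers that difference, and
the two modes agreeing per site (within ±0.1 at the depths used) is
itself one of the validation checks.

The cohort generator `simulate_embryo_cohort()` emulates spiked
single-embryo RNA-seq: per-gene log-normal baseline means, a per-sample
log-normal capture efficiency (sd 0.25 on the log scale), Poisson
counts, and a genotype effect — per-biotype down-regulation in null
samples (defaults 0.3× mRNA, 0.5× rRNA, 0.4× snoRNA, reflecting a
regulator whose loss destabilises rRNA, snoRNA and, through arrested
translation, mRNA), a zeroed knockout target gene, and a deleted-region
read count that is 0 in nulls and Poisson(30) in controls. ERCC rows
scale with capture efficiency only, because the spike volume added per
embryo is constant; a 10× lower spike mean emulates the per-blastomere
dilution when needed. Library-size confounding is exactly what the
ERCC normalization must remove, and the recorded truth lets the tests
verify it does.

# ERCC normalization and the quantification conventions

`ercc_scale_factors()` uses total-spike scaling:
$f_s = \text{spike total}_s / \text{median}_t(\text{spike total}_t)$,
and every normalized quantity is $X_s / f_s$. The median reference makes
the factors robust to a single failed library. Per-gene spike regression
would be an alternative; total scaling is simpler, deterministic, and
sufficient for class-level and fold-change summaries.

Other conventions: TPM excludes ERCC rows from the per-sample denominator
by default (TPM is reported for endogenous genes); `log2_fold_change()`
is an effect size on spike-normalized means with a symmetric pseudocount
and deliberately carries no significance machinery; rDNA feature
assignment (`quantify_rdna()`) gives each read to the feature with the
largest aligned-base overlap and leaves ties unassigned, a rule chosen
because it is deterministic and checkable against a per-base oracle.

# The intron-retention rule

A read is an *effective intron read* when a **single aligned block**
shares **strictly more than 3 contiguous bases** with a **single
intron** (so ≥ 4 bases; `min_more_than` is configurable). N-gaps are not
aligned bases and contribute nothing, which is what makes spliced reads
crossing an intron score zero. Exonic reads are those fully contained in
the exon union of at least one transcript (strand-agnostic, matching
common exon-counting defaults) and not effective intron reads; everything
else is excluded from the ratio. The reported statistic is the bounded
ratio $r = n_\text{intron} / (n_\text{intron} + n_\text{exonic})$; the
alternative intron/exon ratio is a one-line change and the rule
parameters are echoed in the output so the definition travels with the
numbers.

# Genotype calling and cohort statistics

Deleted-region mode calls null at ≤ 2 reads over the engineered deletion
and control at ≥ 10, surfacing everything between as `ambiguous` rather
than silently resolving it; the thresholds are conventions chosen to sit
far below any plausible control coverage. TPM mode splits
$\log(\text{value}+1)$ with a two-centroid Lloyd iteration initialized
deterministically at the min and max — seed-free by construction — and
marks samples within a margin (default 10% of the inter-center distance)
of the midpoint as ambiguous. The Mendelian test is the textbook
$\chi^2 = \sum_k (O_k - E_k)^2 / E_k$ against expected ratios, with the
p-value from the upper tail; `stats::chisq.test` serves as an
independent cross-check in the test suite, never as the implementation.

# Numerical choices and degenerate inputs

* Scores are clipped to $[0,1]$; $n_{i+1} \ge F_i$ (sampling noise or
  unmodelled enrichment) reports 0, never a negative fraction.
* Scores are undefined — `NA` with `coverage_ok = FALSE` — wherever the
  flank mean is below `cov_min` or the window leaves the track; the first
  and last bases of a reference are therefore never scored.
* A track must have at least $2k_\text{flank}+2$ positions; shorter
  tracks error rather than scoring an unusable window.
* `intronic_ratio()` with zero classified reads returns an `NA`-flagged
  row, not an exception; a sample with no informative reads is data.
* Zero spike totals, all-zero TPM columns, overlapping exons or features,
  infeasible site spacing, and degenerate cleavage probabilities
  (0 or 1) all fail fast with named errors.
* All generators draw through an isolated RNG scope keyed by their
  `seed` argument, so identical seeds give byte-identical output and the
  caller's RNG state is never disturbed.

# Validation problem sizes

The shipped checks use: a 2,000-base reference with 20 sites
($m \in \{0.25, 0.5, 0.75, 1\}$, spacing ≥ 20) at depth 300 over 50
replicate libraries for score bias, recall and precision; a 200-base
reference with 6 sites and $10^5$ retained fragments for the
fragmentation-vs-Poisson comparison (about 500 starts per position, at
which the per-site sampling noise of the comparison sits well inside the
±0.1 band); ≥ 1,000 random reads over random multi-transcript gene
models for the intron oracle; and cohorts of 10 null vs 10 control
embryos with 0.3× down-regulation for the normalization checks. These
sizes were chosen so each check is decisively powered at desk scale.

# Known limitations

* The score variant is one member of the published depletion-score
  family; absolute values from other tools may differ slightly even on
  identical tracks, though site ranking is stable.
* Placement is exact-match and single-reference; real SMARM-seq data
  needs an external aligner and a multi-copy rDNA-aware strategy
  upstream of `count_five_prime_ends()`.
* PCR-duplicate removal is position-based (the protocol has no UMIs), so
  at extreme depth on a short reference it collapses genuine distinct
  molecules; dedup is therefore optional and off in the simulator-driven
  checks.
* Differential expression beyond spike-normalized fold changes —
  dispersion modelling, shrinkage, multiple testing — is intentionally
  out of scope; the count matrices interoperate with dedicated packages
  for that.
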