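---
title: "srnapipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnapipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

srnapipe is a small non-coding RNA sequencing (sRNA-seq) analysis toolkit
built around a fully ground-truthed synthetic-data generator. It quantifies
seven sRNA species — miRNA (with 5' isomiR calling), tRNA, snoRNA, snRNA,
yRNA, 7SK and 7SL — from single-end short reads, profiles tRNA fragments by
anticodon family and position, tests for differential expression between
tumor subtypes (the four TNBC transcriptional subtypes BL1, BL2, M and LAR
are the built-in label set), and infers miRNA–mRNA Spearman correlation
networks. This vignette records the methods, the tunable parameters, and the
design decisions that were genuinely open.

## 1. The read-processing model

### Adapter trimming

Reads are single-end, ~50 nt, with a 3' sequencing adapter ligated after the
RNA insert (default adapter: the Illumina TruSeq small RNA 3' adapter,
`TGGAATTCTCGGGTGCCAAGG`; the adapter is always a configuration value).
`trim_adapter()` scans every start position for the full adapter, or for an
adapter *prefix* of at least `min_overlap` bases (default 5) running off the
read's 3' end, accepting a position when its mismatch fraction over the
overlap is at most `max_error_rate` (default 0.1) and cutting at the
leftmost qualifying position. These defaults match common small-RNA trimming
practice. Reads with no detectable adapter are kept: long inserts (tRNA,
snRNA, ...) legitimately fill the whole read so absence of adapter is not
evidence of a bad read.

After trimming, reads shorter than 16 nt are discarded — 16 nt is retained,
15 nt is not. Usable reads are collapsed into non-redundant *tags*
(sequence, copy number) per sample; collapsing is lossless for
quantification and the funnel is conserved exactly:
`n_raw = n_usable + n_too_short_discarded` and tag copies sum to
`n_usable`. Base qualities are ignored after trimming; quantification uses
sequences and copy numbers only. Reads containing `N` are retained; `N`
never matches a genome base during alignment, so each `N` consumes one
mismatch.

### NTA-aware one-mismatch alignment

`align_tags()` aligns each tag to the genome full length, allowing at most
one substitution (no gaps, matching the one-mismatch contract; the read
simulator correspondingly injects substitutions only). Because miRNAs
frequently carry 1–3 non-templated 3' additions (NTAs: bases added
enzymatically after transcription that are absent from the genome), the
aligner retries with k = 0..3 3'-terminal bases trimmed, requiring the
remaining aligned length to stay ≥ 16 nt. All hits of the best tier are
reported, where the tier minimizes the substitution count first and the trim
length k second. The ordering matters: a read with one NTA aligns both
untrimmed-with-one-mismatch and trimmed-with-zero — preferring fewer
mismatches recognizes the NTA, which is the point of NTA-aware
quantification; preferring the smaller trim would silently absorb every
1-NTA read as a mismatch.

The implementation indexes genome 8-mers and uses the pigeonhole principle
(with ≤ 1 mismatch, one half of the tag is exact, so an exact 8-mer seed
from each end enumerates every candidate placement), then verifies
candidates base by base. The test suite compares its hit sets — positions,
strands, mismatch counts, NTA lengths — against an exhaustive
every-position scan on genomes up to 50 kb.

### Annotation, category priority and isomiRs

A hit is matched to same-strand features whose interval covers at least
`overlap_fraction` (default 0.8) of the aligned span. When a tag's
candidates span several categories, only the highest-priority category
survives: miRNA > tRNA > snoRNA > snRNA > yRNA > 7SK > 7SL. Published
category totals are only reproducible if this precedence is fixed; the order
puts the shortest, most easily shadowed species first. Within the surviving
category the tag's unit weight is split equally over the distinct features
(equal splitting is deterministic and count-conserving; random assignment or
discarding would be neither). Mapped tags with no surviving feature are
counted as *unannotated*, so that per sample, category totals plus
unannotated equal mapped copies exactly.

The 5' offset of an assignment is strand-aware: on plus-strand features it
is `hit_start − feature_start`, on minus-strand features it is measured from
the feature's biological 5' end (`feature_end − hit_end`). miRNA reads at
offsets +1/+2 are isomiR calls (classes `isomiR_plus1` / `isomiR_plus2`);
offset 0 is canonical; other offsets keep counting toward the locus but take
class `not_applicable` (the rule names only +1 and +2; discarding other
offsets is available via the assignment audit if a stricter reading is
wanted). In count matrices the +1/+2 classes form a separate `isomiR`
species (rows `locus:+1`, `locus:+2`) so that miRNA and isomiR act as
distinct species in detection curves and differential summaries, as in the
eight-species reporting convention.

Internally all coordinates are 1-based inclusive (the R and GFF3
convention); GFF3 input/output therefore needs no conversion.

## 2. tRNA analysis

tRNA counts are aggregated into anticodon families (amino acid + anticodon,
e.g. `Val_CAC`) and expressed as per-sample fractions of all tRNA counts;
fractions are the natural scale because total tRNA content varies between
libraries. Positional coverage adds each read's `copies × weight` to feature
positions `offset .. offset + aligned_length` (clipped), pools loci within a
family over 100 percentile-of-length bins so families of different lengths
(73–94 nt) are comparable, and summarizes 5'-half enrichment as the fraction
of unbinned depth in the first half of the feature. The family-level
subtype test runs on fractions with a Wilcoxon rank-sum test (one subtype
vs the rest, BH-adjusted); a rank test is robust to the compositional,
non-Gaussian nature of fractions. Mitochondrial tRNA loci need no special
casing — they are ordinary records distinguished only by chromosome name.

## 3. Differential expression by rank aggregation

Counts are normalized to CPM; tests run on `log2(CPM + 1)` (pseudocount 1
is zero-safe and standard). For each feature and comparison, three criteria
are computed: a two-sided Wilcoxon rank-sum p-value, a two-sided Welch
t-test p-value, and the log2 fold change of group mean CPM (+1). Features
are ranked by each criterion and the aggregate rank is the sum — a
rank-aggregation design that combines evidence from several statistics
instead of trusting one model; additional per-feature p-value columns (for
example from external count-model tests) can be plugged in and each adds a
rank. FDR is Benjamini–Hochberg over the rank-sum p-values, and a feature is
*significant* when `fdr < alpha` (default 0.05) and `|log2FC| ≥ lfc_min`
(default 1). The thresholds are defaults, not claims; both are arguments.

Subtype-exclusive features come from the four one-vs-rest comparisons: a
feature is exclusive to S when significant in "S vs others" and in no other
subtype's one-vs-rest comparison, which makes the sets pairwise disjoint by
construction. One property of this definition is worth knowing: a very
strong marker of subtype S also perturbs every *other* subtype's
one-vs-rest contrast (S sits inside "the rest" with, say, 7 of 19 samples),
producing an opposite-sign fold change of about
`log2((n_rest − n_S + n_S·F)/n_rest)` for an F-fold marker. Beyond roughly
4-fold this cross-contrast clears the default `|log2FC| ≥ 1` gate and the
marker stops being *exclusive* — the sets empty out even though every
individual test behaves correctly. The recovery tests therefore use 3-fold
spikes, where the subtype's own contrast (log2 3 ≈ 1.58) passes the gate and
the cross-contrast (≈ 0.8) does not.

A related caveat applies to CPM compositionality: spiking a highly abundant
feature changes every other feature's CPM in the spiked samples, which can
shift null features' test statistics. This is intrinsic to relative
abundance data, not to the test.

## 4. Correlation networks

All sRNA–mRNA associations use Spearman correlation (rank-based, robust to
outliers and to scale differences between the two platforms). rho is the
Pearson correlation of mid-ranks; the two-sided p-value uses the
t-approximation with n − 2 degrees of freedom for n ≥ 10 and a permutation
distribution for n < 10 (full enumeration when `n! ≤ 10000`, i.e. n ≤ 7;
10,000 deterministic sampled permutations otherwise). Matrix-level
correlation ranks `log2(CPM+1)` rows once and computes the full rho matrix
as one cross-correlation; constant rows (for example all-zero counts) are
dropped and audited, and BH q-values are computed over all pairs within each
sRNA category.

The directional-bias profile bins records by |rho| into `[0,0.1), …,
[0.9,1]` (bin width 0.1 is a reporting choice, exposed as an argument) and
reports the positive fraction per bin; records with rho exactly 0 carry no
direction and are excluded from both counts. All nonzero pairs enter the
profile — restricting to significant pairs is a switch, not the default.
Gene-class summaries count, per listed tumor suppressor or oncogene, the
distinct miRNAs passing `|rho| ≥ 0.5` and `q ≤ 0.05` (defaults, exposed),
split by sign. The subtype target table pairs subtype-up miRNAs with
negatively correlated class genes (`decreased_target_of_increased_miRNA`)
and subtype-down miRNAs likewise (`increased_target_of_decreased_miRNA`);
both relations are emitted with full provenance rather than guessing a
single table semantics. Networks export as plain edge-list / node-attribute
TSVs (deterministically ordered by |rho|) for standard network viewers.

## 5. The synthetic-data generator

The generator is first-class, tested code; every downstream recovery test is
computable from its ground truth alone.

* **Reference**: a uniform-random genome (default 2 × 50 kb) with
  non-overlapping features — 30 miRNA (19–25 nt), 20 tRNA (73–94 nt, the
  biological parent-tRNA range), 10 snoRNA, 10 snRNA, 8 yRNA, 4 7SK, 4 7SL.
  tRNA loci draw anticodon families from a 20-family alphabet weighted so
  that Val/Gly/Lys/Glu/His dominate (~95% of sampling weight), mirroring
  the concentration of real cellular tRNA pools. Features sit on the plus
  strand by default, with a mixed-strand switch used by the strand-handling
  tests.
* **Expression**: per-feature log2-normal baselines (mean 6, sd 1.5 on the
  log2 scale), optional per-sample biological noise (sd 0.25 log2 by
  default; 0 in tests that need multinomial sampling as the only noise),
  subtype-restricted fold-change spikes, and multinomial read totals of
  200,000 per sample over a 26-sample, four-subtype design (7 BL1, 5 BL2,
  7 M, 7 LAR).
* **Reads**: insert (miRNA 5' offsets 0/+1/+2 with probabilities
  0.8/0.15/0.05; tRNA 5'-half fragments spanning positions `1..L/2 ± 5`
  with probability 0.8, else the full molecule; other species full length)
  + 0–3 NTA bases (probabilities 0.7/0.2/0.08/0.02) + adapter, truncated to
  50 nt, with per-base substitution errors at rate 0.001. Constant Phred+33
  qualities; no indels (the aligner contract allows one substitution, not
  gaps), no ligation bias, no PCR-duplicate structure, no quality-score
  realism. Passing recovery tests therefore demonstrates correctness of the
  pipeline's logic under its stated error model, not robustness to every
  artifact of real libraries.
* **Paired expression**: a Gaussian copula. For a designated (sRNA, mRNA)
  pair with Spearman target ρ, the latent bivariate normal uses Pearson
  `r = 2·sin(πρ/6)` — the exact inverse of the Spearman–Pearson relation
  for Gaussians — and latents map through a strictly monotone log-normal
  transform, so ranks (and hence Spearman correlation) are controlled
  analytically.

Determinism: every operation derives its RNG stream from the configuration
seed (read construction and error injection use separate per-sample
streams, so the same seed yields identical pre-error reads at any error
rate). Identical configurations produce byte-identical FASTA/GFF3/FASTQ/TSV
outputs and identical run manifests.

## 6. Numerical choices and degenerate inputs

* Wilcoxon tests use R's exact small-sample distribution where available
  and the normal approximation under ties; an all-constant feature gets
  p = 1 and can never be significant.
* Welch t-tests on zero-variance groups fall back to p = 1 (equal means)
  or p = 0 (unequal); fold changes always use the +1 pseudocount.
* Aggregate ranks use the `min` tie convention so they stay integers.
* |rho| bin edges are computed as exact rationals (`k/n_bins`) with an
  epsilon guard so boundary values like 0.6 land in their left-closed bin.
* Spearman p-values at ρ = ±1 are clamped away from the singular t
  statistic; permutation p-values for sampled permutations use the
  add-one estimator.
* Coverage reads whose 5' offset falls outside `[−2, L)` are skipped and
  tallied rather than clipped into the profile.
* Zero tRNA counts give NA half-fractions rather than 0/0.

## 7. Problem sizes used by the test suite

The suite validates properties at desk scale, chosen so the whole run stays
comfortably within a half-hour on one CPU: end-to-end recovery at 2 samples
× 200,000 reads (zero-error), aligner–oracle equivalence on 1,000 tags vs a
50-kb genome, differential calibration at 50 permutation rounds × 500
features (n = 7 vs 7) and power at 50 seeds × 200 features with 20 spiked,
copula recovery at 20 seeds × 26 samples, and pipeline determinism at 8
samples × 10,000 reads. The exclusive-set recovery simulation runs 10 seeds
× 400 features. Statistical operating points (group sizes, depths, rounds)
follow the study conditions; only population sizes are scaled.

## 8. Known limitations

* No gapped alignment, color-space support, novel-miRNA discovery,
  precursor/hairpin modeling, or 3'-end isomiR classes.
* tRNA fragments are not typed into tRF-5/tRF-3/tiRNA nomenclature and no
  cleavage-site inference is attempted.
* The differential module is a rank-aggregation test on CPM, not a
  negative-binomial dispersion model; external model p-values can be
  aggregated but are not computed here.
* Correlation signs are associations; no causal or seed-sequence target
  prediction is implied.
* The Spearman t-approximation is used for all n ≥ 10; in the far tails it
  deviates from the exact distribution by design.
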