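# srnapipe

Small non-coding RNA sequencing (sRNA-seq) captures far more than miRNAs:
tRNA-derived fragments, snoRNAs, snRNAs, yRNAs and the 7SK/7SL RNAs all land
in the same size-selected libraries. srnapipe is an R package for analysing
such libraries end to end, written for computational biologists who want
every stage of the analysis to be testable against known ground truth. It
was built around the study design of triple-negative breast cancer (TNBC)
cell-line panels — samples labelled with the four transcriptional subtypes
BL1, BL2, M and LAR — but every stage takes ordinary matrices and sample
sheets.

The pipeline stages:

1. **Preprocess** — 3' adapter trimming (leftmost match, mismatch-tolerant),
   discarding reads shorter than 16 nt, and collapsing reads into
   non-redundant tags with copy numbers. The count funnel is conserved
   exactly: `n_raw = n_usable + n_too_short`.
2. **Align + annotate** — full-length genome alignment of each tag with at
   most one substitution, retrying with k = 0..3 bases trimmed from the 3'
   end to recognize non-templated additions (NTAs); the reported hit tier
   minimizes mismatches, then the trim. Hits are assigned to seven sRNA
   categories with fixed priority (miRNA > tRNA > snoRNA > snRNA > yRNA >
   7SK > 7SL), reads at +1/+2 of a miRNA 5' end are called isomiRs, and
   copy-weighted count matrices satisfy
   `sum(category totals) + unannotated = mapped copies` exactly.
3. **tRNA analysis** — anticodon-family fractions (e.g. `Val_CAC`),
   percentile-binned positional coverage pooled per family, and the
   5'-half fraction quantifying tRNA-half enrichment.
4. **Differential expression** — rank aggregation over three criteria per
   feature (Wilcoxon rank-sum p, Welch t p, |log2 fold change| on
   log2(CPM+1)), BH FDR, all six pairwise subtype comparisons plus
   one-vs-rest tests, and subtype-exclusive feature sets (significant in
   exactly one one-vs-rest comparison; disjoint by construction).
5. **Correlation networks** — Spearman rho for every sRNA–mRNA pair
   (mid-ranks; t-approximation for n ≥ 10, permutation p below), the
   positive/negative direction-bias profile by |rho| bin, per-gene counts of
   correlated miRNAs for tumor-suppressor/oncogene lists, subtype-resolved
   miRNA–target tables, and edge-list/node-table export for network
   viewers.
6. **Synthetic data** — a ground-truthed generator for all of the above:
   random genome + GFF3 annotations, reads with adapters, sequencing
   errors, 5' isomiR offsets, NTAs and 5'-biased tRNA halves, and paired
   sRNA/mRNA matrices with Gaussian-copula-controlled Spearman structure
   (latent Pearson r = 2·sin(πρ/6)).

Everything is deterministic under a configuration seed; two identically
seeded pipeline runs produce byte-identical output manifests.

## Worked example

A small four-subtype simulation (20 samples × 20,000 reads) with one miRNA
spiked 8-fold in the LAR subtype:

```r
library(srnapipe)

cfg <- srna_sim_config(
  seed = 42, reads_per_sample = 20000,
  features_per_category = c(miRNA = 15, tRNA = 8, snoRNA = 4, snRNA = 4,
                            yRNA = 3, `7SK` = 2, `7SL` = 2),
  design = data.frame(sample_id = sprintf("s%02d", 1:20),
                      subtype = rep(c("BL1", "BL2", "M", "LAR"), each = 5)),
  spike_table = data.frame(feature_id = "miRNA-sim-1", subtype = "LAR",
                           log2_fold_change = 3))
report <- run_pipeline(cfg, "readme_run")
print(report)
#> srna_run_report: readme_run
#>   stages: simulate -> preprocess -> quantify -> trna -> de
#>   checks: preprocess_conservation=TRUE quantify_conservation=TRUE
#>   outputs: 74 files
```

The quantification recovers all eight species (isomiRs are counted as their
own species, split from their parent miRNA loci), with nothing left
unannotated on this clean simulation:

```r
print(report$quant)
#> srna_quant: 8 species matrices over 20 sample(s)
#>   miRNA    15 features, 142758 copies
#>   tRNA     8 features, 63339 copies
#>   snoRNA   4 features, 63597 copies
#>   snRNA    4 features, 38605 copies
#>   yRNA     3 features, 20413 copies
#>   7SK      2 features, 20061 copies
#>   7SL      2 features, 13995 copies
#>   isomiR   30 features, 35630 copies
#>   unannotated copies: 0
```

tRNA reads, simulated with the default 80% 5'-half bias, show the expected
first-half coverage concentration:

```r
report$coverage$pooled_half_fraction
#> [1] 0.9449
```

The one-vs-rest test finds the spiked miRNA — and its +1/+2 isomiR rows —
as the top LAR hits, and the exclusivity analysis assigns them to LAR only:

```r
head(as.data.frame(report$one_vs_rest$LAR)[, c(1, 4, 5, 7, 9)], 3)
#>       feature_id log2_fold_change     p_value         fdr significant
#> 1 miRNA-sim-1:+1         2.672758 0.000128999 0.002923977        TRUE
#> 2 miRNA-sim-1:+2         2.645032 0.000128999 0.002923977        TRUE
#> 3    miRNA-sim-1         2.619635 0.000128999 0.002923977        TRUE

print(report$exclusive)
#> srna_exclusive_sets: BL1=0 BL2=0 M=0 LAR=3
```

The log2 fold changes sit near the simulated value of 3 (slightly
attenuated by CPM renormalization), the Wilcoxon p of 1.29e-4 is the exact
minimum for a 5-vs-15 rank-sum split, and the three LAR-exclusive features
are precisely the spiked locus and its two isomiR classes.

A YAML-driven command-line wrapper for full runs is installed under
`inst/scripts/srna-pipeline.R`:

```sh
Rscript inst/scripts/srna-pipeline.R --config run.yaml --outdir out --seed 7
```

## Documentation

The methods vignette (`vignettes/srnapipe-methods.Rmd`) documents the
models and assumptions, every tunable parameter with its default and
rationale, what the synthetic data does and does not emulate, numerical
edge-case handling, and known limitations.
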