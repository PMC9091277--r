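# selv — locus variability entropy for variant prioritization

Distinguishing pathogenic from neutral single nucleotide variants (SNVs) is
hardest exactly where most annotation-based predictors stop working: in
non-coding DNA (nuclear and mitochondrial) and at splice sites, where the
redundancy of the genetic code does not shape the selective landscape. This
package scores variants by **SELV**, the Shannon Entropy of Locus
Variability: a position that tolerates variation accumulates many alleles at
appreciable frequencies in population resources such as gnomAD or helixMTdb,
while a position under strong purifying selection shows little or none.
**Low SELV is the pathogenicity signal.**

For a genomic position at which the population resource reports `n` variant
alleles with frequencies `F_1, ..., F_n`, the score is

    SELV = - Σ_{i=1..n} F_i · log(F_i)

with the usual entropy conventions (`0·log 0 = 0`, `1·log 1 = 0`; natural
log by default, base configurable). Frequencies are used exactly as
reported — no renormalization, no reference-allele term — and a position
with no reported variants scores 0, the minimum: a variant observed at a
completely invariant locus is maximally suspicious.

The package is aimed at analysts building variant-prioritization pipelines:

* **Scoring** — read a frequency resource (gnomAD-style VCF via an INFO key,
  or tab-separated exports), pool it into per-locus frequency vectors, score
  query variant tables, optionally stratified by ancestry
  (`read_frequency_vcf`, `read_frequency_tsv`, `build_locus_table`,
  `score_variants`, `stratified_selv`).
* **Benchmarking** — ROC and precision-recall curves with explicit score
  orientation, paired DeLong tests of correlated AUCs against competitor
  scores supplied as numeric columns (ada-score, rf-score, CDTS, HmtVar,
  phastCons, phyloP, ...), two-sample Kolmogorov–Smirnov and Fisher's exact
  tests (`benchmark_report`, `roc_curve`, `pr_curve`, `compare_auc`,
  `ks_two_sample`, `fisher_2x2`).
* **Calibration and classification** — Youden-index cut-offs per genomic
  context (splice-site, nuclear non-coding, mitochondrial non-coding), with
  serializable calibrations and reclassification of variants of uncertain
  significance (`youden_threshold`, `classify_variants`, `evaluate_at_threshold`).
* **Synthetic cohorts** — a generator that emulates a population frequency
  resource and labeled cohorts in which pathogenic variants are placed
  preferentially at low-variability loci, with analytic ground truth
  (`cohort_config`, `generate_frequency_resource`, `generate_labeled_cohort`,
  `expected_placement_auc`).

SELV is only meaningful where locus variability tracks selective pressure;
the package scores protein-coding variants too, but makes no performance
claim there (the genetic code's redundancy distorts the signal).

## Worked example

```r
library(selv)

# a tiny mitochondrial frequency resource (normally read from a VCF or TSV)
freq <- data.frame(
  contig    = "chrM",
  position  = c(152L, 152L, 263L, 750L),
  ref       = c("T", "T", "A", "A"),
  alt       = c("C", "G", "G", "G"),
  frequency = c(0.21, 0.02, 0.55, 0.83)
)
table <- build_locus_table(freq, build = "rCRS")

# three variants of uncertain significance to score
vus <- data.frame(
  contig   = "chrM",
  position = c(152L, 263L, 5024L),
  ref      = c("T", "A", "C"),
  alt      = c("A", "C", "T"),
  context  = "mito_noncoding"
)
scored <- score_variants(vus, table)
scored
#>   contig position ref alt        context      selv n_variants
#> 1   chrM      152   T   A mito_noncoding 0.4059765          2
#> 2   chrM      263   A   C mito_noncoding 0.3288104          1
#> 3   chrM     5024   C   T mito_noncoding 0.0000000          0
```

Position 152 carries two reported alleles (frequencies 0.21 and 0.02), so
its entropy is the highest — a variable, tolerant locus. Position 5024 has
no reported variability at all (`n_variants = 0`), the most suspicious
situation. A cut-off is calibrated on labeled variants of the same genomic
context (here a toy training set of 4 pathogenic / 4 neutral SELV values)
and then applied:

```r
train <- data.frame(
  selv  = c(0, 0, 0.004, 0.011, 0.18, 0.33, 0.41, 0.02),
  label = c(1, 1, 1,     0,     0,    0,    0,    1)
)
cal <- youden_threshold(train$selv, train$label, "lower_is_pathogenic",
                        context = "mito_noncoding")
cal
#> <selv_calibration> context 'mito_noncoding': threshold 0.1 (lower_is_pathogenic)
#>   J = 0.7500 (sensitivity 1.0000, specificity 0.7500; resubstitution, 4/4)

classified <- classify_variants(scored, cal)
classified[, c("position", "selv", "predicted_class")]
#>   position      selv predicted_class
#> 1      152 0.4059765         neutral
#> 2      263 0.3288104         neutral
#> 3     5024 0.0000000      pathogenic
```

Variants scoring at or below the threshold — including every novel-position
variant with SELV 0 — are called pathogenic. `write_scored_table()` and
`annotate_vcf()` export the results; `benchmark_report()` compares SELV to
competitor score columns on labeled cohorts.

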