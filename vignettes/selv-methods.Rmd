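---
title: "Locus variability entropy: model, calibration and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus variability entropy: model, calibration and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selv)
```

## The score and its assumptions

Purifying selection leaves a footprint in population sequencing resources:
positions whose disruption is harmful accumulate few variant alleles, and
those at low frequencies, while tolerant positions accumulate many. SELV
summarizes this footprint for a single genomic position as the Shannon
entropy of the allele frequencies reported there,

$$\mathrm{SELV} = -\sum_{i=1}^{n} F_i \log F_i ,$$

where $F_1,\dots,F_n$ are the frequencies of the $n$ variant alleles that
the resource reports at the position. Low SELV — little observed
variability — is the pathogenicity signal.

The score is deliberately not a probability distribution's entropy: the
$F_i$ are used exactly as reported, they need not sum to one, and the
reference allele contributes no term. This keeps the statistic a direct
function of what the resource asserts, rather than of a reconstructed
genotype distribution. The consequences are worth stating explicitly:

* **Non-negativity.** Every term $-F\log F$ is $\ge 0$ on $[0,1]$ with the
  conventions $0\log 0 = 0$ and $1\log 1 = 0$, so SELV $\ge 0$ always, with
  equality exactly when the locus has no reported allele with
  $0 < F < 1$.
* **Monotonicity.** Adding any allele with $0 < F < 1$ strictly increases
  the score; $n$ alleles at $1/n$ give $\log n$, the familiar maximum.
* **Empty locus.** A position absent from the resource scores 0. This is
  the natural limit of the empty sum, and it encodes the score's core
  claim: a variant at a position where a population of hundreds of
  thousands shows *no* standing variation is maximally suspicious. For the
  same reason a query variant is never added to its own locus vector — the
  score describes the locus as recorded, and a novel query must not be able
  to inflate it.

The signal is expected to be informative only where locus variability
tracks selective pressure directly: splice-site dinucleotides and
non-coding nuclear and mitochondrial DNA. In protein-coding sequence the
redundancy of the genetic code lets synonymous and deleterious alleles
coexist at one position, diluting the relationship; the package scores such
variants but the documentation makes no performance claim for them.

## Parameters that matter

* **Log base** (`base`, default $e$). The formula is stated with an
  unqualified logarithm; the package defaults to natural log and exposes
  the base. The choice rescales all scores by the constant $1/\log b$, so
  rankings, ROC/PR curves and threshold-based decisions are unaffected —
  only raw reported values and thresholds change units. Thresholds are
  therefore meaningful only together with the base used to compute them.
* **AF key** (`af_key`, default `"AF"`). Which INFO field of a frequency
  VCF holds the frequency (overall AF, a popmax value, a per-ancestry
  field) is a caller decision; resources differ and the package does not
  guess.
* **Build tags.** Genome builds are opaque labels attached to tables and
  variant sets; a mismatch is a refusal, never a conversion. Mitochondrial
  contig aliases (`chrM`/`MT`/`chrMT`/`M`) are canonicalized because the
  same position is routinely written all three ways.
* **Orientation.** Every curve, test and calibration takes an explicit
  `higher_is_pathogenic` / `lower_is_pathogenic` declaration (SELV is
  `lower_is_pathogenic`; competitor scores default to higher-is-worse).
  Auto-detecting the direction from the data would silently mask sign bugs,
  so it is never done.

## Frequency-vector construction

`build_locus_table()` pools all alternate alleles at one (contig, position,
ancestry stratum) into one vector. The policy decisions:

* Multi-allelic VCF lines are split into one record per alternate allele on
  reading; pooling is by *position*, not by allele.
* Only SNVs enter vectors; indels and MNVs are rejected with a count,
  matching the score's exclusive focus on single-nucleotide variation.
* Frequency 0 rows are accepted on input (exports often contain them) but
  dropped, with a count, before vector construction: they contribute no
  entropy term and "reported at frequency 0" is not a reported variant.
* A duplicated (contig, position, ref, alt, stratum) record is a hard
  error. Silent deduplication or averaging would corrupt vectors in a way
  that is invisible downstream; resources must be deduplicated upstream.
* Ancestry strata are kept separate end-to-end; `stratified_selv()` scores
  each stratum from its own records only, with the combined stratum always
  reported alongside, since a score driven by one ancestry's sampling depth
  is a known failure mode of population-frequency methods.

## Benchmarking choices

`roc_curve()` enumerates one operating point per distinct score value, so
tied scores move together; the trapezoidal area then equals the
Mann–Whitney pair-ordering probability with ties counted ½, which is the
quantity tested for by the DeLong machinery. `pr_curve()` uses step-wise
(average-precision) interpolation; linear interpolation in PR space is
known to over-estimate the area, and the choice is recorded in the result
metadata. `compare_auc()` implements the paired DeLong construction —
per-observation placement values, covariance of the paired AUC estimates,
$D = (\hat A_1 - \hat A_2)/\sqrt{\widehat{\mathrm{var}}}$ against a
standard normal — because the competitor scores are measured on the same
variants and their correlation must enter the variance. Variants missing a
competitor score are dropped from that comparison only, and the dropped
count is always reported; SELV is re-evaluated on the same
pairwise-complete subset so the comparison is like-for-like. The
Kolmogorov–Smirnov p-value is the asymptotic approximation, appropriate for
the cohort sizes this tool targets; exact small-sample p-values are out of
scope. Fisher's exact test is the conditional (hypergeometric) two-sided
test with the conditional-MLE odds ratio.

## Calibration and classification

`youden_threshold()` maximizes $J = \text{sensitivity} +
\text{specificity} - 1$ over the midpoints between consecutive distinct
scores plus $\pm\infty$ sentinels — the standard ROC-consistent candidate
grid, which can represent every achievable confusion matrix. Decisions use
the *inclusive* rule (pathogenic iff score $\le$ threshold under
`lower_is_pathogenic`): with a strict rule, SELV = 0 variants — novel
positions, the strongest signal the score produces — would flip to neutral
at threshold 0. Ties on $J$ break toward higher sensitivity (in a
prioritization setting a missed pathogenic variant costs more than a false
alarm), then toward the lower threshold, deterministically. Reported
sensitivity and specificity are resubstitution values on the calibration
data and are labelled as such; calibrations serialize to JSON with their
context, orientation, metrics and a checksum of the calibration set so a
classification run can be audited.

## What the synthetic generator emulates — and what it does not

The generator builds a frequency resource locus by locus: an
alternate-allele count drawn from a configurable distribution over 0–3
(default mass 0.15/0.55/0.22/0.08, reflecting that most positions carry no
or one reported variant), and per-allele frequencies from a heavy-tailed
Beta(0.25, 8) on (0, 1] by default, mimicking the rare-allele-dominated
shape of population AF spectra. Frequencies are rounded to 6 decimals
(floor $10^{-6}$), matching the printed precision of public resources and
making text round-trips exact. Labeled cohorts then place pathogenic
variants at loci sampled with probability $\propto \exp(-\beta \cdot
\mathrm{SELV})$ of the *true* locus score (default $\beta = 4$; $\beta = 0$
is the no-signal control) and neutral variants uniformly. Because the bias
acts on locus SELV rather than on scores directly, a recovered AUC
validates the entire pipeline — file writing and parsing, vector pooling,
scoring, curve construction — not just the entropy arithmetic.

Two design details have visible consequences. First, each locus can host at
most three distinct alternate alleles, so cohort sampling is
with-replacement subject to that capacity; a locus drawn a fourth time is
redrawn, which perturbs the nominal placement distribution only when a
locus is hit more than three times (negligible at the default densities)
and is the reason `expected_placement_auc()` — the exact pair-ordering
probability $P(S_{\text{path}} < S_{\text{neut}}) + \tfrac12 P(=)$ implied
by the placement weights — is an expectation the empirical AUC matches to
Monte-Carlo accuracy rather than an identity. Second, ancestry strata are
binomial subsamples of the combined frequencies at a configurable depth,
which reproduces the main real-world effect (rare alleles drop out of small
strata) but none of the demography.

The generator does **not** simulate mutation-rate heterogeneity,
nucleotide-context (5/7-mer) effects, linkage, or the ascertainment quirks
of real resources. Passing tests on synthetic cohorts therefore demonstrate
that the machinery is correct and that the score recovers a
variability-mediated signal when one exists; they are not evidence about
the strength of that signal in real gnomAD or helixMTdb data.

## Numerical and degenerate-input policy

Frequencies outside $[0,1]$ are domain errors naming the offending value;
table rows failing validation are counted per reason, and
`records_in = kept + rejected` always holds. An all-tied score vector
yields AUC ½ and PR-AUC equal to prevalence (the constant-precision limit).
`compare_auc()` with identical or strictly monotone-related scores returns
exactly $D = 0$, $p = 1$ (their placement values coincide termwise); a zero
variance with *unequal* AUCs is refused as degenerate rather than reported
as $\pm\infty$. The test-oracle tolerances are $10^{-12}$ for entropy, AUC
and Youden against brute-force enumeration and $10^{-10}$ for Fisher
against fixed-margin enumeration; the DeLong variance is checked against a
2,000-replicate stratified paired bootstrap within 15%.

Problem sizes in the shipped validation are chosen to keep the full suite
under a minute of compute while leaving no code path untested: entropy and
curve oracles run on hundreds of random instances of up to a few hundred
observations; the end-to-end recovery study uses a 4,000-locus two-point
resource and a 2,000 + 2,000 cohort, large enough that the empirical AUC's
Monte-Carlo error (< 0.01) sits well inside the ±0.02 acceptance band
around its analytic expectation.

## Known limitations

* SELV inherits every bias of the underlying resource: sampling depth,
  ancestry composition, and calling pipeline all shape "reported
  variability". Scores from different resources, builds or AF fields are
  not comparable, which is why builds are refused rather than converted.
* A position can score 0 either because it is genuinely invariant or
  because the resource has no coverage there; the package cannot tell these
  apart and `n_variants = 0` should be inspected when it matters.
* Thresholds calibrated on one resource/context do not transfer to another;
  the serialized calibration records its provenance for exactly this
  reason.
* Reported sensitivity/specificity are resubstitution values; no
  cross-validation is built in.
* Protein-coding variants are scored but the score's premise is weakened
  there by the genetic code's redundancy; treat such scores as exploratory.
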