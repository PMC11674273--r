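---
title: "Methods behind rthclat: the RT h-CLAT decision rule and its supporting pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind rthclat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rthclat)
```

# The assay and its model

RT h-CLAT is a rapid in vitro skin-sensitization assay: THP-1 cells (a
human monocytic line used as a dendritic-cell surrogate) are exposed to a
test chemical for five hours, and the induction of two stress-response
marker genes — *HMOX1* (Keap1/Nrf2-driven oxidative-stress response) and
*JUN* (AP-1 component) — is measured by real-time PCR relative to a
solvent-control culture. The package implements the quantification, the
decision rule, and everything needed to validate them.

## Comparative Cq quantification

Expression is quantified by the comparative Cq (ΔΔCq) method. For a target
gene \(g\) in sample \(s\), with *GAPDH* as the reference gene,

\[
\Delta Cq_{g,s} = Cq_{g,s} - Cq_{\mathrm{GAPDH},s}, \qquad
\mathrm{FC}_g = 2^{-(\Delta Cq_{g,\mathrm{treated}} -
                     \Delta Cq_{g,\mathrm{control}})} .
\]

One PCR cycle corresponds to one doubling of template, so additive error on
the cycle scale is multiplicative (log2-normal) on the ratio scale. The
assay runs in triplicate; `foldchange_from_cq()` produces one fold change
per replicate.

The published protocol does not state whether the control ΔCq is paired
replicate-by-replicate or averaged before the ΔΔCq contrast. Both
conventions are common; `foldchange_from_cq()` defaults to replicate-wise
pairing (`control = "paired"`) and exposes `control = "mean"` as an
option. With paired controls, four independent Cq measurement errors enter
each fold change, so a per-well noise of \(\sigma\) cycles yields a log2
fold-change error with standard deviation \(2\sigma\); the tests use this
propagation to bound recovery error.

## The decision rule

A gene is *positive* for a chemical when at least `quorum` of the
`n_replicates` fold changes reach the `threshold`; a chemical is called a
**sensitizer** when any gene of the panel is positive. The defaults are
the validated rule: threshold 2.0 (linear scale), quorum 2 of 3, panel
*HMOX1* or *JUN*.

Two boundary conventions deserve comment:

* **Inclusive threshold.** The rule counts a replicate exactly at 2.0 as
  positive (`inclusive = TRUE`). The bundled 28-chemical panel forces this
  reading: saccharin's *HMOX1* triplicate (2.0, 1.1, 2.2) is reported as a
  sensitizer call, which requires the boundary replicate to count. A
  strict comparison is available via `inclusive = FALSE` for sensitivity
  analysis.
* **Only increases count.** The rule is phrased in terms of induction;
  down-regulated fold changes (< 1) never contribute to positivity, no
  matter how extreme.

Fold changes are compared at the precision supplied by the user; the
package never re-rounds values, so tables transcribed at one decimal are
evaluated at one decimal.

# RNA-Seq marker discovery

The marker panel was originally found by RNA-Seq on nine reference
chemicals (six sensitizers, three non-sensitizers, plus solvent and
medium controls — eleven treatment conditions, three samples each). The
package reproduces that cascade on any count matrix:

1. **Low-count filter** (`filter_low_counts()`): a gene is kept when its
   per-segment statistic reaches `min_count = 10` in at least one of the
   treatment segments. The source descriptions of this filter disagree at
   the boundary ("fewer than 10 in all segments" versus "more than 10 in
   any"), so both the segment statistic (`mean`, default, or `sum`) and
   the boundary (`inclusive`, default, or `exclusive`) are configurable.
2. **TPM** (`compute_tpm()`): within-sample length-normalized abundance,
   \( \mathrm{TPM}_g = 10^6 \, (c_g/\ell_g) / \sum_h (c_h/\ell_h) \);
   every column sums to \(10^6\) by construction.
3. **Differential test** (`differential_test()`): see below.
4. **Sensitizer-specific selection** (`select_sensitizer_specific()`): a
   gene qualifies when it passes \(|\log_2 \mathrm{FC}| > 1\) and BH-adjusted
   \(p < 0.05\) in the sensitizer-vs-control contrast *and fails* that
   compound cutoff in the non-sensitizer-vs-control contrast. Genes
   significant in both contrasts respond to chemical exposure generally,
   not to sensitization, and are excluded. The sensitizer-vs-non-sensitizer
   contrast is computable with the same function but is deliberately not
   part of the selection predicate, since the selection is defined by
   sensitizer-specificity relative to control.
5. **Ranking** (`rank_candidates()`): among candidates with mean TPM of at
   least `min_tpm = 10` over the sensitizer-treated samples, the `n_up = 10`
   largest up-regulated log2 fold changes and the `n_down = 2` most negative
   down-regulated ones are kept; ties break toward higher mean TPM, then
   lexicographic gene id. The TPM floor has no published numeric value;
   10 TPM is this package's default for "robustly expressed", chosen once
   as a configuration value, not a claim about the original analysis.

Treatments are pooled by group label (all sensitizer treatments against
all controls) because the selection is defined at the group level;
per-chemical contrasts are available by passing a treatment id to
`differential_test()`.

## The simplified negative-binomial test

The differential test is written to be fully self-contained and
desk-checkable rather than to reproduce any particular package
numerically:

* **Normalization** — median-of-ratios size factors (the reference is the
  per-gene geometric mean across samples; genes containing zeros are
  excluded from the reference, with a total-count fallback for degenerate
  fixtures).
* **Dispersion** — per-gene method of moments on normalized counts,
  pooled within groups: \(\hat\alpha = (v - \bar m \overline{1/s}) / \bar
  m^2\), floored at \(10^{-4}\). No empirical-Bayes shrinkage toward a
  mean–dispersion trend is applied; the floor is the only regularization.
* **Wald statistic** — the log ratio of group means of normalized counts,
  with the delta-method variance \(\widehat{\mathrm{Var}}(\log \hat\mu_g)
  = n_g^{-2} \sum_j (\hat\mu_g s_j)^{-1} + \hat\alpha / n_g\) per group. A
  pseudocount of 0.5 on each group mean keeps genes absent from one group
  testable; genes absent from both groups get \(p = 1\) and fold change 0.
* **Reference distribution** — \(t\) with \(n_a + n_b - 2\) degrees of
  freedom rather than the normal. With triplicates the dispersion estimate
  carries only about four degrees of freedom, and a normal reference makes
  the tail p-values anti-conservative enough to leak BH discoveries under
  the null; the \(t\) reference keeps the null simulation clean (no
  discoveries among 5,000 null genes at BH 0.05 in the bundled test) at a
  modest cost in power at n = 3. At the pooled design (18 vs 6 samples,
  22 df) the two references are practically identical.
* **Multiplicity** — Benjamini–Hochberg across all tested genes.

A unit test compares this estimator against DESeq2 on a simulated
fixture: log2 fold-change estimates correlate above 0.95 and the
discovery set of the simplified test sits almost entirely inside DESeq2's
(the simplified test is the more conservative of the two at triplicate
sample sizes, as intended).

# Platform concordance

Before trusting a candidate marker, its qPCR behaviour must agree with the
RNA-Seq signal that nominated it. For each chemical × gene cell the
RNA-Seq fold change (TPM ratio) is compared with each of the three qPCR
replicates; a replicate is *discrepant* when the symmetric ratio
\(\max(a,b)/\min(a,b)\) reaches 2.0 (inclusive), and the cell is a
*mismatch* when at least two of three replicates are discrepant. A gene is
retained only if every reference chemical's cell is a match — the reading
that reproduces the published five-gene retention set
\{*HMOX1*, *JUN*, *PPP1R15A*, *BTG2*, *PMAIP1*\} from the bundled
12-gene × 9-chemical table.

Numerical conventions, each forced by printed boundary verdicts in the
bundled data:

* the comparison is a **ratio**, not an absolute difference (an absolute
  reading cannot reproduce the down-regulated *CCR2*/*ICMT* cells);
* the ratio threshold is **inclusive** (several reported mismatch cells
  sit exactly at 2.0);
* printed values of 0.0 (below one-decimal precision) are handled by
  convention: two zeros are concordant, a zero against a non-zero value is
  discrepant (the limiting ratio is infinite).

At printed one-decimal precision, recomputation reproduces 106 of the 108
verdicts in the bundled table. The two deviating cells
(4-aminobenzoic acid × *SAT1* and glycerol × *ULBP2*) both contain a
replicate sitting exactly on the two-fold boundary, where the authors'
unrounded values could fall on either side; neither affects the retained
gene set, which is insensitive to both cells. No single consistent rule
reproduces all 108 printed verdicts.

# Accuracy accounting

Calls are scored against murine LLNA potency categories binarized as: any
potency class (extreme/strong/moderate/weak) → sensitizer;
non-sensitizer → non-sensitizer; no data (ND) → not evaluable. Every
`accuracy()` report carries its own denominator (`n_evaluable`) because
chemicals without reference data are excluded from it but retained in
`n_total`. `hclat_accuracy()` scores the flow-cytometry h-CLAT judgments
carried verbatim in the metadata (`p`/`n`); no CD86/CD54 computation is
performed or attempted. `marker_sweep()` re-runs the classification over a
grid of thresholds and panels (e.g. 1.5- versus 2.0-fold, single genes
versus the OR panel); lowering the threshold can only add sensitizer
calls, which the tests assert as a monotonicity property.

# What the synthetic data emulate — and what they do not

The generators exist so that every stage is testable without downloads.

* `generate_cq()` plants known true fold changes and adds Gaussian noise
  on the cycle scale (`replicate_noise_sd`, default 0.1 cycles, a typical
  well-to-well repeatability for SYBR assays). A noiseless scenario
  inverts exactly through `foldchange_from_cq()`, which the tests use as a
  round-trip identity.
* `generate_counts()` draws negative-binomial counts for the full
  marker-discovery design (6 + 3 + 2 treatments × 3 replicates): baseline
  means log-normal (median 100 counts), gene lengths log-uniform in
  \([500, 10^5]\) bases so TPM length-normalization is exercised
  non-trivially, dispersions log-normal around 0.05, library-size factors
  uniform within ±30%. Planted sensitizer-specific genes (60 up, 2 down,
  matching the published discovery) are shifted in all sensitizer-treated
  samples with \(|\log_2 \mathrm{FC}|\) uniform in [1.5, 6], straddling
  the reported range up to fold changes above \(2^5\).
* `generate_chemical_panel()` fabricates labelled chemical metadata for
  evaluation tests.

The simulations do **not** model sequencing-level artefacts (GC bias,
batch effects, mapping ambiguity), cytotoxicity, amplification-efficiency
deviations from 2.0, or between-chemical heterogeneity of effect sizes
within the sensitizer group. Passing the recovery tests therefore shows
that the filter cascade and decision rule are implemented correctly and
calibrated under the stated error model — not that the assay generalizes
to chemistries beyond those validated.

# Problem sizes and determinism

All generators are bit-reproducible given a seed, and every stochastic
test fixes one. The test suite uses the default 8,000-gene scenario for
the end-to-end recovery check, 5,000 genes for the null-calibration check,
2,000 genes for the planted-effect power check, 600 genes for the DESeq2
comparison, and 500 simulated chemicals for the Monte-Carlo check that a
true 2.5-fold induction is detected in at least 95% of noisy runs (the
analytic detection probability under the error model above is ≈ 0.99 per
gene). These sizes were chosen to make the binomial/FDR bounds sharp
enough to detect calibration defects while keeping the suite quick to run.

# Known limitations

* The method is a binary classifier; it does not grade potency and the
  package deliberately offers no potency prediction.
* The bundled validation tables are transcriptions at the printed
  one-decimal precision; boundary cells inherit that rounding (see the
  concordance section).
* The headline accuracy of the assay on the full 43-chemical study cannot
  be recomputed from the bundled data alone, because the fold changes for
  nine of the chemicals and the exact composition of the 43 were not
  published in the main tables; the package reports accuracy with explicit
  denominators on the enumerable 28-chemical panel instead.
* No amplification-efficiency (Pfaffl-type) correction and no
  melting-curve QC are implemented; inputs are assumed to be valid Cq
  values from specific amplification.
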