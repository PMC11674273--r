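# rthclat

Rapid qPCR-based classification of skin sensitizers with THP-1 cells.

Chemicals in cosmetics and topical drugs must be screened for their
potential to cause allergic contact dermatitis. Animal-free alternatives
to the murine local lymph node assay (LLNA) exist — notably the h-CLAT,
which reads CD86/CD54 surface markers on THP-1 cells by flow cytometry —
but they are slow and equipment-heavy. RT h-CLAT replaces the cytometry
readout with a five-hour chemical exposure followed by real-time PCR of
two stress-response marker genes, *HMOX1* and *JUN*. This package
implements the complete computational side of that assay for
toxicologists and assay developers:

* **Comparative Cq quantification** — fold changes from raw quantification
  cycles, normalized to *GAPDH* against a solvent control:
  FC = 2^-ΔΔCq, with replicate-paired or mean-control conventions.
* **The decision rule** — a chemical is called a *sensitizer* if either
  panel gene shows a ≥ 2-fold increase in ≥ 2 of 3 PCR replicates
  (threshold, quorum, panel and boundary behaviour all configurable).
* **Marker discovery from RNA-Seq** — low-count filtering, TPM, a
  self-contained negative-binomial Wald test with median-of-ratios
  normalization and Benjamini–Hochberg adjustment, sensitizer-specific
  gene selection (|log2FC| > 1, adjusted p < 0.05 versus control in the
  sensitizer contrast only), and effect-size/TPM ranking.
* **Cross-platform concordance** — the two-fold replicate-majority rule
  that compares qPCR against RNA-Seq fold changes and reduced twelve
  candidate markers to the retained five (*HMOX1*, *JUN*, *PPP1R15A*,
  *BTG2*, *PMAIP1*).
* **Accuracy accounting** — calls scored against binarized LLNA potency
  categories, h-CLAT comparison, and threshold/panel sweeps.
* **Synthetic data** — seeded generators for Cq tables and
  negative-binomial count matrices with planted effects, so the whole
  pipeline is testable offline.

The bundled validation tables (37 chemicals; a 9-chemical × 12-gene
concordance table and a 28-chemical × 2-gene evaluation panel) reproduce
the published judgments end to end.

## Worked example

Classify the bundled 28-chemical evaluation panel with the default rule
and score it against the murine LLNA categories:

```r
library(rthclat)

fc   <- hmox1_jun_panel()     # 28 chemicals x {HMOX1, JUN} x 3 replicates
chem <- study_chemicals()     # metadata incl. LLNA category, h-CLAT call
fit  <- rt_hclat(fc, chemicals = chem)
fit
#> RT h-CLAT classification of 28 chemical(s)
#> decision_rule: fc >= 2 in >= 2 of 3 replicates; panel: HMOX1 or JUN
#> calls: 22 sensitizer, 6 non-sensitizer
#> agreement with LLNA: 23/27 evaluable chemicals

fit$accuracy
#> accuracy: 23/27 evaluable chemicals match (4 mismatch, 1 not evaluable)
#> mismatches: Coumarin, Ethyl benzoylacetate, Potassium dichromate, Saccharin
#>   HMOX1 alone: 21/27
#>   JUN alone: 19/27

head(fit$judgments[, c("chemical", "HMOX1_positive", "JUN_positive",
                       "call", "match")], 5)
#>                      chemical HMOX1_positive JUN_positive           call match
#> 1                   1-Butanol          FALSE        FALSE non_sensitizer match
#> 2   1-Phenyl-1,2-propanedione           TRUE         TRUE     sensitizer match
#> 3             1,2-Propanediol          FALSE        FALSE non_sensitizer match
#> 4               2-Aminophenol           TRUE         TRUE     sensitizer match
#> 5 3-Dimethylamino propylamine           TRUE         TRUE     sensitizer match
```

Reading the output: 22 of the 28 chemicals trip the two-gene OR rule; of
the 27 chemicals with LLNA reference data, 23 are classified consistently
with the in vivo category. One chemical (sodium sulfite) has no LLNA
label and is reported but excluded from the denominator. The per-gene
lines show that the two-gene panel outperforms either marker alone.

The marker-discovery side runs the same way on a count matrix — here on
synthetic data with 62 planted sensitizer-specific genes:

```r
cm  <- generate_counts(rnaseq_scenario(seed = 1))
res <- select_markers(cm)   # filter -> NB test x2 -> selection -> ranking
nrow(res$candidates)        # recovered candidate set
```

A thin command-line front end over the same functions lives in
`inst/scripts/rt-hclat.R` (subcommands: `simulate`, `foldchange`,
`classify`, `concord`, `select-markers`, `evaluate`, `sweep`).

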