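# bandscape

Cytoband-level copy-number loss analysis for tumor cohorts.

Recurrent loss of chromosomal cytoband 13q14.2 — the region harboring the
*RB1* tumor suppressor — is one of the most frequent somatic copy-number
alterations in breast cancer, where it associates with poorer overall
survival and with increased sensitivity of tumor cells to BCL2 inhibitors.
`bandscape` packages the full analysis chain needed to study such a
cytoband-loss event in any cohort with gene-level copy-number calls:

1. **Band calling** — summarize GISTIC-thresholded gene-level calls
   (−2 … +2) to a per-sample cytoband status: `deep_loss`, `loss`,
   `neutral`, `gain`, `amplification`, or `ambiguous` when an intra-band
   breakpoint leaves the band's genes with mixed values.
2. **Association screen** — co-occurrence / mutual exclusivity of the
   band-loss anchor against mutated genes and other copy-number events,
   by Fisher's exact test with `Direction = log2(OR)` and
   `score = −log10(p) · Direction`.
3. **Expression contrast** — per-gene z-scoring, median differences
   between loss and diploid samples, independent-samples rank-sum tests
   with Bonferroni (genes) or Benjamini–Hochberg (proteins) adjustment,
   pathway-input selection that excludes anchor-arm downregulated genes,
   and hypergeometric over-representation over GMT gene sets.
4. **Microenvironment deconvolution** — cell-type fractions under the
   linear mixing model `P_j = SM · β_j + ε`, solved per sample by
   non-negative least squares with simplex renormalization and averaged
   over a 10-signature-matrix ensemble.
5. **Pharmacogenomics** — feature × drug screens on log10 IC50 with
   Glass' Δ (both group denominators), Mann–Whitney tests, per-screen BH
   FDR, point-biserial effect sizes (magnitude boundaries 0.10 / 0.24 /
   0.37), elastic-net ranking, and an anchor-only volcano mode.
6. **Survival** — Kaplan–Meier curves and log-rank tests of loss vs
   diploid patients, overall and per molecular subtype.

A synthetic-cohort generator (`sim_config()` / `simulate_cohort()`)
reproduces the statistical structure every stage assumes — segmental CN
profiles with intra-band breakpoints, planted odds ratios, dosage-coupled
expression, `SM · β + ε` mixtures, planted drug-sensitivity effects, and
proportional-hazards survival — so the whole pipeline is testable with no
external downloads.

## Worked example

```r
library(bandscape)

cfg <- sim_config(seed = 7, n_samples = 800)
sim <- simulate_cohort(cfg)
bundle <- exclude_pathogenic_carriers(sim$bundle, "RB1")

st <- band_status_table(bundle$cn, bundle$annotation)
head(band_loss_frequencies(st), 3)
#>   band_name chrom    start n_callable n_loss frequency rank
#> 1   13q14.2    13  6000000        795    375 0.4716981    1
#> 2   13q15.2    13  8000000        795    286 0.3597484    2
#> 3   13q16.2    13 10000000        795    223 0.2805031    3

anchor <- binary_anchor(st["13q14.2", ])
screen <- screen_features(anchor, sim$features)
screen[1:2, c("feature_id", "odds_ratio", "p_value", "score", "call")]
#>   feature_id odds_ratio      p_value     score               call
#> 1     PIK3CA  0.2502228 1.626883e-17 -33.55571 mutually_exclusive
#> 2       TP53  3.8980325 1.169424e-16  31.27053       co_occurring

sv <- survival_by_group(bundle$clinical, st["13q14.2", ], "all")
sv$results$all
#> log-rank: loss 375 vs neutral 397 ; chi2 = 57.661, p = 3.11e-14
```

The anchor band tops the loss ranking at the planted 47.2% frequency
(44% heterozygous + deep losses, plus linkage from the segmental
process); the screen recovers the planted odds ratios (4 and 0.25) with
the right calls; and patients with the loss show the planted survival
disadvantage.

The same analyses are scriptable through the CLI
(`inst/cli/bandscape`): `simulate`, `call-bands`, `associate`,
`diffexp`, `deconvolve`, `pharmaco`, `survival`, `report`, or `all`,
with `--out DIR --config FILE.yaml --seed INT`. Every subcommand writes
TSV outputs plus a JSON run manifest, and a fixed seed reproduces every
output byte-identically.

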