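---
title: "Methods: cytoband-loss analysis with bandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytoband-loss analysis with bandscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandscape)
options(bandscape.log_level = "warn")
```

`bandscape` analyzes a single recurrent cytoband-loss event — the
motivating case is 13q14.2 loss in breast cancer — across five
statistical stages. This vignette documents the models, the conventions
adopted where the analysis design was genuinely open, the generator that
makes everything testable offline, and the known limitations.

## Band calling

Input is a gene × sample matrix of GISTIC-thresholded integer calls:
−2 (deep/homozygous loss), −1 (one-copy loss), 0 (diploid), +1 (gain),
+2 (amplification). Genes are assigned to the cytoband containing their
interval midpoint (all coordinates 0-based half-open internally; gene
tables are declared 1-based inclusive at the reader and converted once,
at the boundary). A band's status in a sample is a total function of its
genes' non-missing values: a uniform value maps to the corresponding
label, two or more distinct values imply an intra-band breakpoint and
yield `ambiguous`, and no values yield `missing`.

Conventions the data do not dictate, fixed here once:

* **Binary contrasts** compare `loss ∪ deep_loss` against `neutral`
  only; gains, amplifications and ambiguous samples are excluded (and
  listed). This mirrors a loss-vs-diploid design; homozygous loss is
  rare (about 1–2% of samples) so pooling it with heterozygous loss
  costs little resolution.
* **Denominators** are per-band callable samples: `ambiguous` counts in
  the denominator of a loss frequency but in no numerator. Missing CN
  cells are excluded pairwise per gene.
* **Loss-frequency ties** are broken by genomic order (chromosome, then
  start), so ranks are deterministic.
* The **band-vs-genome contrast** needs a replicate unit; we use the
  gene: each gene contributes its fraction of altered samples, and
  in-band genes are compared with all other genes by a two-sample
  Student t test (equal variances). This is a design convention, not a
  property of the data, and is logged as such.

## Association screen

For the binary anchor (band loss) against each binary feature (mutated
gene, or another band's loss/gain), we form the 2×2 table and report the
two-sided Fisher exact p, the sample odds ratio, `Direction = log2(OR)`
and `score = −log10(p) · Direction`; features are called
`co_occurring` (p < α, Direction > 0) or `mutually_exclusive`
(p < α, Direction < 0). Features at or below 2% prevalence are dropped
before testing. Numerical conventions:

* Zero cells get the Haldane–Anscombe +0.5 on **all** cells for the
  odds ratio only; the exact p always uses the raw counts.
* At p = 1, the score is defined as 0 regardless of the odds ratio,
  avoiding ±0 ambiguity.
* No multiple-testing correction by default (the screen keeps raw
  p < 0.05); a BH mode exists for conservative use.
* Band features on the anchor's own chromosome arm are flagged — their
  association is partly linkage through the segmental structure of
  copy-number alterations — but never removed.

## Expression contrast

Expression is standardized per gene across samples (sample sd,
denominator n − 1); zero-variance genes are dropped with a report. The
per-gene effect is the difference of median z-scores (loss − neutral)
and the p value comes from the independent-samples rank-sum
(Mann–Whitney) test — exact for combined n ≤ 20 without ties,
tie-corrected normal approximation otherwise. Gene mode adjusts by
Bonferroni, protein mode by Benjamini–Hochberg; both at adjusted
p < 0.05. The two groups are independent and of unequal size, which is
why the unpaired rank-sum test is the implemented estimator.

For pathway analysis, genes are ranked by adjusted p (ties by |effect|),
downregulated genes on the anchor's chromosome arm are removed — their
signal is the dosage loss itself, not a downstream program — and the top
50 survivors feed a hypergeometric over-representation test against
user-supplied GMT sets, BH-adjusted across sets.

## Microenvironment deconvolution

The mixing model is linear: for bulk profile $P_j$ of sample $j$,
signature matrix $SM$ (mean expression of gene $i$ in cell type $k$) and
fractions $\beta_j$,

$$P_j = SM \cdot \beta_j + \epsilon.$$

Per sample we solve $\hat\beta_j = \arg\min_{\beta \ge 0}
\lVert P_j - SM\beta \rVert^2$ by non-negative least squares
(`pracma::lsqnonneg`), renormalize to the simplex, and keep the residual
norm as the realized noise term. Sum-to-one is imposed after solving
rather than as a constraint; this matches the fraction semantics while
keeping the solver simple, and makes $\hat\beta$ invariant to positive
scaling of $P_j$. Estimates are averaged element-wise over an ensemble
of signature matrices (default 10) and renormalized; ensemble averaging
demonstrably reduces the error from signature-matrix perturbation.
Heavier machinery (support-vector regression, batch correction) used by
dedicated deconvolution tools is deliberately not reproduced: this
module solves exactly the linear model above. Two preprocessing modes
mirror common cohort handling: `log2_scale` and `scale`.

Degenerate cases: a rank-deficient signature matrix warns with its
condition number (duplicated cell types split their fraction
arbitrarily, sums still valid); a sample whose optimum is all-zero
cannot be normalized and receives uniform fractions plus a flag.

## Pharmacogenomic screen

For each (feature, drug, screen) with at least 3 cell lines per
genotype class: mean difference of log10 IC50, Glass' Δ with **both**
group standard deviations as denominators, Mann–Whitney p,
point-biserial r with a Fisher-z 95% CI and magnitude labels at |r|
boundaries 0.10 / 0.24 / 0.37, and BH q computed per screen (IC50
scales differ between screens; a pooled mode exists). A hit requires
p < 0.001, q < 0.25 and the **smaller** Glass' Δ above 1.4 — the
conservative reading, since only an unqualified "Glass' Δ" cutoff is
conventional. The anchor-only mode applies the same machinery to one
feature across all drugs and screens at q < 0.05, keeping duplicate
drugs as separate per-screen records. Elastic-net ranking
(`glmnet`, mixing 0.5, 10-fold CV at the 1-SE rule) provides a
complementary multivariate candidate list; the univariate Mann–Whitney
p accompanies it rather than a screen-specific ANOVA pipeline.
Xenograft response summaries (e.g. AUC) reuse the identical two-group
machinery without any curve fitting.

## Survival

Kaplan–Meier product-limit curves and the standard log-rank test
(hypergeometric variance at each distinct event time, chi-square with
1 df) are implemented directly from their definitions; the `survival`
package serves as an independent cross-check in the test suite, never
as the implementation. At tied times, events are processed before
censorings (the common convention; nothing in the data decides it).
Stratified comparisons require a configurable floor (default 5) of
patients per class per stratum; under-sized strata are reported
untestable rather than errored. Hazard-ratio point estimates (Cox
models) are intentionally out of scope: the comparison design is KM +
log-rank.

## The synthetic-cohort generator

`sim_config()` fixes the study conditions; its defaults are the
conditions the pipeline targets, not tuning knobs:

* **Cohort**: 1000 samples; genome of 6 chromosomes × 8 bands × 5
  genes (2 Mb bands). The last chromosome is labelled "13" and its
  fourth band "13q14.2" so the anchor exists by construction.
* **Copy number**: a first-order Markov state process over bands (mean
  segment length 3 bands; fresh-segment state probabilities 0.01 / 0.15
  / 0.64 / 0.15 / 0.05 for −2…+2); with probability 0.02 a band of ≥ 2
  genes receives a mid-band switch to a different state at a uniform
  gene index — the breakpoints an `ambiguous` call detects. The anchor
  band's state is drawn marginally: heterozygous loss 0.44, deep loss
  0.01 (loss frequency ≈ 44–45%, homozygous loss rare), diploid
  otherwise.
* **Mutations**: features planted at configured (prevalence, OR)
  against the anchor by solving the implied 2×2 cell probabilities
  (defaults: one co-occurring feature at OR 4 and one mutually
  exclusive at OR 0.25, both at 30% prevalence, echoing the TP53-like
  and PIK3CA-like patterns such screens detect); 20 independent null
  features at 5%; 0.8% of samples carry a pathogenic RB1 mutation so
  the exclusion rule has work to do.
* **Expression**: per-gene baseline N(8, 2) on the log2 scale, dosage
  (cis) effect of 1 log2 unit per CN step, 10 trans genes off the
  anchor chromosome shifted by 1 unit in loss samples, residual sd 1 —
  so the planted trans effect is a 1-sd effect. A one-copy change of
  roughly one log2 unit is the linear-dosage expectation.
* **Mixtures**: 5 cell types × 200 marker genes, symmetric Dirichlet
  fractions (concentration 1), additive Gaussian noise (sd 0.05), a
  10-matrix ensemble perturbed at sd 0.1, and an optional +0.1
  fraction shift of the first cell type in loss samples.
* **Drugs**: 52 cell lines (anchor prevalence 0.44), 300 drugs over two
  screens with 10% assayed in both; 10 planted sensitivity interactions
  shifting log10 IC50 by −2 against residual sd 1, i.e. Glass' Δ = 2.
* **Survival**: exponential event times at baseline hazard 0.01/month
  (median ≈ 69 months), hazard ratio 2 for anchor loss, independent
  exponential censoring calibrated to ≈ 30% censored.

One master seed expands into fixed per-stage child seeds
(`seed %% 65011 × 33013 + offset × 1009`, below 2³¹), so identical
seeds give bit-identical cohorts and each stage is reproducible in
isolation — changing drug parameters never alters the CN matrix.

What the generator does **not** emulate: GC and mappability artifacts,
subclonal and fractional copy numbers, correlated mutation processes
(signatures, hypermutators), expression covariance structure beyond the
planted effects, compositional distortions of real bulk profiles, or
informative censoring. Passing tests therefore demonstrate that the
estimators are correct and calibrated under the stated models — not
that real cohorts satisfy those models.

## Problem sizes used in the checks

The packaged checks run exhaustive enumeration for the band caller
(all gene-value vectors to length 4) and the Fisher p (all 2×2 tables
with n ≤ 40); calibration at 500 replicate cohorts of 200 null features
(n = 400); recovery at 100 seeds for planted odds ratios, mixtures and
expression effects; 50-seed power/null screens for the pharmacogenomic
stage; and 200-seed null calibration for the log-rank test. The
demonstration pipeline in the continuous-integration chain uses a
200-sample cohort. These sizes give the binomial margins the assertions
need while keeping a full run on a single CPU in the minutes range.

## Known limitations

* The band caller treats any two distinct values as `ambiguous`; a
  99-gene band with one discordant gene call is ambiguous even though
  the discordance may be a per-gene artifact rather than a breakpoint.
* The prevalence filter and α of the association screen act on raw p
  values by design; with hundreds of features, some null features will
  be called (the calibration tests quantify exactly how many).
* NNLS deconvolution inherits the linear model's assumptions: additive
  noise, a complete and correct signature matrix, and no
  platform-specific compression of bulk profiles.
* The elastic-net coefficient at the 1-SE penalty is a ranking device,
  not an unbiased effect estimate; shrinkage is expected and tested
  for, not corrected.
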