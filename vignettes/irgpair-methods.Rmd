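---
title: "Gene-pair prognostic signatures: models, parameters and design choices"
author: "irgpair authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irgpair)
```

## The model

`irgpair` builds prognostic signatures from *immune-related gene pairs*
(IRGPs). For a pair of genes $(i, j)$ and a sample $s$, the feature is the
binary within-sample order indicator

$$ r_{ij,s} = \mathbf{1}\{x_{i,s} > x_{j,s}\}, $$

with ties scored 0 (the strict-inequality rule is deliberate: the
published definition specifies only the 1-case, and its complement covers
equality). Because $r_{ij,s}$ depends only on which of two genes is
higher *within* a sample, it is invariant to any strictly monotone
per-sample transformation of expression — normalization, log scaling,
platform-specific gain — which is the core robustness argument for
rank-pair signatures. The package tests this invariance exactly rather
than treating it as a slogan.

A signature is an ordered list of pairs with coefficients
$\alpha_1, \dots, \alpha_K$ and a risk cutoff. The risk score of sample
$s$ is the linear combination

$$ \text{risk}(s) = \sum_k \alpha_k \, r_{k,s}, $$

and samples with score strictly above the cutoff are called high-risk.
The packaged `irgp_signature()` fixture carries the published 17-pair
oral-cancer signature (6 negative, 11 positive coefficients), transcribed
verbatim including its typographic minus signs; `load_signature()`
therefore accepts both the ASCII hyphen-minus and the Unicode minus.

## The pipeline and its thresholds

The canonical analysis (available both as `run_pipeline()` and as the
numbered drivers under `analysis/`) proceeds:

1. **Differential expression.** Library-size normalization to log2
   counts-per-million (`pseudocount` default 1), then a per-gene Welch
   t-test, tumor vs normal. The screen retains $|\log_2 FC| > 1$ and
   $P < 0.05$, both strict, on raw p-values; Benjamini–Hochberg
   adjustment is an opt-in flag (`fdr = TRUE`). The choice of a Welch
   test on log2-CPM — rather than a negative-binomial count model — is a
   deliberate scope decision: the signature machinery downstream consumes
   only within-sample gene orders, so the DE step merely shortlists
   genes, and a transparent test with the same threshold semantics keeps
   the package self-contained. The run log records this choice.
2. **Immune intersection.** DEGs are intersected with an immune gene
   list. A small synthetic subset ships with the package
   (`immune_gene_fixture()`); real analyses should supply the full
   immune-gene repository list as a file.
3. **Pair construction.** All unordered pairs of the immune-DEGs, one
   canonical orientation each (former = earlier in input order; the
   reversed orientation is the complement indicator, hence redundant).
   The *prevalence filter* removes pairs whose indicator is constant in
   more than 80% of samples; a pair constant in exactly 80% is on the
   boundary and kept (closed interval $[0.2, 0.8]$), because removal is
   specified for "more than 80%".
4. **Split and screening.** A seeded 1:1 split (387 samples yield
   194/193; training receives the extra sample). Each candidate pair is
   screened with a univariate Cox model; pairs with Wald $P < 0.01$
   (strict) proceed.
5. **Penalized fit.** An L1-penalized Cox model over the screened pairs,
   with 10-fold cross-validated selection of $\lambda$.
6. **Stratification.** Risk scores for all samples; the cutoff maximizes
   Youden's $J$ on the training set's 1-year ROC curve and is *frozen*
   for the test set; Kaplan–Meier curves, a log-rank test and per-group
   death fractions summarize the separation.
7. **Independence.** Univariate Cox fits per clinical covariate and one
   joint fit including the risk score. The continuous score is the
   default risk term (`use = "group"` switches to the binary group);
   encodings are ordinal (grade I–IV → 1–4, stage I–IV → 1–4, T1–4 →
   1–4, N0–3 → 0–3, male = 1). Missing covariate values are dropped
   per-model and counted, never imputed.
8. **Mutations.** MAF records restricted to the signature's genes and a
   caller-supplied sample list (the pipeline uses its own high-risk
   assignment); summaries follow the waterfall-plot conventions: genes
   ranked by number of mutated samples (ties alphabetical), SNV classes
   collapsed onto the pyrimidine reference frame, multiple hits of one
   gene in one sample counted once for frequency but fully for burden.

## Survival machinery

The survival statistics are implemented in the package rather than
delegated, because they are the analysis's core:

* **Kaplan–Meier** product-limit curves and the standard two-group
  **log-rank** test (a vacuous comparison — no events at all — returns
  $p = 1$ with a warning).
* **Cox proportional hazards** by Newton–Raphson with step-halving on
  the partial likelihood. Efron's tie correction is the default — with
  binary pair indicators, tied event times are the norm rather than the
  exception in day-resolution data — and Breslow is a flag; the two
  coincide exactly on tie-free data, which the tests assert. Convergence
  requires the Newton update to fall below `1e-9` (50 iterations cap).
  Constant covariates are reported with `se = Inf` rather than fit; a
  monotone likelihood (perfect separation) is detected by coefficient
  divergence, capped, flagged non-converged and warned about.
* **L1-penalized Cox** by iteratively reweighted least squares with
  cyclic coordinate descent, warm starts along a geometric
  $\lambda$-grid from $\lambda_{\max}$ (computed from the null-model
  score, so the all-zero solution at $\lambda_{\max}$ is exact by the
  KKT conditions) down to `lambda_min_ratio` (default 0.01) in
  `n_lambda = 100` steps. Covariates are standardized internally (mean
  0, variance 1 with the $1/n$ convention) so the penalty is symmetric;
  coefficients are reported on the original scale. Sequential
  strong-rule screening restricts each coordinate-descent pass to a
  working set, with a full KKT check before a solution is accepted. The
  outer loop stops when the relative change of the penalized objective
  falls below `1e-9`; this is tighter than the `1e-7` one might default
  to because the package asserts that the small-$\lambda$ end of the
  path agrees with the unpenalized Newton fit to about `1e-4`, and the
  diagonal-curvature IRLS converges only linearly near that endpoint.
* **Cross-validation** assigns samples to folds by a seeded permutation
  into near-equal blocks (not event-stratified; a fold with fewer than
  3 events warns, a fold with none is skipped with a warning). The CV
  criterion is the held-out partial-likelihood deviance in the
  Verweij–Van Houwelingen form, $-2(\ell_{\text{all}}(\beta_{-k}) -
  \ell_{\text{train}}(\beta_{-k}))$, which credits each fold with its
  held-out contribution without pretending the partial likelihood
  factors over samples. The default selection rule is the CV minimum
  (`rule = "min"`), consistent with a published selection of 17 pairs
  out of 49 screened — the one-standard-error rule would be more
  conservative — but `rule = "1se"` is available, and the package's own
  null-design experiments use it: on pure-noise designs the CV-minimum
  rule (ours and `glmnet`'s alike, which agree seed-for-seed) admits
  more than 5 spurious pairs in roughly a quarter of runs, while the
  1-SE rule selects none.

The 1-year ROC curve labels samples that died by the horizon as
positives and samples followed beyond it as negatives; samples censored
before the horizon carry no label and are excluded. This simple
exclusion is documented in the output (`n_excluded`); inverse
probability-of-censoring weighting would be the refinement if early
censoring were heavy. The AUC is the Mann–Whitney concordance with ties
counted one half, and the cutoff maximizes Youden's $J$ over midpoints
between consecutive distinct scores (ties toward the smaller threshold;
a degenerate single-score curve returns that score with a warning).

## The synthetic cohort

`simulation_config()` defines the study conditions the package validates
itself under; its defaults are fixed and mirror the target cohort:

* 390 tumor and 32 normal samples; 1,000 genes of which 25% are labeled
  immune.
* Log-normal expression: $\log_2 x \sim N(\mu_g, 1)$ with gene baselines
  $\mu_g \sim U(3, 10)$. 100 planted differential genes with a tumor
  shift of $\pm 2$ on the log2 scale. Expression is generated log-normal
  rather than as negative-binomial counts because everything downstream
  is order-based; a count layer would add realism the pipeline cannot
  see.
* Five planted prognostic pairs with log hazard ratios $\pm 1$. The two
  genes of a planted pair share one baseline mean (so the indicator is
  balanced) and receive one *common* tumor shift (so the planted pairs
  are themselves differential immune genes — as signature pairs are in
  the real analysis — while the within-pair order is provably
  untouched).
* Survival: event times exponential with rate
  $5.5 \times 10^{-4} \cdot e^{\text{lp}}$ per day (median ≈ 3.5 years
  at baseline), censoring exponential with rate $8 \times 10^{-4}$
  truncated at an administrative 5 years. Together these censor roughly
  half the cohort, in the range typical of TCGA-style follow-up. Event
  and censoring laws are the simplest pair satisfying proportional
  hazards with independent censoring.
* Clinical covariates (age, gender, grade, stage, T, N) are drawn from
  simple categorical laws *independent of the hazard* by default, so the
  independence analysis has a negative control; `age_effect` adds a log
  hazard ratio per year of age as a positive control (the recorded
  truth-set linear predictor remains the pair part only, preserving the
  exact identity `lp = sum(beta * indicator)`).
* Mutations: per-sample counts Poisson(1), genes drawn by configurable
  weights, variant classes and a C>T-dominant substitution spectrum from
  categorical laws, written on a random strand so summaries must
  strand-collapse.

What the generator does *not* emulate — real marginal expression
distributions, batch effects, correlated clinical covariates, mutation
signatures beyond a class histogram — bounds what green tests mean:
they demonstrate correctness of the machinery and recoverability of
planted structure under the stated laws, not performance on TCGA data.
The published TCGA-specific numbers (698 DEGs, 1,490 candidate pairs,
AUC 0.774, cutoff 1.016) depend on the actual download and an
unreported split seed, and are deliberately not reproduction targets;
the packaged 17-pair fixture and the printed cohort arithmetic
(387 = 194 + 193) are checked exactly.

## Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` run the recovery experiment at
$n = 500$ samples with 100 candidate pairs over 20 seeded replicates,
calibration checks at 1,000 replicates (log-rank), 1,000 noise pairs
(univariate screen) and $n = 1000$ (null AUC), and the end-to-end
pipeline at the full default cohort (390 tumor / 32 normal, 1,000
genes). These sizes were chosen so the whole suite completes in a few
minutes on one core while leaving the Monte-Carlo bounds comfortably
away from their thresholds.

## Known limitations

* No elastic-net mixing, time-varying covariates, stratified baselines
  or competing risks.
* The 1-year ROC excludes early-censored samples instead of IPCW
  weighting.
* The DE step is a two-group location test; paired designs or batch
  covariates are out of scope.
* Mutation summaries are descriptive; no driver-gene statistics or
  TMB-per-megabase normalization (exome size is not an input).
* CIBERSORT-style immune-cell deconvolution and gene-set enrichment are
  intentionally outside the package.
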