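---
title: "Methods: normalization, moderated contrasts, competitive enrichment and the stability-LASSO malignancy score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, moderated contrasts, competitive enrichment and the stability-LASSO malignancy score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spitzsig)
```

## The problem

Spitzoid melanocytic neoplasms span a spectrum from benign Spitz nevi
(SN) through atypical Spitz tumors (AST) to malignant Spitz tumors
(MST). The AST category is the clinically hard one: histopathology
alone cannot predict whether such a lesion will behave benignly or
malignantly. `spitzsig` implements a complete count-based expression
workflow for three-group cohorts profiled on a targeted panel
(NanoString nCounter-style, 770 genes of which 40 are housekeeping):
normalization, per-gene differential expression between diagnostic
groups, gene-set enrichment, and a weighted gene signature whose
per-sample score places every sample — including the ambiguous AST
group — on a 0–1 malignancy scale with a 0.4 low/high cut.

## Normalization and precision weights

Counts are normalized by **total library size** only (the column
total), the recommended approach when several hundred genes are
measured at once. The log scale is

$$\mathrm{logexp}_{gj} = \log_2\!\frac{(y_{gj} + 0.5)\,10^6}{N_j + 1},$$

with the conventional 0.5/1 offsets. Count data have a strong
mean–variance relationship on this scale, so per-gene linear models
need observation-level **precision weights**. We fit the one-way group
model per gene, lowess-smooth (span 0.5, 3 robustifying iterations)
the square root of the residual standard deviation against the average
log2 count size, and set each observation's weight to the inverse
fourth power of the trend evaluated at its fitted log-count. This is
the standard voom construction; our implementation reproduces the
reference one to numerical precision (asserted in the test suite).
The predicted trend is floored at a small positive value so weights
stay finite for genes with zero residual variance.

## Moderated two-group contrasts

Each contrast (SN vs MST, SN vs AST, AST vs MST) is fit on the two
groups' samples only, by weighted least squares per gene. With tens of
samples and hundreds of genes, per-gene variances are noisy; we shrink
them with an empirical-Bayes scaled inverse-chi-square prior whose
hyperparameters $(s_0^2, d_0)$ are fitted by moment matching on the
log residual variances (digamma/trigamma matching, with a Newton
inversion of the trigamma function). The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields the
moderated t on $d_g + d_0$ degrees of freedom. Setting $d_0 = 0$
recovers the ordinary weighted t exactly — this reduction is one of
the package's oracle tests.

Zero-variance genes are kept (p = 1) rather than dropped, so the
full-panel denominator is preserved. Multiple testing uses our own
Benjamini–Hochberg step-up (`adjust_bh`), verified against exhaustive
enumeration; significance reporting applies **both** thresholds raw
p < 0.05 and BH q ≤ 0.25, because the source analysis states the FDR
rule in its methods but counts significance at p < 0.05 in its
results. Both counts are exposed; `significant_genes()` intersects
them, which is the conservative reading.

## Competitive gene-set enrichment

Per contrast, each gene's moderated t is mapped to an exactly
equivalent standard-normal z. A gene set is tested by a two-sample
comparison of member vs non-member z-scores in which the variance of
the member mean is inflated by $\mathrm{VIF} = 1 + (m-1)\bar\rho$,
where $\bar\rho$ is the mean inter-gene correlation estimated from the
standardized residual space of the member genes. Without the VIF,
co-regulated sets produce wildly anti-conservative p-values; the
correction is the defining feature of the camera method. $\bar\rho$ is
estimated per set by default (a fixed value is a config option) and
floored at $-1/(m-1) + 10^{-3}$ so the VIF stays positive. FDR across
the 50 Hallmark sets reuses `adjust_bh`. Sets with fewer than two
panel members after symbol matching (case-insensitive) are skipped
with a warning.

## The stability-LASSO signature

The discriminative signature for SN vs MST is built by repeated
cross-validated L1-penalized logistic regression with **all** genes as
candidates:

1. Fit the full regularization path by cyclic coordinate descent
   (compiled code; sequential strong-rule screening, warm starts,
   IRLS quadratic approximation for the logistic loss; convergence
   when the largest coefficient change is below $10^{-7}$). The grid
   has 100 log-spaced penalties from $\lambda_{\max}$ down to
   $0.01\,\lambda_{\max}$ — the usual choice when genes outnumber
   samples.
2. Repeat 500 times: draw a fresh stratified 10-fold CV split, pick
   $\lambda^\*$ by minimum held-out binomial deviance (ties towards
   the stronger penalty), and record the full-data coefficients at
   $\lambda^\*$.
3. Genes nonzero in at least 250 of the 500 repetitions form the
   signature; each gene's weight is its coefficient averaged over
   **all** repetitions, zeros included. (Averaging over selecting runs
   only is a documented alternative; the all-runs average is the
   literal reading of the source procedure.)

Folds are stratified by class because the smaller class has only 14
samples and unstratified splits can produce single-class folds; if a
training split is ever single-class the split is redrawn from a
shifted seed. Every repetition's seed derives from the master seed
through one seeded stream, so a single repetition can be re-run in
isolation and the whole procedure is bit-reproducible. Selection
counts treat coefficients below $10^{-8}$ (well under the solver
tolerance) as zero; without this floor, a gene sitting exactly on the
soft-threshold boundary at $\lambda_{\max}$ can "enter" with a
$10^{-16}$ coefficient through floating-point drift.

Note one deliberate reading of reproducibility: with the same seed the
procedure is invariant to gene reordering exactly; reordering
*samples* permutes the CV stream, so results are invariant in
distribution but not bit-identical.

Because the L1 model is multivariate, a signature gene need not be
individually significant in the univariate contrast tables — a gene
can earn its place through its partial association given the other
selected genes. No procedural consequence follows; the scoring uses
the signature as selected.

Convergence of the coordinate descent is verified against closed-form
and reference oracles (soft-threshold solutions on orthonormal
designs, an independent Newton solver at vanishing penalty, and the
reference path implementation along the whole grid) rather than by
per-sweep objective instrumentation in the compiled code.

### Scoring

The per-sample raw score is $\sum_g w_g \cdot \mathrm{logexp}_{gj}$
over signature genes, on the same voom-normalized log2 scale used for
fitting (the source does not name the scoring scale; using the fitted
scale is the consistent choice). Raw scores are min–max transformed to
[0, 1] over the full scored cohort — all three groups jointly, since
the published per-sample "transformed proportions" are reported on one
scale for all groups. A score above 0.4 is called *high*; exactly 0.4
is *low* (the rule is stated as "< 0.4 is low", so the boundary goes
to the low side).

## The synthetic cohort generator

`generate_cohort()` states the simulated world once and is the basis
of every statistical test:

* 27/10/14 samples (SN/AST/MST) over 770 genes, 40 housekeeping;
* library sizes log-normal with natural-log mean $\log 3\times10^5$
  and sd 0.7, so the median total is ≈ 3×10⁵ and the min/max span
  about the 1.9×10⁴–7.9×10⁵ decade-plus range seen on FFPE material;
* gene counts negative-binomial with variance $\mu + \phi\mu^2$,
  $\phi = 0.1$ (a typical biological dispersion for targeted count
  panels; the source reports no per-gene dispersion, so this default
  is chosen, not fitted);
* baseline relative abundances log-normal (sd 1.5 natural-log units),
  normalized to sum to one;
* planted effects: `n_de_genes` genes shifted by `de_logfc` log2 units
  in MST (alternating sign), and `n_signature_genes` genes with
  ordered group means baseline / +step / +2·step across SN/AST/MST
  (alternating sign), so the AST-intermediate property is true by
  construction. Signature genes are swapped into the upper half of the
  abundance draw: a diagnostic marker on a ~zero-count probe is
  undetectable by construction and would make "recovery" meaningless.
  DE genes keep their random abundances — real differential expression
  spans the expressed range, and concentrating many large effects among
  the most abundant genes would materially distort the library
  composition (total-count normalization then shifts every gene's
  log-CPM, the classic compositionality caveat; with DE genes spread
  over the abundance range this shift is ≈ 0.1 log2 at the default 50
  genes x 2 log2 planted effects). Housekeeping genes never carry
  effects.

What the generator does **not** emulate: probe-level chemistry and
spike-in controls, batch effects, inter-gene correlation (genes are
conditionally independent given library size), and compositional
coupling beyond the shared library-size budget. A green recovery test
therefore establishes correctness of the estimation machinery under
the stated stochastic model, not robustness to correlated or batched
real-world data.

## Numerical choices

* Working-response weights in the logistic IRLS are floored at
  $10^{-5}$ and predicted probabilities clamped to
  $[10^{-5}, 1-10^{-5}]$ when computing held-out deviance, the
  convention of the reference implementation.
* $\lambda_{\max}$ is nudged up by a relative $10^{-6}$ so the
  top-of-path solution is exactly zero despite the argmax gene lying
  exactly on the threshold.
* BH ties resolve by the stable sort, making output order-preserving.
* MDS distances use the root-mean-square of the 500 most different
  genes per sample pair (all genes when the panel is smaller); with
  all genes the distance is Euclidean and classical scaling at
  $k = n-1$ reproduces it exactly.
* A pipeline-level manifest stores MD5 hashes of every artifact;
  re-running a config under the same master seed is asserted
  bit-identical.

## Known limitations

* The minimum-deviance rule (not 1-SE) is used for $\lambda^\*$, as
  stated by the source; under a pure-noise cohort this rule has an
  appreciable per-split probability of choosing an interior penalty,
  and stability selection controls — but does not eliminate — the
  resulting false selections. The null-calibration test quantifies
  this on the stated world.
* Three separate two-group fits are used (not a single three-group
  model with contrasts), matching the source's description; the two
  parameterizations give slightly different pooled variances.
* No multi-factor designs, covariates, batch correction, elastic-net
  alternatives, or survival endpoints.
* No raw RCC parsing: inputs are count tables.
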