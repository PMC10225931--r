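---
title: "A neuro-fuzzy advisor for selecting minimally invasive glaucoma surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuro-fuzzy advisor for selecting minimally invasive glaucoma surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migsfis)
```

## The clinical problem

Minimally invasive glaucoma surgery (MIGS) offers four broad implant
choices — iStent combined with endoscopic cyclophotocoagulation ("ICE2"),
the PreserFlo MicroShunt, the XEN-45 gel stent, and the iStent inject —
whose relative suitability depends on the individual patient. `migsfis`
models treatment selection as a supervised mapping from six baseline
measurements (age in years, best-corrected visual acuity in LogMAR,
intraocular pressure in mmHg, Humphrey visual-field mean deviation in dB,
number of daily pressure-lowering drops, and a glaucoma-type code 1–6) to a
treatment-category code 1–4. Cohorts of this kind are small (a few hundred
patients), which motivates a fuzzy-rule system tuned by neural-style
learning rather than a data-hungry deep model.

## The model

The core is a first-order Takagi–Sugeno fuzzy inference system. Rule $c$
has a Gaussian premise per input,
$\mu_{cd}(x_d) = \exp\!\left(-\frac{(x_d - m_{cd})^2}{2\sigma_{cd}^2}\right)$,
a product-t-norm firing strength $w_c(x) = \prod_d \mu_{cd}(x_d)$, and a
linear consequent $f_c(x) = p_c \cdot x + r_c$. The crisp output is the
firing-strength-weighted average
$\hat y(x) = \sum_c w_c f_c(x) \big/ \sum_c w_c$ — the centroid of the rule
outputs — which is then thresholded to the nearest integer class code
(half-up, so 1.5–2.49 becomes class 2) and clamped into 1..4. The product
t-norm and weighted-average defuzzification were chosen over min/Mamdani
alternatives because they are differentiable, which the premise training
below requires.

Rules are extracted by subtractive clustering of the joint
input-plus-output matrix, unit-box scaled so that the single
radius-of-influence parameter (default 0.15) has a uniform meaning across
features. Each data point's potential is
$P_i = \sum_j \exp(-4\lVert x_i - x_j\rVert^2 / r_a^2)$; the highest-potential
point becomes a center, a squashed neighbourhood
($r_b = 1.25\, r_a$) is subtracted, and the accept/reject thresholds (0.5
and 0.15 of the first potential, with the usual distance-plus-potential
tie-break in between) control termination. These three auxiliary knobs are
the classical defaults of the subtractive-clustering literature and are all
exposed in `subclust_params()`. Clustering the joint space, with the class
code scaled like an input, keeps each extracted rule associated with a
single outcome region — one rule per cluster. Premise widths convert the
cluster radius into a Gaussian sigma by
$\sigma_d = r_a\,(\max_d - \min_d)/\sqrt 8$, floored at $10^{-6}$ on
degenerate dimensions.

Training is the classical hybrid scheme. With premises fixed, the output
is linear in all consequent coefficients, so every epoch starts with one
global minimum-norm least-squares solve (an SVD pseudoinverse) — this can
never increase the training SSE. The premise centers and widths then take
one batch gradient step of length $\eta$ along the normalized negative SSE
gradient (the gradients are analytic and are checked against finite
differences in the test suite). The step length starts at 0.01, grows by
×1.1 after four consecutive training-error decreases, and shrinks by ×0.9
after two consecutive up–down oscillations. A validation share — 5% carved
out of the 60% training split, floor-rounded — checkpoints the epoch with
the lowest validation RMSE, which is the model returned. Class codes are
fitted regression-style as the raw numbers 1–4, consistent with the
rounding step; the codes are ordinal only by construction of the output
scale, and the model makes no further ordinality assumption.

Preprocessing divides each predictor by its largest observed absolute
value (mapping the cohort into $[-1, 1]$ per feature, without variance
standardization); treatment codes are never rescaled. The normalizer is
fitted on the full cleaned cohort before the random split and travels
inside the model file so that later predictions reuse the training-time
maxima. Cleaning drops — never imputes — records with non-finite fields or
out-of-code categorical values.

## The regression comparator

The baseline is the pseudoinverse least-squares fit
$TC = a_1\,\mathrm{Age} + a_2\,\mathrm{VA} + a_3\,\mathrm{IOP} +
a_4\,\mathrm{VF} + a_5\,\mathrm{Drops} + a_6\,\mathrm{Type}$
on the raw (unnormalized) predictors, with no intercept — the model is a
pure weighted sum of the six measurements (an optional intercept flag
exists for exploration). Its continuous estimate is thresholded by the
same rounding rule as the fuzzy system, so the two classifiers differ only
in the regression surface.

## The evaluation rubric

Because the task is multiclass, sensitivity-style measures are derived
one-vs-rest from the confusion matrix: for class $k$, TP is the diagonal
cell, FP the rest of its predicted column, FN the rest of its true row,
and TN everything else. Eight ratios are reported per class (TPR, TNR,
PPV, NPV, FPR, FNR, FDR, ACC), with a zero denominator yielding `NaN`
rather than an error — an empty class leaves its rate indeterminate.
Aggregate comparisons use the unweighted mean over classes, skipping `NaN`
entries. Agreement between actual and estimated codes is additionally
summarized by the Pearson correlation with its two-sided $t$-based
p-value. Decision structure can be inspected through the
$\binom{6}{2} = 15$ pairwise surfaces (`decision_surfaces()`), each a grid
over one input pair spanning the observed training range with the other
inputs held at their training means (grid size 50 by default).

## The synthetic cohort generator

The clinical audit data behind this modelling problem is not public, so
`generate_cohort()` emulates its marginal statistics: truncated-normal
draws per feature with means and SDs matching the published cohort summary
(age 77.36 ± 3.82 years, acuity 0.30 ± 0.25 LogMAR, pressure 18.54 ± 4.62
mmHg, field deviation −7.65 ± 7.2 dB, drops 2.12 ± 1.08), upper bounds at
the published absolute maxima, and documented clinically sensible lower
bounds. The ± figures are treated as standard deviations — the source
summary does not say whether they are SDs or intervals, and SD is the
conventional reading of mean ± spread in cohort tables. Glaucoma type is
uniform over the six codes by default; `skewed_gtype_probs()` provides an
open-angle-dominated alternative whose mean matches the published 5.13.

Labels come from a planted, ordered rulebook; the default is
`iop > 23 → PreserFlo; vf < −13 → XEN; va > 0.55 → ICE2; else iStent`.
The threshold form mirrors how surgical choice tends to key on one
dominant clinical driver; the specific cut points were fixed once, by a
marginal-probability calculation, so that every class keeps at least
roughly 10% prevalence at realistic cohort sizes (the simulated
prevalences are about 11/17/21/51%). An optional `label_noise` probability
replaces a planted label with a uniform random class, for studying
degradation.

What the generator deliberately does not emulate: feature correlations
(draws are independent; real age, field loss and drop counts are
correlated), longitudinal follow-up, complication events, and any claim
about the true treatment prevalences of the audited cohort. Passing tests
on this synthetic bed therefore demonstrate that the pipeline recovers a
planted feature-to-treatment structure of realistic marginal scale — not
that it reproduces the clinical performance reported for the real audit.

## Numerical choices and degenerate inputs

* Minimum-norm least squares everywhere (SVD with the standard
  `max(dim) * max(d) * eps` cutoff): rank-deficient designs — duplicated
  predictors, more rule coefficients than samples — get the unique
  smallest-norm solution deterministically.
* Gaussian firing never reaches exact zero analytically, but can
  underflow; evaluation guards the $\sum_c w_c$ denominator, and samples
  whose every firing strength underflows contribute zero premise gradient.
* Subtractive-clustering ties on equal potentials resolve to the lowest
  row index, making center selection permutation-stable up to ties.
* Rounding uses `floor(y + 0.5)`: the half point goes up, fixed by the
  convention that the class-2 band starts at 1.5 inclusive.
* Training is epoch-capped (no convergence tolerance is defined for this
  system); early stopping happens only through the validation checkpoint.
* Sigma floor $10^{-6}$: constant features and aggressive gradient steps
  cannot produce non-positive widths.

## Problem sizes and known limitations

The bundled tests and the acceptance script run cohorts of a few hundred
patients (n = 400 for the end-to-end benchmark, matching the scale of the
audit that motivated the system) with 10 hybrid epochs; training at this
scale takes seconds. At radius 0.15 on six normalized inputs the
clustering is very fine — nearly one rule per training patient, echoing
the "almost 2 samples per cluster" granularity of the original setting —
so the consequent solve effectively interpolates the training data. Two
consequences are worth knowing. First, with zero training error the
premise gradients vanish, so the hybrid epochs refine little at this
radius; the `epochs = 0` model is nearly identical. Second, generalization
then behaves like a narrow-kernel local method: on the synthetic benchmark
the advisor reaches an overall test accuracy of about 0.73–0.81 with mean
per-class accuracy near 0.9, clearly beating the regression comparator but
below what a tree ensemble achieves on the same planted thresholds. Wider
radii trade rule count against smoothness and are worth exploring through
the exposed `radius` argument. The four-class codes are nominal
categories; fitting them as numbers (required by the regression-style
output layer) embeds an artificial between-class ordering, a structural
limitation shared by the comparator.
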