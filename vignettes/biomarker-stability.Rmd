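---
title: "Stability-selected biomarker panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected biomarker panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stabmark` identifies candidate biomarkers in high-dimensional omics tables
with a binary clinical outcome. This vignette explains the statistical
machinery, the tunables and their defaults, what the synthetic benchmark
does and does not emulate, and the numerical and design choices that a
maintainer would want written down.

## The selection model

For samples $i = 1,\dots,n$ with standardized feature vectors
$x_i \in \mathbb{R}^p$ and a binary outcome $y_i \in \{0,1\}$, the package
fits penalized logistic regression:

$$
\min_{\beta_0,\ \beta}\;
-\frac{1}{n}\sum_{i=1}^n \Big[ y_i(\beta_0 + x_i^\top\beta)
  - \log\big(1 + e^{\beta_0 + x_i^\top\beta}\big) \Big]
\;+\; \lambda\Big[\alpha\lVert\beta\rVert_1
  + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big].
$$

The intercept is never penalized. $\alpha = 1$ is the LASSO; $\alpha = 0.5$
is the default Elastic Net mix. The L1 component produces exact zeros, so a
fitted model doubles as a feature selection; the L2 component lets groups of
correlated features enter together where the pure LASSO would arbitrarily
pick one representative. Although the penalty structure is usually
introduced through the squared-error objective, the outcomes this pipeline
targets are case/control classes, so the loss is the binomial deviance
throughout — the penalty and its sparsity behaviour are unchanged by that
substitution, and evaluation is ROC-based either way. Coordinate-descent
solving is delegated to `glmnet` with its internal standardization disabled:
the data-quality stage autoscales features, so coefficients come back on the
analysis scale. The boundary case is handled analytically: for
$\lambda \ge \lambda_{\max} = \max_j |\langle x_j, y - \bar y\rangle|/(n\alpha)$
the all-zero coefficient vector satisfies the optimality conditions exactly
and is returned as such, with the intercept at the empirical log-odds.

## Penalty optimisation

Each training split gets its own penalty grid: 100 log-spaced values from
the data-derived $\lambda_{\max}$ down to $10^{-4}\lambda_{\max}$.
Stratified 10-fold cross-validation scores the grid by mean out-of-fold
binomial deviance (fold-wise means averaged, with their standard error
across folds). Two selection rules are exposed via `cv_rule`:

* `"min"` — the deviance-minimising $\lambda$, exact ties resolved toward
  the larger (sparser) value;
* `"1se"` — the largest $\lambda$ whose mean deviance is within one
  standard error of the minimum.

`cv_optimize_penalty()` defaults to `"min"`, the natural default for a
stand-alone cross-validation. **Stability selection defaults to `"1se"`.**
The reason is a property of the min rule worth recording: because every
stability iteration resamples from the *same* cohort, a noise feature that
is marginally correlated with the outcome in that cohort is marginally
correlated in almost every training split, and the min rule — which
habitually picks a slightly-too-small $\lambda$ — admits the same few noise
features iteration after iteration. Their appearance counts then clear a
">90 of 100" bar that was meant to filter them out; we verified this
behaviour is not an artifact of our implementation by reproducing the same
admitted features with `glmnet`'s own `cv.glmnet`/`lambda.min` on identical
splits. The one-standard-error rule buys back exactly the sparsity margin
the stability count needs, and on the synthetic benchmark below it recovers
the planted features — and nothing else — essentially always.

## Stability selection

`stability_select()` repeats, `n_iterations = 100` times: draw a fresh
stratified 75/25 train/test split; optimise $\lambda$ by inner CV on the
training part; fit at the chosen $\lambda$; record every feature with a
nonzero coefficient. Features appearing **strictly more than**
`appearance_threshold = 90` times form the stable set (the strict reading
of "more than 90"; the threshold is configurable). Per-iteration
coefficients are kept for the weight-distribution display.

Splitting preserves class proportions exactly: each class contributes
`round(fraction × class size)` samples to training, adjusted only so both
partitions contain both classes; no boosting or undersampling is ever
applied. With the default 75% fraction a 60/40 cohort of 100 yields a
45/30 training split on every draw.

Randomness is organised as one master seed spawning independent
per-iteration streams, so a profile is bit-reproducible and does not depend
on iteration order or on feature column order (up to documented
tie-breaks).

## Panel evaluation and the permutation null

The stable set is small by construction, so panels are enumerated
exhaustively: all subsets up to `max_panel_size` (all sizes when the stable
set has ≤ 10 features, else up to 3 — the cap is configurable). Every panel
is scored on one *shared* schedule of stratified 75/25 resamples — the
default `n_resamples = 1000` — by an unpenalized logistic fit on the
training part and rank-based ROC AUC on the test part, so differences
between panels cannot be attributed to split randomness. Unpenalized
logistic regression is used as the evaluation learner deliberately: the
panel is already selected, the fit is interpretable, and regularisation at
this stage would only bias the comparison between small panels. Ranking is
by mean test AUC, ties toward the smaller panel and then lexicographic.

The top panel's validity is then assessed against an empirical null:
the identical split/fit/score procedure with outcome labels re-permuted
uniformly at random **before every resample**. Re-permuting per resample
(rather than once globally) nulls the entire procedure, not one unlucky
relabelling; permuting before the split preserves class proportions while
destroying feature–label association. The panel is *not* re-selected under
permuted labels: the test quantifies the performance of a fixed panel, not
selection bias — re-running the whole selection per permutation is a far
costlier design and answers a different question. When several $\alpha$
values run (the default pairs LASSO with Elastic Net), the pipeline carries
forward the features identified by *all* methods.

Confusion-matrix metrics (sensitivity, specificity, precision, accuracy)
are reported at a fixed 0.5 predicted-probability threshold; AUC is
threshold-free. Precision is reported as missing — not zero — when no
positive predictions are made. The bounded-iteration IRLS fit saturates
under perfect separation instead of aborting, which matters in small test
partitions.

## Data quality

The preprocessing chain has a fixed, logged order: duplicate-probe merge →
probe-to-gene collapse (when a map is supplied) → near-zero-variance filter
→ missingness handling and median imputation → autoscaling.

* Duplicate probes (identical feature ids) merge to their per-sample
  median.
* A gene with several probes keeps the probe with the highest mean value
  across all samples, verbatim — no cross-probe averaging; mean ties break
  to the lexicographically first probe id.
* A feature is near-zero-variance when the ratio of its most common to
  second most common value exceeds 19 (i.e. 95/5) *and* fewer than 10% of
  its values are distinct — the conventional defaults of this filter, used
  because the underlying idea is standard but the thresholds are not fixed
  by any one source; both are arguments.
* Imputation: features with > 20% missing values are dropped, then samples
  with > 20%, then remaining gaps take the per-feature median of observed
  values. These caps and the median strategy are deliberately simple
  defaults; imputation preferences vary by platform, so everything is
  exposed.
* Autoscaling (zero mean, unit sample SD per feature) can be bypassed for
  matrices already normalised upstream, e.g. RMA-processed microarray data.
* Multi-level outcomes become binary contrasts through `make_contrast()`,
  which pools the requested levels and excludes all others — the pattern
  used when a transitional cohort sits between cases and controls.
* Orientation is never guessed: files with features as rows require an
  explicit `transpose` flag.

## The synthetic benchmark

`simulate_omics()` generates the study conditions every statistical test
runs under: $n = 200$ samples split 50/50 between classes, $p = 103$
features of which 3 are informative, noise i.i.d. standard normal and
informative features adding a 2.0-SD mean shift to the positive class,
optional equicorrelated noise blocks (to exercise the grouped-selection
contrast between Elastic Net and LASSO), optional uniform missingness.
Under this model a single informative feature has population AUC
$\Phi(\delta/\sqrt{2}) \approx 0.92$ at $\delta = 2$, which the generator's
tests verify empirically at large $n$.

What the generator does *not* emulate is worth stating: real platform
artifacts (batch effects, heteroscedastic intensity-dependent noise,
heavy-tailed or skewed distributions), correlated signal (informative
features are mutually independent), label noise, and cohort confounding.
Passing tests therefore demonstrate correctness of the machinery and
selection consistency under a clean Gaussian shift model — not performance
on any particular real platform.

Problem sizes used by the test suite are chosen at desk scale: the
permutation-null checks run the full 200×103 benchmark with 1000 resamples;
parameter-recovery runs 20 independent replicates of the complete
100-iteration selection; unit tests use matrices from 4×3 up to 300×20.
The whole suite completes in a few minutes on a single core.

## Numerical choices

* Predicted probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ before
  deviance evaluation.
* CV deviance curves are compared with `which.min`, which on the decreasing
  grid resolves exact ties toward the larger $\lambda$.
* `glmnet` may truncate a user-supplied path it cannot finish at extreme
  penalties; coefficients are therefore always extracted by
  penalty-interpolation (`predict(..., s = lambda)`), never by position.
* Rank-based AUC uses the Mann–Whitney identity with ties counted ½ — exact,
  with no trapezoid discretisation.
* The report's class box plots carry two-sided rank-sum p-values computed
  by the normal approximation without continuity correction, so they can be
  re-derived from the rank formula directly.

## Limitations

* Binary outcomes only; continuous outcomes and other learners are out of
  scope by design.
* The permutation null does not account for selection bias (the panel is
  fixed before permutation); treat the null as validating panel
  performance, not the selection procedure end-to-end.
* Exhaustive panel search is exponential in the stable-set size; the
  default cap keeps it tractable precisely because stability selection
  keeps stable sets small.
* No batch correction, raw-array normalisation, or enrichment-service
  integration; the package consumes pre-normalised matrices.
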