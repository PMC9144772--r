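---
title: "Methods: composite scoring, response surfaces and LS-SVM for extraction optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite scoring, response surfaces and LS-SVM for extraction optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaeopt)
```

This vignette is the package's own account of the statistics it
implements: the data model and its assumptions, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, the numerical choices made where conventions diverge, and the
known limitations. Every number quoted here is recomputed by the test
suite or the examples; nothing is asserted that the code does not itself
compute.

## The design and the composite response

A Box–Behnken design (BBD) probes k three-level factors with runs at the
midpoints of the cube's edges plus replicated center points. For
k = 3, 4, 5 each non-center run sets exactly two factors to ±1; for
k = 6, 7 the catalog designs vary balanced triples of factors instead
(48 and 56 edge runs). Either construction gives coded columns that sum
to zero and are mutually orthogonal — the property that later makes the
per-term ANOVA partition equal the simple orthogonal-column formula for
linear terms. `build_bbd()` refuses k outside 3–7 rather than improvise
a non-catalog design.

Factors are defined by their natural-unit values at coded −1/0/+1
(`bbd_factor`). The coding map is **piecewise linear** around the mid
level: `(x − mid)/(high − mid)` above it, `(x − mid)/(mid − low)` below.
For symmetric levels this is the familiar `(x − mid)/Δ`; the piecewise
form exists because three-level designs in the applied literature
occasionally use an off-center mid level (e.g. an ethanol series quoted
as 50/70/85%), and the map must still send the anchors exactly to
−1/0/+1 while staying invertible. Values outside `[low, high]` code with
a warning — legitimate for prediction, suspicious for fitting.

With several analytes, a single response is formed as the weighted
composite `Y = Σ wₐ yieldₐ`. Weights may come from a **precedence
chart** — pairwise importance scores in {0, 0.5, 1} whose row sums are
normalized to 1 (`precedence_weights`) — or be supplied directly
(`weight_scheme`). These routes genuinely differ for two strictly
ordered analytes: the row-sum rule gives (1, 0), whereas the packaged
study uses (0.75, 0.25), which must arise from an additional, unstated
normalization. The package therefore treats explicit weights as the
canonical reproduction path and keeps the chart computation as the
documented general rule; `fixture_weights()` returns the published
override.

## The quadratic response-surface model

`fit_quadratic()` fits, by ordinary least squares on the coded design,

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j +
      \sum_i \beta_{ii} x_i^2 + \varepsilon,$$

15 terms for k = 4. The assumptions are the usual ones: the true surface
is locally quadratic over the cube, and replicate error is i.i.d.
Gaussian and homoscedastic. Coefficients are kept at full precision;
two-decimal display is a reporting convention only.

`anova_quadratic()` reports **partial (drop-one-term) sums of squares**,
$SS_j = \hat\beta_j^2 / [(X'X)^{-1}]_{jj}$, the convention of the
commercial DoE software this field uses. On a BBD the linear columns are
orthogonal to everything, so their partial and sequential SS coincide
(a property test cross-checks $SS_j = (\sum x_{ij} y_i)^2 / \sum
x_{ij}^2$ for every linear term); the intercept-adjusted quadratic terms
do not, which is why the partial convention must be implemented rather
than `anova(lm(...))`'s sequential one. F statistics use the residual
mean square; p-values use the exact F distribution with no corrections.
Significance marks follow the strict thresholds `***` p < 0.001, `**`
p < 0.01, `*` p < 0.05 — applied to the computed p, not to its printed
rounding.

The residual is partitioned into **lack of fit** and **pure error**
using exact equality of coded rows to define replicate groups (design
levels are integers, so no floating tolerance is wanted). Degenerate
cases are defined, not left to crash: no replicates at all → the
partition is omitted with a warning; pure-error SS exactly zero → the
lack-of-fit F is infinite and reported with p = 0 plus a warning.

Predicted R² is PRESS-based: $PRESS = \sum_i (e_i/(1-h_{ii}))^2$ from
the leave-one-out identity, so `pred_r2 ≤ r2` always (asserted as a
property test). SS and df additivity are asserted inside
`anova_quadratic()` itself on every call.

## The LS-SVM and its conventions

`fit_lssvm()` solves the (n+1)×(n+1) saddle system
$\bigl[\begin{smallmatrix}0 & 1' \\ 1 & K + I/C\end{smallmatrix}\bigr]
\bigl[\begin{smallmatrix}b \\ \alpha\end{smallmatrix}\bigr] =
\bigl[\begin{smallmatrix}0 \\ y\end{smallmatrix}\bigr]$
directly — at design scale (n ≤ a few hundred) there is no reason for
anything but a dense solve, and the KKT identities $\sum_i \alpha_i = 0$
and $\hat y_i = y_i - \alpha_i/C$ are checked after every fit (the
second ties the dual solution to the primal residuals and catches any
sign or scaling slip immediately).

Three conventions had to be fixed where the applied literature is
silent:

* **Kernel parameterization.** "RBF with parameter g" can mean
  $e^{-d^2/g}$ (g as σ², the classic LS-SVM toolbox convention) or
  $e^{-g d^2}$. The package defaults to the former and exposes the
  latter as `kernel = "rbf_gamma"`. The test suite records the
  in-sample MSE of the packaged design under both conventions at the
  published (g = 0.1, C = 10.4) as a diagnostic; neither reproduces the
  published per-row predictions, so those are never asserted — only the
  pure-arithmetic MSE between the *printed* predictions and the
  replicate-averaged actuals (0.1357) is part of the acceptance surface.
* **Input scale.** Coded units. The published workflow feeds the design
  matrix after "preprocessing"; coded −1..1 inputs are the only scale
  actually documented by the design itself.
* **Duplicates.** Replicated design points make K + I/C structurally
  ill-conditioned in the saddle system and conceptually double-count
  evidence; `fit_lssvm()` refuses them and points at
  `aggregate_replicates()`, mirroring the published 30 → 25 averaging.

`cv_grid_search()` evaluates every (g, C) pair exhaustively.
**Leave-one-out is the default scheme**: at n = 25 it is cheap, and it
removes the one source of nondeterminism (fold assignment) from the
selection; k-fold with a seeded shuffle is available. Ties break toward
the smallest g, then smallest C — preferring the smoother, more
regularized model among equals.

## Surface optimization

For the quadratic, write the fit as $\hat Y = \beta_0 + b'x + x'Bx$.
If B is negative definite and the stationary point $-\tfrac12 B^{-1}b$
lies in the cube, that point is returned analytically
(`analytic-stationary`). Otherwise — optimum on the boundary, or an
indefinite saddle — a dense coded grid (step 0.01) is scanned and the
incumbent polished with box-constrained quasi-Newton
(`grid+polish`). A property test checks both paths agree on random
concave surfaces pushed against the boundary.

For the LS-SVM there is no closed form; `maximize_lssvm()` scans an
exhaustive grid at a user step (default 0.05 coded) and then refines
coordinate-wise at step/10 until no coordinate moves. The published
workflow's "80 gradient data sets (gradient 0.05)" candidate scheme is
under-specified; the dense deterministic grid-plus-refinement used here
can only find an equal-or-better optimum on the same fitted surface,
which is why it supersedes a literal transcription. Grid ties break to
the lexicographically smallest coded point, and a surface that is flat
across the whole grid is flagged (`"grid+polish (flat)"`) rather than
silently returning an arbitrary corner.

## Validation and model comparison

`validation_report()` scores the validation replicates with the same
composite weights, then reports the mean, the spread and the
**relative deviation** $|pred - \bar y|/pred \times 100$ — the
denominator is the model's prediction, which is what makes the published
validation arithmetic reproduce exactly. The spread uses the
**n-denominator (population) SD**: recomputing the published validation
table settles the convention empirically — 0.0963 and 0.0405 are the
n-denominator values of the printed replicates (the n−1 values would be
0.1077 and 0.0453). `compare_models()` ranks ascending by relative
deviation and flags exact ties.

## The synthetic-data generator

`simulate_bbd_experiment()` generates exactly the world the inference
assumes: a fixed quadratic surface evaluated on the BBD, plus i.i.d.
N(0, σ²) noise, with replicated center points sharing their design point
but drawing independent noise. Defaults are calibrated to the packaged
study: `noise_sd = 0.066` (the square root of its residual mean square
≈ 0.0043) and `n_center = 6`. Seeding is part of the spec — the same
`surface_spec` always yields the same table, and the caller's RNG stream
is restored afterwards.

What a green simulation-based test establishes, therefore, is that the
*estimators* are correct under the model's own assumptions: coefficients
are recovered within their 2-standard-error bands in ≥ 90% of draws
(the per-coefficient coverage of a ±2 SE band is ≈ 95%, so the pooled
90% bar is met with margin, not tuned to pass), the residual mean square
is calibrated, and coefficient RMSE shrinks monotonically as σ → 0.
What it does **not** establish: robustness to heteroscedastic or
drifting replicate error, curvature beyond second order, analyte
cross-talk, or measurement error in the factor settings — none of which
the generator emulates (an extended mode adds two correlated analyte
surfaces, but still Gaussian and homoscedastic).

## Numerical choices, in one place

* Composite reproduction tolerance is 5e-5 (half-ulp of four printed
  decimals) plus 1e-12 of floating-point slack — several printed rows
  sit exactly on the half-ulp boundary.
* Replicate grouping: exact equality of coded levels, never a floating
  tolerance.
* LS-SVM solve: dense `solve()`, with a relative-residual check at 1e-8;
  a singular system is an error suggesting a different g, never a silent
  pseudo-inverse.
* Rank-deficient design matrices name the aliased terms and stop.
* Grid scans chunk at 1e5 points and refuse > 1e7 points outright.
* p-values: exact F distribution; marks from computed (not printed) p.

## Known limitations

* BBD only, k = 3–7; no central-composite or fractional-factorial
  designs, no stepwise model reduction or Box–Cox transforms.
* LS-SVM: regression only, RBF/linear kernels only, dense solve — fine
  for designed experiments, wrong tool past a few thousand points.
* The published per-row LS-SVM predictions and its (g, C) = (0.1, 10.4)
  selection are not reproducible without the unstated kernel convention
  and CV scheme; the package records both conventions' diagnostics and
  asserts only convention-independent arithmetic.
* Calibration utilities are deliberately minimal (straight line,
  r², range warning); chromatogram processing is out of scope.
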