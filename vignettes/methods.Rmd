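---
title: "Surrogate modelling and genetic-algorithm dose optimization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modelling and genetic-algorithm dose optimization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnnga)
```

## The problem

Factorial fertilizer trials answer "which of the tested treatments is
best?", but the doses a grower can apply are continuous. This package
treats the trial as training data for a smooth surrogate of the
dose–response surface and then optimizes over the whole dose box. The
packaged dataset is a greenhouse banana trial: 36 treatments on a full
3 × 4 × 3 factorial of N, K and Mg (grams per plant), three replications,
with fruit yield, fruit length and rows-per-spike recorded as
mean ± SEM.

## Replicate reconstruction

Model fitting targets replicate-level observations, but the published
table carries only means and SEMs. `reconstruct_replicates()` draws, per
treatment and trait, `r` values from N(mean, (SEM·√r)²) and affinely
corrects the draw so the sample mean equals the published mean exactly
and the sample SD equals SEM·√r exactly (the identity SD = SEM·√r).
This moment matching means any estimator that depends on the data only
through per-treatment first and second moments sees exactly the published
experiment; what is synthetic is the *shape* of the within-treatment
scatter, which is assumed Gaussian. Cells printed with SEM = 0 yield
identical replicates.

## Preprocessing

* **Inputs** are designed doses, so they are min–max scaled to [0, 1]
  per factor using training-fold extrema (`fit_minmax()`); values beyond
  the extrema scale outside [0, 1] and are deliberately not clipped.
  Bounded inputs suit both the kernel distance and tanh saturation.
* **Targets** are Box–Cox transformed (`boxcox_fit_transform()`), with λ
  chosen by profile maximum likelihood on [−5, 5] per trait and training
  fold. Only targets are transformed: the inputs are fixed design levels,
  not samples from a skewed population. The inverse transform clamps
  λz + 1 at zero so a surrogate extrapolating below the transform's
  domain maps to the domain edge instead of NaN.
* **Outlier screening** (`pca_outlier_flags()`) projects treatments onto
  the principal components explaining ≥ 95% of variance and computes each
  row's score distance. Because the squared score distance of a Gaussian
  row is χ²-distributed with as many degrees of freedom as retained
  components, the familiar "3 standard deviations" threshold is
  calibrated through the χ² quantile with matching tail probability —
  a fixed radius of 3 would have a dimension-dependent false-positive
  rate. Screening is flag-and-report by default; with only 36 treatments,
  silent removal would change results invisibly, so removal is opt-in
  (`outlier_action = "remove"`).
* **Cross-validation** uses one shared 5-fold assignment
  (`kfold_split()`) for both model families, making the comparison
  paired. Folds are assigned over the modelling records — the 108
  reconstructed replicates — rather than over treatments. We verified
  both granularities: record-level folds reproduce the magnitude and
  ordering of the published accuracy table closely, while
  treatment-grouped folds give substantially lower held-out R² for every
  trait. The record-level protocol is therefore the default, with an
  important caveat spelled out below ("What testing R² means here").

## The GRNN

`grnn_fit()`/`grnn_predict()` implement the generalized regression neural
network, i.e. Nadaraya–Watson kernel regression with an isotropic
Gaussian kernel:

$$\hat y(x) = \frac{\sum_i y_i \exp(-D_i^2 / 2\sigma^2)}
                  {\sum_i \exp(-D_i^2 / 2\sigma^2)},
  \qquad D_i^2 = (x - x_i)^\top (x - x_i).$$

Properties the tests rely on:

* predictions are convex combinations of training targets, hence bounded
  by [min y, max y];
* σ → 0 interpolates the exemplars, σ → ∞ predicts their mean;
* evaluation subtracts the largest exponent before exponentiation, so the
  weight sum cannot underflow; the stabilized value equals the naive
  formula wherever the latter is finite.

σ is a single scalar in scaled-feature units (the printed distance form
is isotropic), selected by cross-validated RMSE over 20 log-spaced
candidates in [0.01, 2] — spanning interpolation to heavy oversmoothing
on the unit cube — with ties broken toward the smoother model. Each trait
gets its own univariate GRNN.

## The MLP

`mlp_model()`/`train_lm()` implement a single-hidden-layer perceptron
(tanh hidden, identity output) trained by full-batch Levenberg–Marquardt
on the residual sum of squares, with the Jacobian assembled analytically.
The damping factor starts at 1e−3, ×10 on a rejected step, ÷10 on an
accepted one; iteration stops at `max_iter`, at gradient max-norm
< 1e−8, or when damping exceeds 1e10. Weights initialize uniformly in
[−0.5, 0.5] from a seed and the best-SSE weights seen are returned, so
training is exactly reproducible. These are the conventional LM controls;
all are exposed in the configuration.

The hidden size is picked by "trial and error" made reproducible:
for each candidate in 1..10, five seeded restarts of the shared-fold CV,
scored by the *median* held-out RMSE (LM on n ≈ 100 rows is
init-sensitive; the median ignores the occasional bad basin), ties toward
the smaller network. The default `max_iter` during selection is 200:
on these problem sizes LM converges or stalls well before that, and the
cap keeps the full comparison around half a minute.

## Metrics

`compute_metrics()` reports R² = 1 − SS_res/SS_tot, RMSE, and
MBE = mean(predicted − observed); the sign convention is fixed so
RMSE ≥ |MBE| always holds. Under the shared 5-fold protocol,
"training" metrics pool the in-fold fitted predictions of all five
fold-models and "testing" metrics pool the held-out predictions, both
after inverse-transforming to original trait units. Pooling is the
determinate aggregation when a single training/testing pair is reported
per model and trait.

### What testing R² means here

With folds over replicates, a held-out replicate usually shares its
treatment with training replicates, so "testing" accuracy measures
prediction at noise level *within* the design region — how well the
surrogate denoises — not extrapolation to unseen dose combinations. The
treatment-grouped alternative (folds over whole treatments) measures
true interpolation across the design and is available by constructing
folds per treatment and fitting to means; its held-out R² is naturally
lower. Consumers of the metrics table should know which question it
answers.

## The genetic algorithm

`ga_optimize()` is a real-coded, single-objective GA over the dose box:

* chromosomes are dose triples; initialization is uniform in the box;
* roulette-wheel selection on shifted fitness f − min(f) + 0.01·range(f)
  (roulette needs non-negative weights; the shift keeps the worst
  individual selectable and handles all-equal fitness as uniform);
* 2-point crossover at rate 0.7: two distinct cut points from the gene
  boundaries, middle segment exchanged — on a 3-gene chromosome the cut
  pairs are (1,2), (1,3), (2,3), chosen uniformly;
* uniform mutation at rate 0.04 per gene, redrawing within bounds, which
  also guarantees every candidate ever evaluated is feasible;
* one elite individual per generation (configurable to 0), giving a
  non-decreasing best-fitness history and well-defined "best ever"
  semantics;
* population 200, 1000 generations.

Rates, population and generations follow the trial's optimization
protocol; encoding, elitism and the negative-fitness shift are this
package's determinate choices where that protocol is silent. Non-finite
objective values are demoted to the worst fitness of their generation
with a warning rather than crashing the search.

The GA objective is the better surrogate per trait (higher pooled testing
R²), refitted on *all* data with its CV-selected hyper-parameter — the
selection step answers "which family generalizes better", the refit uses
every observation for the final surface.

## Synthetic experiments as ground truth

`surface_spec()`/`generate_experiment()` simulate factorial trials from a
quadratic-with-interaction surface

$$f(N,K,Mg) = b_0 + \textstyle\sum_f b_f x_f + \sum_f q_f x_f^2
  + b_{NK}\,N\,K,$$

the simplest family exhibiting the phenomenology such trials report:
strong N and K main effects, N×K synergy, curvature/plateaus, and a weak
Mg response with an interior optimum. Defaults are calibrated to resemble
the packaged trial's yield column: values spanning roughly 42–134
kg/plant, an Mg effect of order 8 kg peaking at 50 g, replicate noise SD
6 (the trial's implied replicate SDs mostly lie between 2 and 11), three
replicates on the same 3 × 4 × 3 grid. `true_optimum()` locates the
surface's argmax by a 201-points-per-axis grid sweep plus L-BFGS-B
refinement and is the oracle for optimizer-recovery tests.

What the generator does *not* emulate: non-Gaussian or
heteroscedastic replicate noise (the real trial's SEMs vary strongly by
cell), split applications over time, year effects, or any response shape
outside the quadratic family. Passing parameter-recovery tests therefore
demonstrates the pipeline recovers a known smooth surface at realistic
signal-to-noise — not that the banana surface itself is quadratic.

Two numerical notes on the generator's SEMs: with three replicates a
single cell's sample SEM is χ-distributed with two degrees of freedom and
individually spreads widely around noise_sd/√r (its mean is ~0.89 of the
target and single cells deviate by 50% routinely); unbiasedness holds in
quadrature, so the tests pool cells and compare root-mean-square SEMs,
and verify per-cell concentration at larger replication instead.

## Descriptive analyses

`trait_correlations()` is the Pearson matrix of trait means across
treatments. `upgma_cluster()` z-scores each trait column by its
across-treatment standard deviation, takes Euclidean distances and
agglomerates by average linkage. (The source trial's figure caption
defines its z-score with a standard-error denominator; per-column SD is
the determinate reading and is scale-equivalent for clustering — a
deliberate, documented deviation. Distance and standardization choices
move cluster memberships, so group-membership checks are advisory.)

## Reproducibility

Every stochastic stage scopes its RNG locally from an explicit seed, and
the pipeline derives per-stage seeds from one global seed by fixed
offsets (reconstruction +1, folds +2, model fits +3, GA for trait t
+10t). Reports echo their configuration; rerunning a config reproduces
every number exactly.

## Known limitations

* The GRNN's convex-combination bound means its GA-maximized prediction
  can never exceed the best training observation; optimizing it can
  confirm near-best doses and find cheaper equivalents, but cannot
  predict yields beyond the observed range.
* Published optimization results for this trial report interior optima
  (~55–76 g of each nutrient) for fruit length and rows-per-spike with
  predicted values well below those traits' best observed means. A
  kernel-regression surrogate maximized over the box peaks near its best
  exemplars instead, and this package's results do so for all three
  traits; the discrepancy is structural, not a tuning matter.
* With n = 36 design cells, surrogate accuracy between design points is
  limited by the grid spacing; the dense-grid recovery tests quantify
  this on synthetic surfaces.
* Replicate reconstruction assumes Gaussian within-cell noise; heavy
  tails in the real replicates would alter Box-Cox λ and σ selection.
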