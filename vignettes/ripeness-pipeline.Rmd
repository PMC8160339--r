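---
title: "Grading fruit ripeness from bioimpedance spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading fruit ripeness from bioimpedance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ripegrade)
```

`ripegrade` implements a complete discrimination pipeline for fruit
ripeness from electrical impedance spectroscopy (EIS, "bioimpedance" on
biological tissue): synthetic data generation, spectral feature
engineering, frequency and covariate screening, F-beta-optimised training
of six classifier families with backward feature selection, bootstrap
validation, a two-stage multi-layer-perceptron search, and a train/test
report table. This vignette explains the underlying models, the tunable
parameters, and the design decisions taken where the problem was genuinely
open.

## The measurement model

A fruit pressed onto a pair of electrodes, swept with a small AC signal,
yields a complex impedance $Z(\omega)$ per frequency. Tissue with a single
relaxation process is well described by the Cole model

$$Z(\omega) = R_\infty + \frac{R_0 - R_\infty}{1 + (j\omega\tau)^\alpha},$$

with zero- and infinite-frequency resistances $R_0 > R_\infty > 0$ (ohms),
characteristic time $\tau$ (seconds) and a constant-phase-element exponent
$\alpha \in (0, 1]$ that depresses the impedance arc. The pipeline uses
this model *generatively* only — spectra are never fitted to it. Circuit
fitting is deliberately out of scope: over a 20 Hz–300 kHz sweep the
high-frequency plateau that anchors $R_\infty$ lies outside the band, so
fitted parameters are unreliable, and the scalar index $P_y$ (below)
already summarises the same resistances.

## The synthetic fruit batch

Because no public fruit EIS dataset accompanies this problem, the
generator is first-class, tested code. It emulates:

* **Two ripeness classes** defined by the CIELab redness coordinate
  $a^*$ with threshold 35: `label = 1` iff $a^* > 35$ (boundary values go
  to unripe — the threshold side is a convention the package fixes).
* **The study sample sizes**: 534 unripe + 150 ripe training fruit,
  128 + 111 test fruit (train/test 684/239).
* **Heavy class overlap**: a latent ripeness score $u \sim N(0,1)$ drives
  both the colour, $a^* = 30 + 10u + \varepsilon$ with
  $\varepsilon \sim N(0, 8)$, and the spectra: $\log R_0$ and $\log\tau$
  shift *down* with $u$ (ripening tissue loses low-frequency resistance
  and its dispersion moves up in frequency), scaled by a single
  `separation` parameter.
* **Size-dependent scaling**: impedance is multiplied by
  $g(\text{size}) = \text{size}/\text{reference size}$ — electrode
  separation grows with the fruit — so raw magnitude features are
  confounded with size, which is exactly what the frequency screen and
  size covariate are there to handle.
* **Measurement noise**: multiplicative log-normal magnitude noise
  (relative sd 2%) and additive Gaussian phase noise (sd 0.5°), visually
  consistent with bench-top sweeps of soft fruit; both configurable.

Baseline Cole values ($R_0 \approx 2\,\mathrm{k\Omega}$,
$R_\infty/R_0 \approx 0.1$, $\tau \approx 2\times10^{-5}\,$s so the
dispersion sits mid-band, $\alpha \approx 0.75$) are typical of
fresh-fruit tissue measured with surface electrodes at these frequencies.

The default `separation = 2.5` was calibrated once, as part of the
package's study conditions, so that a grid-tuned KNN reaches an external
test F1 of roughly 0.7–0.8 — the difficulty regime this kind of on-plant
fruit classification lives in. Below that the task saturates near the
noise ceiling imposed by the colour noise: with $a^*$ noise sd 8 the class
boundary in $u$ is intrinsically fuzzy, so even a perfect recovery of $u$
cannot push F1 much past the mid-0.8s.

What the generator does **not** emulate — and hence what passing tests do
not certify about real fruit: electrode-polarisation and instrument
residual artifacts, multi-dispersion tissue, day-to-day longitudinal
structure, and any correlation between fruit size and ripeness. The last
point matters for interpreting the size screen below.

## Feature engineering

From each spectrum the package derives magnitude $|Z|$, signed phase
$\varphi \in (-90°, 0]$ and the loss tangent
$\tan\delta$ with $\delta = 90° - |\varphi|$, equivalently
$\mathrm{Re}(Z)/|\mathrm{Im}(Z)|$ (capped at $10^6$ with a warning where
$\mathrm{Im}(Z) = 0$). Scalar features:

* $P_y = 1 - |Z|(f_{\max})/|Z|(f_{\min})$ — the relative magnitude drop
  across the band. For a single dispersion with both plateaus in band this
  approaches $1 - R_\infty/R_0$, and the geometry factor cancels, making
  it size-invariant. The literature index it implements is cited without
  a reprinted formula in the source material, so the definition is
  isolated in `compute_py()` where an alternative is a one-line swap.
* **Minimum phase** — the most negative phase *value* over the grid (not
  its frequency; the feature count only works with one scalar).

Five frequency points per derived curve, plus $P_y$ and minimum phase,
give 17 bioimpedance features; fruit size (mm) is the 18th.

## Frequency screening

Each curve's value at each grid point is correlated with $a^*$ and with
size; good points correlate with colour and poorly with size. Design
choices, since the original procedure was visual:

* **Rank (Spearman) correlation** by default — impedance–colour relations
  are monotone but not linear; a Pearson switch is provided.
* "Median correlation" is operationalised as the median over `n_boot`
  bootstrap resamples of the fruit (default 100; `n_boot = 1` is a plain
  correlation).
* Selection is deterministic: with
  $D(f) = |r_{\text{colour}}| - |r_{\text{size}}|$, candidates are zero
  crossings of $D$ (ranked by $|dD/d\log f|$) and interior local maxima
  (ranked by $|D|$), picked greedily with at least `min_sep = 0.3` decades
  between picks — neighbouring frequencies are strongly autocorrelated.
  Too few candidates are padded with evenly log-spaced points. An explicit
  frequency list can override the automatic choice.

## The size covariate screen

For each feature $X_i$, three nested linear models of colour are fitted by
maximum likelihood: $a^* \sim X_i$, $a^* \sim X_i + Z$ and
$a^* \sim X_i * Z$ with $Z$ the size, compared by likelihood-ratio tests
($2\Delta\log L \sim \chi^2_1$, significance at $p \le 0.05$, inclusive,
no multiple-testing correction — the screen reports raw per-feature
p-values). Size is treated as a **fixed continuous covariate**: a
continuous per-observation "random effect" is unidentifiable in this
design, and the nested formulas above are covariate-style; ML (not REML)
fitting keeps the likelihood-ratio tests between fixed-effect structures
valid.

On synthetic batches only the magnitude-derived features benefit from the
size covariate (roughly 5 of 17 significant) because the generator couples
size into the spectra only through the geometric factor $g$, and size is
independent of ripeness. On real fruit all 17 features can benefit. The
pipeline follows the design decision to always keep size in the feature
set; the screen documents *why*.

## Classifiers, priors and the F-beta objective

The training set is imbalanced (534:150), so accuracy is a poor figure of
merit. All optimisation uses

$$F_\beta = \frac{(\beta^2 + 1)\,P\,R}{\beta^2 P + R}$$

at $\beta \in \{1, 0.5, 2\}$ (balanced, precision- and recall-oriented).
Edge cases are pinned: no true positives with any error gives 0; a
perfect prediction gives 1; an all-empty confusion is defined as 0 with a
warning. Features are z-scored with training statistics (refit inside
every CV fold, so no leakage), and both class priors are treated as
uniform. The mechanism is per family, since "uniform priors" alone does
not fix one: case weights for ridge logistic regression (`glmnet`),
native class priors for the decision tree (`rpart`), equal log-priors in
the in-package naive Bayes (Gaussian or kernel-density likelihoods),
inverse-class-frequency-weighted voting for the in-package KNN
(euclidean or manhattan), and class weights for the SVM (`e1071`).
Hyperparameter grids live in the configuration, not in code; each grid is
enumerated simplest-first so score ties resolve toward the simpler model.

## Backward selection, importance, and validation

Feature selection is multi-pass greedy backward elimination: from all 18
features, each pass removes the single feature whose removal most
improves the cross-validated $F_\beta$ (stratified folds fixed by seed
across the whole grid), stopping when no removal improves by more than
`tol = 1e-4`. Size is never removable. Running this across every
hyperparameter combination yields a **selection-frequency importance**
per feature; thresholds on it give four nested subsets of sizes
18/12/9/6 (full, and roughly 2/3, 1/2, 1/3 — a stated subset count of 20
per model is arithmetically irreconcilable with three thresholds plus the
full set, so four subsets per family per beta is what the package
builds). Each subset gets a final grid search; the best-CV subset is
validated by an out-of-bag bootstrap (train on a resample, score the
left-out rows; single-class draws and empty out-of-bag sets are redrawn
and counted) and then frozen for external testing.

The report's "train" column for classical families is the bootstrap
median; for MLPs it is the internal-test estimate. Both are
training-data estimates of generalisation. Note that $F_\beta$ is
prevalence-sensitive: the training estimates are computed at the skewed
training prevalence (22% ripe) and the external test at a balanced one
(46%), so on synthetic batches the "test" column can legitimately exceed
"train".

## The MLP branch

MLPs use all 18 features (no SFS): 18 inputs, one or two tanh hidden
layers, a 2-node softmax output, class-weighted cross-entropy. The search
is two-stage on 60:20:20 stratified splits (reduced-train / validation /
internal-test; each 20% part gets `round(0.2 n)` rows, remainder to
train — 684 splits 410/137/137): stage 1 searches node counts (1-layer
sizes and 2-layer pairs $n_1 \ge n_2 \ge 1$, total $\le$ 20) per training
function; stage 2 retrains each function's winner on a second split and
keeps the best internal-test $F_\beta$.

The eight training functions are a registry of classical optimiser
configurations: plain gradient descent, momentum, adaptive learning rate,
momentum + adaptive, Fletcher–Reeves and Polak–Ribière conjugate
gradients, BFGS (the latter three via `stats::optim`), and a
Levenberg–Marquardt-type damped Gauss–Newton. For two classes the softmax
Fisher matrix is rank-one per sample, so the LM step reduces to the
Jacobian of the logit *difference* — an $n \times p$ matrix — which keeps
the update exact and cheap.

Early stopping monitors validation F1 each epoch (one epoch = 10
optimiser steps) with patience 10 over at most 500 epochs, restoring the
best-validation weights. Activation, loss, patience and the epoch
granularity are package choices; nothing in the source procedure pins
them.

## Numerical and scale choices

Desk-scale defaults keep a full run in minutes on one core: 5-fold CV in
the SFS stage with small per-family grids, full grids only in the final
optimisation, 200 bootstrap rounds, MLP search capped at 6 hidden nodes
and 150 epochs. The full-scale protocol (10-fold SFS CV over the full
grids, 10,000 bootstrap rounds, 20-node MLP search) is reachable entirely
through `pipeline_config()`. The test suite uses the same machinery at
smaller sizes (toy feature tables of 60–400 rows; the full 684/239 batch
where the property under test needs it).

Other numerics worth knowing: the frequency grid is exactly
log-spaced with endpoints pinned; grid membership of selected
frequencies is checked to a relative $10^{-6}$ (CSV round-trips preserve
15 significant digits; no interpolation ever happens); percent
differences round half-away-from-zero to one decimal and F scores to
three, which is the convention that reproduces a reference report's
printed differences from its printed scores; all randomness flows from
explicit integer seeds, and two runs with one configuration byte-match
their CSV outputs.

## Known limitations

* Synthetic spectra are single-dispersion with well-behaved noise; real
  electrode contact adds artifacts the screen cannot see here.
* The bootstrap "train" estimate inherits the skewed-prevalence bias
  discussed above; comparing it to a balanced external test mixes two
  effects (generalisation and prevalence).
* Greedy backward elimination finds local optima; with many equally
  uninformative features it stops early, which flattens importance
  contrasts on easy problems.
* The kernel-density naive Bayes uses per-feature univariate densities
  with a fixed floor; heavily multimodal features may be better served by
  the Gaussian variant despite its stronger assumption.
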