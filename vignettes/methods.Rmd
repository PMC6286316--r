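---
title: "Online optimization of microscope acquisition parameters: models and methods"
author: "stedopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online optimization of microscope acquisition parameters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stedopt)
```

## The problem

Super-resolution modalities such as STED are acutely sensitive to their
acquisition parameters: excitation and depletion power, pixel dwelltime.
Good settings vary between samples, structures and even regions of a
coverslip, and every mis-parameterized acquisition costs fluorophores
(photobleaching), sample health and operator time. `stedopt` treats
parameter selection as an *online* optimization problem: each acquisition
both produces a scientific image and informs the choice of the next
configuration, so that the cost of learning is paid in useful images
rather than in a separate calibration phase.

The machinery is a multi-armed bandit over a discretized parameter grid,
driven by Thompson sampling on a kernel-regression posterior, extended to
multiple objectives through sampled "option clouds" and a preference
function (a human expert, a simple scalarization, or a learned ranking
network).

## Kernel regression posterior and Thompson sampling

The objective $f$ (say, the autocorrelation amplitude of a periodic
structure) is modeled over the grid $\mathcal X$ with an anisotropic
Gaussian kernel

$$k(x, x') = \exp\Big(-\sum_{i=1}^D \frac{(x_i - x'_i)^2}{2\rho_i^2}\Big),$$

with a per-dimension bandwidth defaulting to $\rho_i = \ell_i D / 3$
($\ell_i$ = span of parameter $i$, $D$ = number of parameters). After $N$
observations $\mathbf y_N$ at configurations $x_1,\dots,x_N$, the
posterior over $f$ is Gaussian with

$$f_{\lambda,N}(x) = \mathbf k_N(x)^\top (\mathbf K_N + \lambda I)^{-1}
  \mathbf y_N, \qquad
  k_{\lambda,N}(x,x') = \frac{\sigma^2}{\lambda}\big[k(x,x') -
  \mathbf k_N(x)^\top (\mathbf K_N + \lambda I)^{-1} \mathbf k_N(x')\big].$$

Each round, `sample_function()` draws one function from this posterior
and `select_config()` acquires where the draw is optimal — the classic
Thompson-sampling recipe, which explores exactly in proportion to the
posterior probability of a configuration being the best one.

Numerical and modeling choices:

* **Regularizer $\lambda$.** Defaults to 1, so the prior variance equals
  the noise estimate; it is a free knob in `kernel_spec()`.
* **Noise variance $\sigma^2$.** Estimated as the mean squared residual
  between observations and the current predictive mean, clipped into
  declared bounds (defaults 0.001–0.3; an upper bound of 3 suits
  intensity-scale objectives such as uncaging peak intensity). An empty
  history uses the upper bound — maximal caution. This clipped-residual
  estimator is the simplest one respecting the stated bounds; the
  bound on the feature-space weight norm (default 5) is carried in
  `kernel_spec` and used only to sanity-check synthetic ground-truth
  scales, as it does not enter the posterior equations.
* **Bandwidth formula.** $\rho_i = \ell_i D/3$ is implemented as stated;
  growing the bandwidth with $D$ is unusual (most heuristics shrink it),
  so `default_bandwidths(..., divide_by_dims = TRUE)` offers
  $\ell_i/(3D)$ for users who prefer the conservative reading. With one
  parameter the two coincide.
* **Sampling jitter.** Covariance factorization failures are retried
  with diagonal jitter $10^{-8}\,\mathrm{tr}(\Sigma)/n$, escalated
  tenfold at most three times. A zero-trace covariance returns the mean
  (degenerate Gaussian). The Gaussian draw is consumed *before*
  factorization so that seeded trajectories do not depend on the jitter
  path.
* **Ties** in the arg-max are broken toward the lowest grid index, and
  the grid is enumerated row-major with the first declared dimension
  varying fastest; determinism keeps replay comparisons exact.

## Multi-objective loop

With $K$ objectives, $K$ *independent* kernel-TS models are maintained —
observations are never shared across objectives, since e.g. bleaching
and quality respond differently to the same parameters. One function is
sampled per posterior; joining their per-configuration values yields an
option cloud with one $K$-vector per grid configuration. A preference
function picks one option; the configuration behind it is acquired and
all objectives evaluated on the resulting image are appended to their
histories. Failed acquisitions are recorded (configuration kept,
objectives `NA`) and excluded from regression, since the posterior
equations need numeric observations. There is no forced exploration
phase: round 1 samples from the zero-mean prior, which is already
near-uniform exploration.

The cloud has exactly one option per grid configuration. Published
experiments report cloud sizes that differ slightly from their quoted
grid cardinalities; since the mechanism is per-configuration sampling we
keep the one-to-one default and leave subsampling to the caller.

## Image-derived objectives

* **Foreground** is extracted by Otsu's method over a 256-bin histogram
  spanning the image range; the mask keeps pixels strictly above the
  threshold. A constant image has no separable modes and yields an empty
  mask with a degenerate flag.
* **SNR** is $(\mathrm{STED}_{fg}^{75} - \overline{\mathrm{STED}_{fg}})
  / \mathrm{Confocal1}_{fg}^{75}$, each image masked by its *own* Otsu
  foreground; percentiles interpolate linearly between order statistics
  (the `type = 7` convention).
* **Photobleaching** is the relative drop of the before-confocal
  foreground mean across the STED scan, with the before-mask applied to
  both confocal images. It is reported unclipped — negative values
  (intensity increase) are informative. Under photon noise the noisy
  mask preferentially retains noise-high pixels, which biases the
  estimate upward by a fraction of the observation noise; the simulator
  round-trip tests bound this truncation bias at three noise standard
  deviations.
* **Autocorrelation amplitude** of a line profile is the difference
  between the first local maximum following the first local minimum (at
  positive lag) of the mean-subtracted, variance-normalized
  autocorrelation over lags $0..n/2$. The *unbiased* estimator (lag-$k$
  sum divided by $n-k$) is used: the biased one tapers by $1-k/n$ and a
  pure 180 nm cosine sampled at 20 nm could then never reach the
  theoretical amplitude of 2 at realistic profile lengths. "First
  maximum after first minimum" pins down the lattice signature while
  excluding the trivial maximum at lag 0.
* **FRC resolution**: the image is split by a moving 2×2 bin into four
  independent sub-images at doubled pixel size, each Hann-windowed
  ($\alpha=\beta=0.5$) in both axes and Fourier transformed. Ring
  correlation on integer-radius rings (DC excluded) is averaged over all
  six unordered pairs, smoothed with a moving average of half-width 3,
  and compared against the 3-σ threshold curve $3/\sqrt{n_{ring}/2}$;
  the resolution is the reciprocal of the first sub-threshold frequency,
  absent when no crossing occurs. At 40 nm subsampled pixels the
  estimate is coarse; it is reported, not validated against optical
  ground truth.
* **Calcium uncaging**: frames are tiled 8×8 pixels; a tile is
  foreground when its mean over all baseline frames plus the first ten
  response frames exceeds the photon threshold (default 5 counts,
  applied globally). $\Delta F/F$ uses the time-averaged baseline as
  $F_0$ and the average of the first two response frames as $F$. The
  response size ratio is the fraction of foreground tiles at
  $\Delta F/F \ge 0.75$; at a 0.6 threshold a positive ratio classifies
  as a local response, above it as widespread. Partial trailing tiles
  are dropped.

## Offline baselines

Grid search acquires a fixed number of images at every grid point and
picks the best sample mean; its budget is (grid size) × (repeats) — 50
for ten configurations at five repeats, 5000 for a 10³ grid. Random
sampling draws configurations uniformly with replacement. NSGA-II runs
on continuous genomes within the grid's box bounds with the canonical
bounded simulated-binary crossover and polynomial mutation (both
crowding degree η = 20, mating probability 0.9, per-gene mutation
probability 1/D), non-dominated sorting and crowding-distance
truncation; every evaluation re-acquires its images (no caching), which
is what makes the 10 generations × 10 individuals × 3 images = 300
budget exact. The operators are implemented natively from the canonical
algebra so no optimization library is required, and are tested for
bound-respecting behavior and front coverage on an analytic toy.

## The synthetic microscope and replay harness

No physical instrument is available to a package, so `ground_truth()` +
`generate_image()` define a forward model with known optima: a
horizontal "dendrite" band over dark background carrying a vertical
raised-cosine lattice with a 180 nm period at 20 nm pixels (the axonal
actin-ring geometry), Poisson shot noise on expected counts, and an
after-confocal attenuated on the foreground by the configured bleaching
fraction. The quality surface is a unimodal Gaussian bump over the
normalized parameter space (peak 0.5, width 0.22, maximum 0.9 by
default) scaling the lattice amplitude (default peak 20 photons over a
background of 2); bleaching saturates exponentially in the mean
normalized parameter. These shapes — a rise to a plateau and decline,
with bleaching growing with dose — were chosen once to mirror the
qualitative dose–response of the real instrument, and deliberately not
revisited. The simulator declares its own lattice-detectability rule:
an image fails when the measured autocorrelation amplitude falls below
1.0, half the ideal noise-free amplitude.

What the simulator does *not* emulate: realistic point-spread functions,
drift, structure heterogeneity, phototoxicity, or expert judgment of
image quality (its quality surface is a proxy, not a reconstruction of
expert scoring). Tests passing on it demonstrate the optimization and
analysis machinery, not performance on real micrographs.

The replay harness mirrors the replay-experiment protocol: a dataset of
pre-generated triplets (12 excitation powers × 39 images = 468 in the
reference configuration) with queues shuffled per trial seed; each
selection pops the chosen queue's head, so algorithms issuing identical
selection sequences observe identical images. Queues never exhaust at
the reference scale (39 ≥ any per-config demand in 60 iterations);
should they, they recycle from the start with a flag. The benchmark —
100 trials of 60 iterations — shows kernel TS accumulating failures
sublinearly (second-half increment well under 70% of the first half)
while grid search's halves differ by a few percent.

## Learned preference articulation

The scorer is a shallow fully connected network: two hidden layers of
ten rectifier units, scalar output. A cloud of $N$ options with one
chosen yields $N-1$ (chosen, rejected) pairs; training minimizes the
mean margin ranking loss over shuffled batches of 128 pairs with the
adaptive-moment optimizer (rate 0.001, decays 0.9/0.999), stopping when
the validation loss stalls for ten epochs and returning the
best-validation weights. Objectives are normalized to [0, 1] by their
declared ranges before scoring, since quality (0–1), bleaching (0–1)
and time-per-pixel (µs) live on incommensurate scales.

Two loss variants exist. The form $(s_i - s_\star - m) \vee 0$ assigns
*zero* loss at score equality, so a scorer that maps every option to the
same constant is a global minimum of the training objective — gradient
training reliably stalls there before any ranking is learned (we
measured 21% top-1 teacher agreement versus 99% for the hinge). The
conventional margin ranking loss $\max(s_i - s_\star + m, 0)$ penalizes
ties by the margin and is what "penalized when the chosen option's score
is below the rejected option's within a margin" describes; training
therefore defaults to the hinge, with the other form available as
`variant = "printed"`. `margin_ranking_loss()` itself evaluates the
printed form by default so both conventions remain inspectable.

## The quality-rating network

The fully convolutional rater has six 3×3 convolution layers of widths
32, 48, 48, 64, 64, 64, each followed by spatial batch normalization and
an exponential-linear activation, with 2×2 max pooling after all but the
last layer (deepest downsampling factor 32). The head combines the
activations of the last three layers — at 1/8, 1/16 and 1/32 resolution
— by upsampling the coarser two (nearest-neighbor) to the 1/8 grid and
applying a learned 1×1 linear combination over the concatenated
channels, then a sigmoid; a H×W input yields a H/8 × W/8 score map in
[0, 1]. The global score is the map mean over the Otsu foreground mask,
resized nearest-neighbor to the map grid and binarized; an empty mask
returns an undefined-value sentinel rather than a score over empty
background. Being fully convolutional, the network accepts arbitrary
sizes; inputs are center-cropped to multiples of 32 so the three head
grids align exactly, and anything under 32 pixels errors.

Everything — convolution (im2col + BLAS products), batch-norm and
pooling backward passes, the Adam updates — is implemented natively in
the package and verified against finite differences in the test suite.
Training whitens inputs by the training-set mean/sd, optionally augments
with 90° rotations, reflections and intensity scaling, and minimizes the
RMSE between masked global scores and expert targets with Adam at rate
0.002 halved every 50 epochs, batch size 96. The package's contract is
architectural fidelity plus smoke-scale trainability: an 8-image,
200-epoch memorization run reaches training RMSE well under 0.05.
Large-scale training on thousands of expert-scored micrographs is out of
scope, so no claim is made about validation error on real data.

A note on the rotation test: plain convolution with arbitrary kernels is
not equivariant under 90° rotation, so the suite checks equivariance
with 4-fold-symmetric kernels — that isolates what *should* be
rotation-stable, namely the padding, pooling and upsampling alignment.

## Evaluation

Failure rules follow the "below"/"over" wording with strict
inequalities: quality < threshold fails, bleaching > threshold fails,
and missing objectives referenced by a rule count as failures. The
cumulative failure count per trial is the regret curve; curves average
element-wise across trials. Confidence intervals are percentile
bootstrap (plain resampling, default M = 1000 at 95%) — not BCa — and
the response-frequency curve reports, per threshold, the fraction of
defined response-size ratios that are positive and at most the
threshold, with bootstrap bands. The suite verifies 93–97% empirical
coverage of the 95% interval for a Gaussian mean at n = 100 over 500
replications.

## Problem sizes and determinism

The shipped benchmarks use the sizes of the reference protocol where
they are cheap (468-image replay datasets, 100 trials × 60 iterations,
500/100 preference training records, M = 1000 bootstrap) and smoke
scales where full scale is a data-collection exercise rather than an
algorithmic one (8-image quality-net memorization, 64×64 synthetic
fields). Every stochastic component draws from R's RNG so a single
`set.seed()` — or the `--seed` flag of `scripts/acceptance.R` —
reproduces a run exactly; replay trajectories are fully determined by
the (dataset seed, trial seed) pair.

## Known limitations

* The parameter grid is dense and enumerable; nothing here scales to
  continuous spaces or to grids beyond a few thousand configurations
  (posterior covariance is dense over the grid).
* The noise-variance estimator is a pragmatic clipped residual; it
  inherits no regret guarantees.
* FRC on 2×2-subsampled small images is frequency-starved; treat the
  resolution numbers as indicative.
* The simulator's quality ground truth is a stand-in for expert rating;
  agreement with human scoring is untested by construction.
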