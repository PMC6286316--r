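# stedopt

Online optimization of fluorescence nanoscopy acquisition parameters
with kernelized Thompson sampling.

Point-scanning super-resolution microscopy (STED in particular) lives or
dies by its acquisition parameters — excitation power, depletion power,
pixel dwelltime. The right settings differ between samples and
structures, and every badly parameterized scan bleaches fluorophores and
wastes sample. `stedopt` treats parameter selection as a multi-armed
bandit over a discretized parameter grid 𝒳: each objective *f* is
modeled by kernel regression with an anisotropic Gaussian kernel

  k(x, x′) = exp( −Σᵢ (xᵢ − x′ᵢ)² / 2ρᵢ² ),   ρᵢ = ℓᵢ·D/3,

whose posterior after N observations **y**_N has mean
f_{λ,N}(x) = **k**_N(x)ᵀ(**K**_N + λI)⁻¹ **y**_N and covariance
(σ²/λ)[k(x,x′) − **k**_N(x)ᵀ(**K**_N + λI)⁻¹ **k**_N(x′)], with σ²
estimated from residuals within declared bounds. Thompson sampling draws
one function from the posterior and acquires where the draw is optimal;
with several objectives, one draw per objective forms a *cloud of
options* (one per grid configuration) from which a preference function —
a scalarization, a human, or a trained ranking network — picks the
trade-off to acquire next.

The package provides, as first-class tested code:

* the kernel-TS posterior, sampling and selection (`compute_posterior`,
  `sample_function`, `kernel_ts_run`);
* the multi-objective loop with option clouds and preference functions
  (`run_optimization`, `build_option_cloud`, `choose_option`);
* every image-derived objective used in the workflow: Otsu foreground,
  SNR, photobleaching, autocorrelation amplitude of periodic lattices,
  Fourier ring correlation resolution with the 3-σ criterion, and
  calcium-uncaging ΔF/F response statistics (`compute_objectives`,
  `frc_resolution`, `calcium_response`);
* offline baselines: grid search, random sampling and a native NSGA-II
  with bounded SBX crossover and polynomial mutation (`grid_search`,
  `random_sampling`, `nsga2_optimize`);
* a synthetic microscope with known ground truth plus a
  replay-experiment harness in which algorithms selecting the same
  parameters observe the same images (`ground_truth`, `generate_image`,
  `build_replay_dataset`, `replay_run`);
* a shallow preference-ranking network trained with the margin ranking
  loss (`train_preference`, `predict_choice`) and a fully convolutional
  image-quality rater with masked global scoring (`quality_net`,
  `train_quality`, `masked_global_score`) — both implemented natively
  with verified backpropagation;
* regret accounting and percentile-bootstrap confidence intervals
  (`cumulative_regret`, `bootstrap_ci`, `response_frequency_curve`).

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.

## Worked example: replay comparison of Kernel TS and grid search

```r
library(stedopt)

# 12 laser excitation powers, one objective: lattice autocorrelation
space <- parameter_space(list(excitation = seq(0.2, 21.1, length.out = 12)))
spec  <- kernel_spec(default_bandwidths(space))

# synthetic microscope with a known unimodal quality landscape
truth   <- ground_truth(space)
dataset <- build_replay_dataset(space, images_per_config = 39,
                                truth = truth, seed = 1)
dataset
#> Replay dataset: 12 configurations x 39 images = 468 images

# one replay trial: Kernel Thompson sampling vs grid search, 60 images each
ts <- replay_run(dataset, function(acquire, sp)
  kernel_ts_run(acquire, sp, spec, T = 60), trial_seed = 7)
gs <- replay_run(dataset, function(acquire, sp)
  grid_search(grid_search_plan(sp, 5), acquire), trial_seed = 7)

rule <- function(v) cumsum(v < truth$detect_min)
data.frame(images = c(30, 60),
           ts_failures = rule(ts$values)[c(30, 60)],
           gs_failures = rule(gs$values)[c(30, 60)])
#>   images ts_failures gs_failures
#> 1     30           2          14
#> 2     60           2          29

# where did each algorithm spend its acquisitions?
table(grid_matrix(space)[ts$selections, 1])
#>  0.2    4  7.8  9.7 11.6
#>    1    1    1   30   27
```

Both algorithms replay the *same* pre-generated image queues. Grid
search cycles all twelve powers five times and accumulates failures
(images whose lattice autocorrelation amplitude falls below the 1.0
detectability rule) linearly — 14 in the first half, 15 in the second.
Thompson sampling fails twice during early exploration, then
concentrates 57 of its 60 acquisitions on the two powers flanking the
quality peak and stops failing: the sublinear-versus-linear regret
contrast that motivates online optimization.

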