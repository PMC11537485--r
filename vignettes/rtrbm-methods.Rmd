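---
title: "Modeling neural assembly dynamics with the RTRBM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neural assembly dynamics with the RTRBM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtrbm)
```

## The model

A restricted Boltzmann machine (RBM) describes binary population activity
`v` (one unit per neuron) through binary latent units `h` (one per putative
neural assembly) with the joint distribution

    P(v, h) = exp(-E(v, h)) / Z,
    E(v, h) = -(bv.v + bh.h + h' W v),

where `W` (`Nh x Nv`, stored hidden-major) couples assemblies to neurons.
Because the graph is bipartite, both conditionals factorize:
`P(h_j = 1 | v) = sigmoid(bh_j + (W v)_j)` and
`P(v_i = 1 | h) = sigmoid(bv_i + (W' h)_i)`, which makes blockwise Gibbs
sampling and contrastive-divergence (CD) learning practical. The RBM is a
purely static model: samples drawn from it explore population patterns but
carry no temporal order.

The recurrent temporal RBM (RTRBM) chains RBMs over time. The hidden bias
at time `t` is shifted by the previous *expected* hidden state:

    r[1] = sigmoid(W v[1] + binit)
    r[t] = sigmoid(W v[t] + bh + U r[t-1]),   t > 1,

and the step-`t` distribution is an RBM with hidden bias `bh + U r[t-1]`
(`conditional_rbm_at_t()`). The real-valued mean-field states `r[t]` — not
binary samples — are propagated forward; `U` (`Nh x Nh`, directed,
asymmetric) holds the assembly-to-assembly temporal interactions the
package exists to estimate. A positive `U[j, i]` means assembly `i`'s
activity at one step raises assembly `j`'s activation probability at the
next.

## Training

Gradients of the sequence log-likelihood `sum_t log P(v[t] | r[t-1])`
decompose into per-step CD gradients (the conditional RBM at each step,
teacher-forced on the data-derived `r[t-1]`) plus a temporal part obtained
by backpropagation through the deterministic `r` recursion
(`bptt_gradients()`). Two implementations coexist deliberately: a
stochastic CD-K estimator (the compiled kernel used by training) and an
enumeration-based exact gradient for small models. The exact path is the
package's internal oracle — the test suite verifies it against central
finite differences of `exact_sequence_loglik()` to relative error below
1e-4, and verifies the stochastic kernel against it in expectation.

`train_rtrbm()` runs mini-batch gradient ascent over contiguous time
windows (default 16 columns, the batch size regime used for whole-brain
recordings), accumulating `batches_per_update` batches (default 20) per
parameter update. Defaults that matter:

* **Optimizer.** Adam (decay 0.9/0.999) with learning rate `3e-3` at desk
  scale; plain SGD with optional momentum is available
  (`optimizer = "sgd"`). Plain SGD from small random weights consistently
  stalls in local optima on assembly data within any reasonable update
  budget (hidden units stay symmetric or settle into distributed codes),
  which is why it is not the default.
* **Initialization.** The visible bias starts near the data log-odds and
  the hidden biases at -3 (a sparse hidden code); de-novo weights warm-start
  from a Ward clustering of the neuron-neuron correlation matrix into
  `n_hidden` groups (`init_method = "assembly"`), each cluster contributing
  an indicator row scaled to 5. The warm start computes an `Nv x Nv`
  correlation matrix and is therefore reserved for recordings of up to a
  few thousand neurons; larger data should supply a donor `W`.
* **Transfer-style slow weights.** `W` moves at
  `w_learning_rate_factor = 1e-2` times the learning rate, whether it came
  from a donor checkpoint or from the warm start, with an L1 penalty
  available (`l1_weight`; `1e-6` is the regime used on real recordings).
  Freezing the assembly structure while `U` and the biases train at the
  full rate is the same transfer-learning scheme used to carry
  compositional-RBM assemblies into the RTRBM, and we found it equally
  necessary de novo: with `W` fully free, CD training degrades the
  assembly structure faster than `U` converges. Training started at the
  generative parameters of the simulator stays there (aligned-`U` cosine
  ~1.0), so the restriction loses nothing at the optimum.
* **Negative phase.** Default is the standard CD Gibbs chain started at
  the data (`cd_steps = 1` suffices for likelihood fitting). The
  alternative `negative_phase = "mean_field"` runs damped mean-field
  iterations from a neutral visible state — a deterministic negative phase
  that must regenerate each frame from the temporal bias alone, which
  produces temporal weights of functional (generative) scale and is what
  the down-sampling scan uses.
* **Budget.** `n_updates` fixes the total number of parameter updates
  irrespective of data length — the "equal gradient-update budget" needed
  when comparing models across down-sampling rates. Desk-scale experiments
  in the tests use 2000-5000 updates on 5000-step simulations (seconds to
  tens of seconds per model); real-recording settings (10,000 epochs,
  learning rate 1e-3) are config-level choices, not code changes.

## The simulator

`simulate_assemblies()` generates ground truth for parameter-recovery and
timescale experiments. `Nh = 10` assemblies each drive
`Nv_per_assembly = 20` neurons. Per assembly, two bump trains (inter-peak
intervals uniform on [5, 10] steps, unit-sum Gaussian kernels with widths
uniform on [0.1, 0.5] steps — effectively near-delta pulses) are min-max
scaled to [0, fmax/10] and [0, fmax] (`fmax = 0.8`) and summed into the
intrinsic rate. Assemblies interact at delay `delta_tA` through
`lambda_i(t) = phi(lambda_init_i(t) + sum_j U[i,j] lambda_j(t - delta_tA))`
with `phi` clamping to `[0, 3 fmax]` (a Gaussian-CDF squashing alternative
sits behind `limiter = "gauss_cdf"`; clamping is the default because the
limiter is described as a range restriction). Each neuron observes its
assembly's rate through an independent Poisson count with a per-neuron
scale uniform on [0.6, 1.4], binarized as count >= 1 because the model's
visible units are binary; the first 25 burn-in columns are dropped.

The default interaction matrix (`default_U()`) excites each assembly's
cyclic successor and inhibits its predecessor at magnitude 1.0, which
makes the interactions — not the intrinsic bumps — the main driver of
activity: pulses travel around the assembly ring as sequences (mean
activity ~0.34, driver-to-target correlation ~0.96 at the interaction
delay, ~0 at lag zero). The inhibit-the-predecessor motif matters: wiring
the inhibition two steps ahead instead collapses the delay-1 dynamics into
a two-phase standing wave in which same-phase assemblies have identical
trajectories and `U` is unidentifiable.

What the generator does *not* emulate: calcium-indicator dynamics and
deconvolution artifacts, neuron-specific noise correlations, multiple or
graded interaction timescales, and non-stationarity. Passing recovery
tests on this generator therefore demonstrates correctness of the
estimation machinery, not performance on fluorescence data.

## Alignment and evaluation

Trained hidden units are matched to ground-truth assemblies by mean
absolute weight (`match_assemblies()`), greedily in order of match
strength; negative-mean matches are inverse codes and flip the sign of
their row and column of `U` (`align_U()`), two inversions cancelling on
the mutual weights. `cosine_similarity_U()` compares z-scored (population
normalization) flattened matrices.

Prediction quality is scored by rolling the model forward from an
observed state and normalizing the mean squared error (`nmse()`). Two
rollout mechanisms are available: Gibbs chains (`rollout = "gibbs"`, the
classic sequential inference scheme) and per-step damped mean-field
inference from a neutral visible state (`rollout = "mean_field"`). The
mean-field rollout is deterministic and is the same fixed point that
`negative_phase = "mean_field"` trains against, so it is the calibrated
inference for models trained that way; Gibbs rollouts of lightly trained
models suffer from the thermalization problem described under Known
limitations. The normalization is:

    nMSE = (MSE - MSEvar) / (MSEnaive - MSEvar)

`MSEnaive = mean(2 p (1 - p))` is the exact error of the unbiased
stochastic estimator that draws each unit at its mean rate;
`MSEvar` (`lower_bound_mse()`) is an empirical bound from the generator
itself: known assembly states are propagated one interaction delay, paired
with independent intrinsic-rate draws, Poisson-observed twice, and the
paired observations compared. Two evaluation conventions are exposed
because they answer different questions. `estimator = "sample"` scores a
sampled binary prediction — the same stochastic class as both bounds, so a
structureless model lands at nMSE = 1 exactly (the test suite asserts
this, and asserts MSE = MAE = 1 - accuracy on every call).
`estimator = "mean"` (the across-chain mean probability) is a
deterministic estimator whose baseline is `mean(p(1-p))` — half the naive
bound — so its nMSE values are not anchored at 1 and can even drop below
0 (a deterministic estimator does not pay the observation noise twice the
way every estimator in the stochastic class must); it is the
lower-variance choice for *paired* comparisons of models or rates on
common data, and is the default of both `prediction_mse()` and the
timescale scan. Bound-ordering statements (`MSEvar <= MSE <= MSEnaive`)
are meaningful only in the sampled class.

Before any rollout, the mean-field state is warmed up by running the
observed recursion over 8 context columns. Initializing from a single
column through the `binit` branch is unreliable: `binit` receives 1/16 of
the bias training signal and a single stray spike can saturate a hidden
unit, which poisons the first prediction step.

Model-vs-data statistics (`compute_moments()`, `sample_model_moments()`)
follow the convention that hidden moments use mean-field traces, and model
statistics are Gibbs-sampled from chains started at random test columns
(defaults 100 chains of 20 recorded steps, 15 sweeps apart, after a 4000
sweep burn-in; tests use shorter burn-ins at their smaller model sizes).
Significance machinery: Spearman correlations per non-overlapping neuron
subset with mean +/- 2 SD intervals (`bootstrap_model_comparison()`), and
the standard tests (Mann-Whitney, Wilcoxon, per-horizon t-tests with
Bonferroni factor equal to the number of horizons, two-way ANOVA) behind
`model_comparison_tests()`.

## Timescale identification

When the sampling interval does not match the assembly interaction delay,
the single-step `U` cannot represent the interactions. `timescale_scan()`
decimates the data at each candidate rate (`downsample_raster()` keeps
every k-th column; no averaging, mirroring plane-by-plane imaging), trains
one RTRBM per rate and run under an identical update budget, and scores
one-step-ahead nMSE on a single shared held-out dataset plus the cosine
similarity of the aligned `U`. The scan trains with the mean-field
negative phase: Gibbs-CD models recover the *pattern* of `U` at the
matching rate (cosine ~0.78) but leave its functional scale too weak for
free-running prediction, so their nMSE dip is shallow and partially
commensurable rates — which admit indirect prediction through the
recurrent memory — crowd the minimum. Mean-field-trained models, scored with
the matching mean-field rollout, both align better (cosine ~0.86) and
separate cleanly (desk scale: mean-estimator nMSE around 0 at the
matching rate versus ~0.45-0.55 elsewhere), because the neutral negative
phase demands that each step be reproducible from the temporal bias
alone. The scan's scale-free cosine signature peaks at the matching rate
under either training mode.

## Numerical choices and degenerate inputs

Conditionals go through a numerically stable sigmoid and log-partition
sums through log-sum-exp / softplus; `exact_partition()` enumerates only
the visible side and refuses models beyond `Nv + Nh = 24`. Always-on or
always-off neurons train as-is but are flagged on the training log. All
stochastic entry points take explicit seeds and restore the caller's RNG
state; equal seeds give bit-identical runs. Ties: assembly matching breaks
by descending score then lowest index; proportional weight thresholding
includes the lower neuron index first; Spearman uses average ranks. The
L1 subgradient at exactly zero weights is taken as 0.

## Known limitations

* Gibbs-CD training systematically underestimates the *scale* of `U`
  relative to the generative parameters (the pattern is recovered, hence
  high cosine after z-scoring): the teacher-forced negative phase stays
  close to the data, so the pressure to enlarge `U` fades once the K-step
  chain stops drifting, and larger CD-K raises the equilibrium scale only
  slowly. The mean-field negative phase (`negative_phase = "mean_field"`)
  mitigates this, but even so free-running prediction stays well above
  the variance-limited bound.
* For the same reason, *thermalized* sampling from desk-scale models runs
  hot: given enough Gibbs sweeps, the learned conditionals co-activate
  most assemblies, because the local negative phases never constrain the
  stationary distribution far from the data. Anchored, prediction-style
  evaluation (short chains from observed states) is reliable; long-run
  moment sampling from lightly trained models is not, and the
  model-vs-data moment machinery is therefore most meaningful for
  well-converged models.
* A single interaction delay is assumed throughout; mixed timescales
  alias into whichever sampling rate is scanned.
* The assembly warm start assumes assemblies are disjoint neuron groups
  with correlated activity; overlapping assemblies need a donor `W` from a
  model that can represent overlap.
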