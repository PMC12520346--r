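---
title: "Methods: E/I rate RNNs for multisensory decision making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: E/I rate RNNs for multisensory decision making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
# Heavy chunks (full-size training, ensembles) are shown but not evaluated so
# the vignette builds quickly; every command is the exact call used in the
# analyses and tests.
run_heavy <- identical(Sys.getenv("DALERNN_VIGNETTE_HEAVY"), "true")
```

```{r setup}
library(dalernn)
```

This vignette documents the modelling pipeline implemented by `dalernn`:
a rate-discrimination task generator, Dale-constrained excitatory/inhibitory
(E/I) rate networks trained by backpropagation through time, behavioral
readouts (psychometric, chronometric, strategy labels), single-unit
selectivity classification, perturbation experiments, permutation statistics,
and a GLM-HMM for latent behavioral states. The guiding idea is that an
ensemble of networks differing only in their random initialization behaves
like a population of individual subjects, whose behavioral variability can be
related to circuit composition.

## 1. The task

Each trial is 100 ms of fixation followed by 1000 ms of stimulus, simulated
at `dt_ms` resolution (20 ms during training, 2 ms for evaluation). The
network receives five input channels: visual-positive, visual-negative,
auditory-positive, auditory-negative, and a multisensory cue that switches
from 0 to `cue_amp` when both modalities are presented. A trial presents a
pulse frequency `f` drawn from the integers 9–16 Hz in one of three modality
conditions (visual, auditory, multisensory), 24 conditions total, and the
network must report whether `f` exceeds the 12.5 Hz threshold.

Frequency is encoded as a pair of opposed step currents per modality: the
positive channel steps to `(f - 9)/7` and the negative channel to
`1 - (f - 9)/7`, on top of a `u0 = 0.2` baseline common to all four tuned
channels. Independent Gaussian noise with variance `2 * alpha * sigma_in^2`
scaled by `1/alpha` (where `alpha = dt/tau`) is added per channel and
timestep, and inputs are rectified.

```{r}
task <- task_config()
task
b <- make_batch(task, n_trials = 4, seed = 1)
b
dim(b$inputs)    # channels x trials x timesteps
```

Targets are defined on two output channels (low/high): both sit at 0.2
during fixation, and after stimulus onset the correct channel ramps to 1.0
while the other stays at 0.2. A 200 ms grace period after onset is excluded
from the loss mask, so the network is not penalized while evidence is still
accumulating.

Task configurations round-trip through YAML (`write_task_config()` /
`read_task_config()`), and `export_condition_manifest()` writes a per-trial
CSV manifest of a generated batch.

## 2. The network

The model is a discrete-time rate RNN with `N = 150` units, 80% excitatory:

```
x_t = (1 - alpha) x_{t-1}
      + alpha (W_rec r_{t-1} + b_rec + W_in u_t + b_inp)
      + sqrt(2 alpha sigma_rec^2) * xi_t
r_t = max(x_t, 0)
z_t = W_out r_t[exc] + b_out
```

with `tau = 100` ms, `sigma_rec = 0.15`, and the readout drawing only from
excitatory units. Dale's law is enforced structurally: after initialization
(uniform `U(-k, k)`, `k = 1/sqrt(fan_in)`) recurrent weights are replaced by
their absolute value times a column sign (+1 for excitatory, -1 for
inhibitory presynaptic units), and inhibitory columns are scaled by 6 to
balance the 4:1 E/I ratio. The same projection (`dale_projection()`) is
re-applied after every gradient update, so sign structure is an invariant of
training, checkable at any time with `dale_compliant()`.

```{r}
p <- init_network(seed = 1, N = 150)
p
dale_compliant(p)
```

The forward pass, BPTT gradients and the training loop are implemented in
C++ (Rcpp/RcppArmadillo); `rnn_step()` and `readout()` expose a pure-R
single-step reference used by the tests to pin down the compiled recurrence
exactly.

## 3. Training

`dale_rnn()` is the front-door fitter: it initializes a network from a seed
and trains it with plain SGD (`lr = 0.01`), decoupled weight decay
(`weight_decay = 0.1`, applied to `W_rec` and the biases; for plain SGD the
decoupled and coupled conventions coincide), and fresh batches of 20 trials
per epoch. Only `W_rec`, `b_rec`, `b_inp`, `b_out` are trained; `W_in` and
`W_out` (`U(0, 0.01)`) stay frozen. Every 500 epochs the network is
validated on 1024 fresh trials; training stops when at least 90% of trials
produce a valid decision and at least 80% of valid trials are correct, or
after 10,000 epochs.

### Loss reduction

The reported loss is the masked mean squared error over trials, timepoints
and outputs (`compute_loss()`), plus an L2 penalty on the trained
parameters. For the *optimizer*, the reduction over time matters a great
deal at this parameter scale: with the per-element mean, the task gradient
reaching `W_rec` is of order `1e-5` (the output error is attenuated through
the frozen `W_out ~ U(0, 0.01)`), while the weight-decay pull `lambda *
W_rec` is of order `4e-3`. The decay term then dominates every update and
the network converges to emitting the target mean on both outputs without
ever discriminating — verified over 10,000 epochs with gradients checked
against finite differences.

`train_config(loss_reduction = "time_sum")` (the default) therefore has the
optimizer minimize the masked error averaged over trials and outputs but
*summed* over timepoints — exactly the mean-loss gradient scaled by the
number of timesteps (55 at `dt = 20` ms). With this convention and the
hyperparameters above unchanged, networks reach criterion in roughly
500–2000 epochs. A twice-larger scale oscillates and can diverge; the
per-element mean (`loss_reduction = "elementwise_mean"`) never learns. The
training history always records the per-element mean, so reported losses
are comparable across reductions.

```{r, eval = run_heavy}
fit <- dale_rnn(seed = 1)
fit
summary(fit)
```

A full-size fit converges in well under a minute of CPU time. The returned
object supports the usual verbs: `coef()` (all six parameter arrays),
`simulate()` (fresh trial records at any `dt_ms`), `predict()` (a decision
table), and `plot()` (psychometric points). Checkpoints round-trip through
JSON bit-exactly via `save_network()` / `load_network()`, which together
with `write_task_config()` and the training history give a fully scripted
train-and-save path (see `scripts/acceptance.R` for a complete example run
with `Rscript`).

## 4. Behavior

A decision is read out from the output time series as the first
post-onset timestep at which `|z_high - z_low| > 0.2`. Crossings before
stimulus onset invalidate the trial (`invalid_pre_stimulus`); trials that
never cross are `no_decision`. Reaction time is measured from stimulus
onset to the crossing, plus a fixed 200 ms non-decision offset.
`decision_table()` applies this to a whole batch of simulated trials.

`behavior_summary()` aggregates a decision table into:

- psychometric points — fraction of high choices per signed stimulus
  strength `x = f - 12.5`, valid trials only — fitted with the 2-parameter
  sigmoid `1 / (1 + exp(-a (x - b)))` by bounded Levenberg–Marquardt
  (`fit_sigmoid()`; `fit_sigmoid_lapse()` adds left/right lapse rates);
- chronometric points — mean RT per `|x|`, correct trials only — and the
  overall mean RT (`mean_rt()`).

Across an ensemble, `label_strategies()` splits networks into fast/slow
(mean RT strictly below the ensemble mean) and accurate/inaccurate
(psychometric slope strictly above the mean), yielding four strategy groups.

```{r, eval = run_heavy}
beh <- behavior_summary(decision_table(simulate(fit, nsim = 2048, seed = 42,
                                                dt_ms = 2)))
beh
```

## 5. Single-unit selectivity

`condition_rates()` simulates correct unimodal trials at `dt = 2` ms and
averages each unit's rate over the final 20 timepoints of the stimulus in
each of the four condition cells (auditory/visual x low/high), along with
its maximal fixation-period rate. `classify_rate_based()` then labels each
unit by a fixed precedence:

1. **silent** — all four condition rates below the fixation maximum;
2. **hyper** — exactly three below (hyper-selective for the remaining one);
3. **modality** or **choice** — both conditions on one side of an axis
   strictly above both on the other; if both axes separate, the larger mean
   difference wins;
4. **mixed** — one axis separates and the orthogonal difference exceeds the
   gap between the 2nd and 3rd ranked rates;
5. **unclassified** otherwise.

`classify_roc()` provides an independent ROC-based alternative
(Mann–Whitney AUC for choice and modality against shuffle nulls, 2.5%
tails). `selectivity_table()` and `count_by_group()` tabulate labels by E/I
identity. The rate-based rule is deliberately simple enough to transcribe
by hand; the test suite checks the implementation against a brute-force
oracle over a grid of rate patterns.

## 6. Perturbations

`perturbation_experiment()` compares a baseline arm against a perturbed arm
on *identical* stimuli and shared recurrent noise, so differences are
attributable to the manipulation alone:

- `mode = "modulate"` — an extra current `alpha * b_per` (`b_per = 0.2`)
  plus private noise (`sigma_per = 0.01`, independent stream) injected into
  a target set of units inside the integration bracket;
- `mode = "lesion"` — the target units' rates are clamped to 0.

`resolve_target()` maps named groups (`"inhibitory"`, `"excitatory"`,
`"all"`, or a selectivity label such as `"choice"`) to unit indices using a
selectivity table. `compare_conditions()` summarizes RT and accuracy deltas
and classifies the outcome per network.

## 7. Statistics

- `perm_test_independent()` / `perm_test_paired()` — difference-in-means
  permutation tests that enumerate *exactly* (all `choose(n1+n2, n1)`
  splits, or all `2^n` sign flips) whenever the arrangement count fits in
  the resample budget, and otherwise use Monte Carlo with the unbiased
  `(k+1)/(n+1)` estimator;
- `holm_bonferroni()` — Holm step-down adjustment (wraps
  `stats::p.adjust`);
- `pearson_correlation()` / `rank_correlation()` — `cor.test` wrappers
  returning estimate, p-value and n;
- `pca_trajectories()` — PCA (via `prcomp`) of trial-averaged population
  rates for the six modality-by-choice conditions, returning 3-component
  trajectories.

## 8. Ensembles

`run_ensemble()` runs the full pipeline over `n_networks` seeds derived
from a master seed: train to criterion, evaluate at `dt = 2` ms, fit
behavior, classify selectivity, then compute the group-level results —
multisensory versus unisensory slope and RT effects (paired permutation
tests, Holm-corrected; `modality_effects()`), the speed–accuracy
correlation across networks (Pearson, psychometric slope versus mean RT),
and Spearman correlations between per-network selectivity counts and
behavior. JSON checkpointing makes long runs resumable.

```{r, eval = run_heavy}
ens <- run_ensemble(n_networks = 20, master_seed = 1)
ens
```

`threshold_sweep()` re-extracts decisions at a range of decision thresholds
from one set of simulated trials per network, showing how the
valid/no-decision split depends on the threshold choice.

## 9. Latent behavioral states

`glmhmm()` fits a hidden Markov model whose per-state emissions are
logistic regressions of the binary choice on (signed stimulus, bias),
estimated by MAP-EM with a sticky Dirichlet prior on transition rows
(`alpha = 1`, `kappa = 10`) and a Gaussian prior (sd 2) on weights, with
random restarts. `glmhmm_data()` builds covariates from a decision table
(valid trials only), `posterior_states()` returns smoothed state
probabilities, and `glmhmm_loglik_bruteforce()` verifies the forward
algorithm by exhaustive path enumeration on short sequences.

```{r}
par <- list(A = matrix(c(0.95, 0.03, 0.02,
                         0.04, 0.92, 0.04,
                         0.03, 0.03, 0.94), 3, 3, byrow = TRUE),
            w = rbind(c(4, 0), c(0.1, 0), c(0.5, 2.5)),
            pi = c(1, 0, 0))
X <- cbind(stimulus = runif(2000, -3.5, 3.5) / 3.5, bias = 1)
sim <- simulate_glmhmm(par, X, seed = 9)
fit3 <- glmhmm(sim$choices, X, K = 3, n_starts = 3, max_iter = 50, seed = 4)
round(fit3$w, 2)
```

## 10. Reproducibility

All stochastic components draw from seeds derived deterministically via
`derive_seed(seed, stream)`, so sub-streams (trial conditions, input noise,
recurrent noise, validation sets, perturbation noise, EM restarts) are
independent yet fully reproducible: the same master seed always yields the
same ensemble, bit for bit. `scripts/acceptance.R` demonstrates an
end-to-end scripted run:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which trains a network from scratch, validates it at the training
resolution and at `dt = 2` ms, and writes the resulting fractions as JSON.
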