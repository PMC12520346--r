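# dalernn

Ensembles of Dale-constrained excitatory/inhibitory rate recurrent neural
networks, trained on a multisensory rate-discrimination task and analyzed
as a population of individual "subjects".

## Science

Individuals trained on the same perceptual task arrive at different
behavioral strategies: some respond fast, some respond accurately, few do
both. This package studies that variability in a fully controlled setting.
Many recurrent networks — identical in architecture, task, and training
procedure, differing only in their random initialization — are trained on
the same audiovisual rate-discrimination task. Each network sees a 100 ms
fixation period followed by a 1000 ms noisy step-current stimulus encoding
a pulse frequency (9–16 Hz) in the visual modality, the auditory modality,
or both, and must report through two output channels whether the frequency
exceeds 12.5 Hz. A decision is the first post-onset moment the two outputs
separate by more than 0.2; the time of that separation is the network's
reaction time.

The networks obey Dale's law — 120 excitatory and 30 inhibitory units whose
outgoing sign is fixed throughout training — and are trained by
backpropagation through time with plain SGD and weight decay, with only the
recurrent weights and biases plastic. Trained networks vary widely in
psychometric slope (accuracy) and mean reaction time (speed), and that
behavioral variability is systematically related to circuit composition:

- **multisensory benefit** — networks are both more sensitive and faster
  when both modalities are presented than with either alone;
- **speed–accuracy relationship** — across an ensemble, steeper
  psychometric slopes go with *faster* responses, not slower ones;
- **selectivity composition predicts behavior** — counting units by a
  rate-based selectivity classification (choice-selective, modality-selective,
  mixed, silent, hyper-selective), networks with more choice and mixed units
  are faster, and networks with more silent units are slower but more
  accurate;
- **causal role of inhibition** — injecting a small excitatory current into
  inhibitory units slows decisions, while stimulating excitatory or
  selective subpopulations speeds them up (paired permutation tests on
  identical stimulus sets).

Latent behavioral states (engaged / disengaged / biased) can additionally be
inferred from choice sequences with a GLM-HMM fitted by MAP-EM.

## Worked example

Train one network to criterion (about half a minute of CPU time), then look
at its behavior. All output below is real.

```r
library(dalernn)

fit <- dale_rnn(seed = 1)
fit
#> Dale-constrained rate RNN (150 neurons, seed 1)
#>   converged after 1000 epochs
#>   final validation: 98.4% valid, 97.9% correct (loss 0.0848)

summary(fit)
#> Dale-constrained rate RNN (150 neurons, seed 1)
#>   converged after 1000 epochs
#>   final validation: 98.4% valid, 97.9% correct (loss 0.0848)
#>
#> Validation history:
#>  epoch       loss valid_frac correct_frac
#>    500 0.09950614  0.6054688    0.8419355
#>   1000 0.08481467  0.9843750    0.9791667
#>
#> Recurrent weights: 0.019 (mean |exc|), 0.0917 (mean |inh|)
```

The trained network generalizes from the 20 ms training resolution to a
2 ms simulation step. Simulate fresh trials at high resolution and
summarize behavior:

```r
rec <- simulate(fit, nsim = 2048, seed = 42, dt_ms = 2)
beh <- behavior_summary(decision_table(rec))
beh
#> Behavioral summary over 2048 trials (99.1% valid)
#>   pooled: slope 6.881, bias 0.305 Hz, mean RT 539 ms
#>   visual:       slope 17.120, bias +0.457 Hz, mean RT 571 ms
#>   auditory:     slope 5.536, bias +0.286 Hz, mean RT 569 ms
#>   multisensory: slope 18.908, bias +0.334 Hz, mean RT 484 ms
```

This single network already shows the multisensory benefit: the
multisensory psychometric slope is the steepest and the multisensory mean
RT is ~85 ms faster than either unisensory condition.

Classify its units by selectivity:

```r
cr <- condition_rates(fit, n_trials = 1024, seed = 3)
count_by_group(selectivity_table(cr))
#>                excitatory inhibitory
#>   modality              0          1
#>   choice               75         21
#>   mixed                 1          0
#>   silent               38          7
#>   hyper                 6          0
#>   unclassified          0          1
#>   unselective           0          0
```

For population-level results, `run_ensemble()` trains many seeds and
computes the modality effects, the speed–accuracy correlation, and the
selectivity-count correlations in one call:

```r
ens <- run_ensemble(n_networks = 20, master_seed = 1,
                    checkpoint_dir = "ckpts")   # resumable
ens
```

Perturbation experiments compare paired arms on identical stimuli:

```r
px <- perturbation_experiment(fit, group = "inhibitory", mode = "modulate",
                              n_trials = 512, seed = 5, dt_ms = 2)
px   # baseline vs perturbed behavior, RT and accuracy deltas
```

## Reproduction

`scripts/acceptance.R` retrains a network from scratch against the
*installed* package and writes headline numbers as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

It reports `t1`/`t2` (valid and correct percentages on a fresh 1024-trial
validation set at the training resolution) and `t3` (valid fraction over
8192 trials at `dt = 2` ms). The run takes about a minute on one CPU.

The test suite (testthat, `tests/testthat/`) covers each module against
independent oracles — finite-difference gradient checks, a brute-force
selectivity classifier, exact permutation enumeration, hand-computed
Holm corrections, sigmoid and GLM-HMM parameter recovery — plus an
acceptance file that retrains a 12-network ensemble and checks the
population-level results above end to end:

```sh
Rscript -e 'testthat::test_dir("tests/testthat")'
```

The full suite trains networks from scratch and takes roughly 15–20
minutes on one CPU.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the task
generator, network equations, training procedure (including why the
optimizer uses a sum-over-time loss reduction while reported losses remain
per-element means), behavioral readouts, selectivity rules, perturbation
design, statistics, and the GLM-HMM. Every exported function has a help
page (`?dale_rnn`, `?run_ensemble`, ...).
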