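#' Configuration of the multisensory rate-discrimination task
#'
#' The task presents a noisy step-current stimulus whose amplitude encodes a
#' pulse frequency between `f_min` and `f_max` Hz in one or both sensory
#' modalities (visual, auditory). After a fixation epoch with no stimulus
#' drive, the stimulus is shown for `stimulus_ms` and the network must report
#' whether the frequency is above or below `f_threshold` by separating its two
#' output variables. Inputs are carried by four tuned channels
#' (visual +/-, auditory +/-) plus an optional stimulus-onset cue channel, and
#' every channel is baseline-shifted by `u0`, corrupted by Gaussian noise with
#' scale `(1/alpha) * sqrt(2 * alpha * sigma_in^2)` (`alpha = dt/tau`), and
#' rectified so inputs are non-negative.
#'
#' @param f_min,f_max Lowest and highest pulse frequency (Hz). Trials sample
#'   the integer frequencies in `f_min:f_max`.
#' @param f_threshold Category boundary (Hz); `high` trials have
#'   `frequency > f_threshold`.
#' @param fixation_ms,stimulus_ms Epoch durations (ms); both must be exact
#'   multiples of `dt_ms`.
#' @param dt_ms Simulation timestep (ms); 20 during training, 2 at test.
#' @param u0 Baseline input amplitude (arbitrary units).
#' @param sigma_in Input noise scale.
#' @param n_input_channels Number of input channels (4 tuned + 1 cue).
#' @param target_low,target_high Output targets during fixation/stimulus.
#' @param grace_ms Window after stimulus onset excluded from the training
#'   loss, so the network is not punished for finite processing time.
#' @param gain Gain of the linear frequency-to-amplitude code.
#' @param cue_on Whether channel 5 carries a stimulus-on cue.
#' @param cue_amp Amplitude of the cue channel during the stimulus.
#'
#' @return An object of class `"task_config"`.
#' @examples
#' cfg <- task_config()
#' n_timesteps(cfg)   # 55 at dt = 20 ms
#' @export
task_config <- function(f_min = 9, f_max = 16, f_threshold = 12.5,
                        fixation_ms = 100, stimulus_ms = 1000, dt_ms = 20,
                        u0 = 0.2, sigma_in = 0.01, n_input_channels = 5,
                        target_low = 0.2, target_high = 1.0, grace_ms = 200,
                        gain = 1.0, cue_on = TRUE, cue_amp = 1.0) {
  if (!(f_min < f_threshold && f_threshold < f_max))
    stop("need f_min < f_threshold < f_max")
  if (fixation_ms %% dt_ms != 0 || stimulus_ms %% dt_ms != 0)
    stop("fixation_ms and stimulus_ms must be exact multiples of dt_ms")
  if (u0 < 0) stop("u0 must be >= 0")
  if (grace_ms > stimulus_ms) stop("grace_ms must not exceed stimulus_ms")
  if (grace_ms %% dt_ms != 0) stop("grace_ms must be a multiple of dt_ms")
  if (!n_input_channels %in% c(4, 5))
    stop("n_input_channels must be 4 (tuned only) or 5 (tuned + cue)")
  structure(list(f_min = f_min, f_max = f_max, f_threshold = f_threshold,
                 fixation_ms = fixation_ms, stimulus_ms = stimulus_ms,
                 dt_ms = dt_ms, u0 = u0, sigma_in = sigma_in,
                 n_input_channels = n_input_channels, target_low = target_low,
                 target_high = target_high, grace_ms = grace_ms, gain = gain,
                 cue_on = cue_on && n_input_channels == 5, cue_amp = cue_amp),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Multisensory discrimination task\n")
  cat(sprintf("  frequencies %g-%g Hz, threshold %g Hz\n",
              x$f_min, x$f_max, x$f_threshold))
  cat(sprintf("  fixation %g ms + stimulus %g ms at dt = %g ms (%d steps)\n",
              x$fixation_ms, x$stimulus_ms, x$dt_ms, n_timesteps(x)))
  cat(sprintf("  u0 = %g, sigma_in = %g, %d input channels%s\n", x$u0,
              x$sigma_in, x$n_input_channels,
              if (x$cue_on) " (incl. stimulus cue)" else ""))
  invisible(x)
}

#' Trial geometry helpers
#'
#' `n_timesteps()` returns the total number of simulation steps of a trial;
#' `onset_index()` the number of fixation steps, i.e. the 0-based index of the
#' first stimulus step (1-based steps `1:onset_index(cfg)` are fixation).
#'
#' @param config A [task_config()].
#' @param dt_ms Optional timestep override (ms).
#' @return Integer count.
#' @export
n_timesteps <- function(config, dt_ms = config$dt_ms) {
  as.integer((config$fixation_ms + config$stimulus_ms) / dt_ms)
}

#' @rdname n_timesteps
#' @export
onset_index <- function(config, dt_ms = config$dt_ms) {
  as.integer(config$fixation_ms / dt_ms)
}

#' Linear frequency-to-amplitude code
#'
#' Maps a pulse frequency to the amplitudes of the positively and negatively
#' tuned input channels of its modality: the positive channel grows linearly
#' from 0 at `f_min` to `gain` at `f_max`, the negative channel mirrors it.
#'
#' @param frequency Frequency in Hz, within `[f_min, f_max]`.
#' @param config A [task_config()].
#' @return Named numeric vector `c(amp_pos, amp_neg)`.
#' @examples
#' encode_frequency(9, task_config())    # c(0, 1)
#' encode_frequency(12.5, task_config()) # c(0.5, 0.5)
#' @export
encode_frequency <- function(frequency, config = task_config()) {
  if (any(frequency < config$f_min | frequency > config$f_max))
    stop("frequency outside [f_min, f_max]")
  p <- config$gain * (frequency - config$f_min) / (config$f_max - config$f_min)
  c(amp_pos = p, amp_neg = config$gain - p)
}

# Deterministic per-trial targets (2 x n x T) and shared loss mask (length T).
make_targets <- function(config, frequency, dt_ms = config$dt_ms) {
  T_all <- n_timesteps(config, dt_ms)
  t_fix <- onset_index(config, dt_ms)
  n <- length(frequency)
  targ <- array(config$target_low, dim = c(2, n, T_all))
  hi <- frequency > config$f_threshold
  for (t in seq(t_fix + 1, T_all)) {
    targ[1, !hi, t] <- config$target_high
    targ[2, hi, t] <- config$target_high
  }
  mask <- rep(1, T_all)
  grace <- config$grace_ms / dt_ms
  if (grace > 0) mask[t_fix + seq_len(grace)] <- 0
  list(targets = targ, loss_mask = mask)
}

#' Generate a batch of task trials
#'
#' Samples `n_trials` conditions with equal probability over the 3 modalities
#' x 8 frequencies grid (unless `modality`/`frequency` are given), then
#' synthesizes the noisy rectified step-current inputs, output targets and
#' loss masks. On multisensory trials both modalities carry the same
#' (congruent) frequency.
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; identical seeds give identical batches.
#' @param modality,frequency Optional fixed conditions, recycled to
#'   `n_trials`. Modality is one of `"visual"`, `"auditory"`,
#'   `"multisensory"`.
#' @param dt_ms Timestep override (ms), e.g. 2 for test-resolution batches.
#' @param tau_ms Network time constant (ms); enters the input noise only
#'   through `alpha = dt/tau`.
#' @return An object of class `"trial_batch"`: inputs as a
#'   `channels x trials x time` array, targets `2 x trials x time`, the loss
#'   mask, condition labels, and bookkeeping (seed, config, condition counts).
#' @examples
#' b <- make_batch(task_config(), 10, seed = 1)
#' b$condition_counts
#' @export
make_batch <- function(config, n_trials, seed, modality = NULL,
                       frequency = NULL, dt_ms = config$dt_ms, tau_ms = 100) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  set.seed(derive_seed(seed, "conditions"))
  mods <- c("visual", "auditory", "multisensory")
  if (is.null(modality)) {
    modality <- sample(mods, n_trials, replace = TRUE)
  } else {
    modality <- rep(match.arg(modality, mods, several.ok = TRUE),
                    length.out = n_trials)
  }
  if (is.null(frequency)) {
    frequency <- sample(config$f_min:config$f_max, n_trials, replace = TRUE)
  } else {
    frequency <- rep(frequency, length.out = n_trials)
    if (any(frequency < config$f_min | frequency > config$f_max))
      stop("frequency outside [f_min, f_max]")
  }
  alpha <- dt_ms / tau_ms
  inputs <- cpp_make_inputs(match(modality, mods) - 1L, frequency,
                            onset_index(config, dt_ms),
                            n_timesteps(config, dt_ms) - onset_index(config, dt_ms),
                            config$n_input_channels, alpha, config$u0,
                            config$sigma_in, config$gain, config$cue_on,
                            config$cue_amp, config$f_min, config$f_max,
                            derive_seed(seed, "inputs"))
  tg <- make_targets(config, frequency, dt_ms)
  structure(list(inputs = inputs, targets = tg$targets,
                 loss_mask = tg$loss_mask, modality = modality,
                 frequency = frequency,
                 correct_choice = ifelse(frequency > config$f_threshold,
                                         "high", "low"),
                 onset_index = onset_index(config, dt_ms),
                 n_trials = n_trials, dt_ms = dt_ms, seed = seed,
                 config = config,
                 condition_counts = table(modality = modality,
                                          frequency = frequency)),
            class = "trial_batch")
}

#' @export
print.trial_batch <- function(x, ...) {
  cat(sprintf("Trial batch: %d trials, %d steps at dt = %g ms (seed %s)\n",
              x$n_trials, dim(x$inputs)[3], x$dt_ms, format(x$seed)))
  print(x$condition_counts)
  invisible(x)
}

#' Generate a single trial
#'
#' Convenience wrapper around [make_batch()] for one fixed condition,
#' returning matrices in `time x channel` orientation.
#'
#' @inheritParams make_batch
#' @param modality One of `"visual"`, `"auditory"`, `"multisensory"`.
#' @param frequency Frequency in Hz.
#' @return A list with elements `inputs` (`T x channels`), `targets`
#'   (`T x 2`), `loss_mask`, `onset_index`, `correct_choice`, `modality`,
#'   `frequency`.
#' @export
make_trial <- function(config, modality, frequency, seed,
                       dt_ms = config$dt_ms) {
  b <- make_batch(config, 1, seed, modality = modality, frequency = frequency,
                  dt_ms = dt_ms)
  list(inputs = t(b$inputs[, 1, ]), targets = t(b$targets[, 1, ]),
       loss_mask = b$loss_mask, onset_index = b$onset_index,
       correct_choice = b$correct_choice[1], modality = b$modality[1],
       frequency = b$frequency[1])
}

#' Read or write a task configuration as YAML
#'
#' @param path File path.
#' @param config A [task_config()].
#' @return `read_task_config()` returns a `task_config`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  do.call(task_config, yaml::read_yaml(path))
}

#' @rdname read_task_config
#' @export
write_task_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Export a batch's condition manifest
#'
#' Writes one row per trial (modality, frequency, correct choice) as CSV.
#'
#' @param batch A [make_batch()] result.
#' @param path Output CSV path.
#' @export
export_condition_manifest <- function(batch, path) {
  write.csv(data.frame(trial = seq_len(batch$n_trials),
                       modality = batch$modality,
                       frequency = batch$frequency,
                       correct_choice = batch$correct_choice),
            path, row.names = FALSE)
  invisible(path)
}
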