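#' Training configuration
#'
#' Hyperparameters of the BPTT/SGD training loop. Only `W_rec` and the three
#' bias vectors (`b_rec`, `b_inp`, `b_out`) are trained; input and output
#' weights stay frozen so the network must solve the task through its
#' recurrent connectivity. L2 regularization is applied as SGD weight decay
#' on the trainable parameters, and the Dale sign constraint is re-imposed by
#' projection (violating entries reset to zero) immediately after every
#' update. Training stops once a fresh validation batch has at least
#' `valid_criterion` valid trials and at least `correct_criterion` correct
#' choices among them, or after `max_epochs`.
#'
#' @param lr SGD learning rate.
#' @param weight_decay L2 weight-decay coefficient (added to the gradient as
#'   `lambda * theta`, the coupled convention of standard SGD optimizers).
#' @param batch_size Trials per gradient step; a fresh random batch is
#'   generated every epoch (Monte-Carlo cross-validation: no batch is ever
#'   reused).
#' @param max_epochs Training budget.
#' @param validate_every Epochs between validation checks.
#' @param validation_size Trials per validation batch.
#' @param valid_criterion,correct_criterion Stopping thresholds on the valid
#'   and correct fractions. A threshold of 0 is always satisfied (a network
#'   with no valid trials has a correct fraction of 0), which stops training
#'   at the first validation check — useful for fast smoke runs that only
#'   exercise the mechanics.
#' @param decision_threshold Output separation that registers a choice.
#' @param loss_reduction Reduction convention the optimizer sees.
#'   `"time_sum"` (default) averages the masked squared error over trials
#'   and outputs but sums over timepoints, so the gradient magnitude is
#'   independent of the trial length; `"elementwise_mean"` divides by
#'   `trials * timepoints * outputs` as well. With plain SGD at the default
#'   learning rate, the elementwise mean shrinks the task gradient on
#'   `W_rec` far below the weight-decay pull and the network converges to
#'   the target mean without ever discriminating; the time-summed reduction
#'   trains to criterion reliably, so it is the default. The reported
#'   history loss is always the elementwise mean of [compute_loss()], which
#'   is comparable across resolutions.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(lr = 0.01, weight_decay = 0.1, batch_size = 20,
                         max_epochs = 10000, validate_every = 500,
                         validation_size = 1024, valid_criterion = 0.9,
                         correct_criterion = 0.8, decision_threshold = 0.2,
                         loss_reduction = c("time_sum", "elementwise_mean")) {
  loss_reduction <- match.arg(loss_reduction)
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, max_epochs >= 1,
            validate_every >= 1, validation_size >= 1,
            valid_criterion >= 0, valid_criterion <= 1,
            correct_criterion >= 0, correct_criterion <= 1,
            decision_threshold > 0)
  structure(as.list(environment()), class = "train_config")
}

#' Masked mean-squared-error task loss
#'
#' Mean over trials, timepoints and the two outputs of the squared
#' target-output difference, with timepoints masked out of the loss (the
#' grace window after stimulus onset) contributing zero while the averaging
#' denominator stays `trials * timepoints * outputs`. When `params` and
#' `lambda` are supplied, the L2 penalty `lambda * sum(theta^2)` over the
#' trainable parameters is added (during training the equivalent pull toward
#' small parameters is applied as optimizer weight decay).
#'
#' @param outputs,targets Arrays `2 x trials x time` (a single `T x 2`
#'   matrix is also accepted for both).
#' @param mask Numeric 0/1 vector over timepoints.
#' @param params Optional `network_params` for the penalty term.
#' @param lambda L2 coefficient.
#' @return Scalar loss.
#' @export
compute_loss <- function(outputs, targets, mask, params = NULL, lambda = 0) {
  if (is.matrix(outputs)) {
    outputs <- array(t(outputs), dim = c(2, 1, nrow(outputs)))
    targets <- array(t(targets), dim = c(2, 1, nrow(targets)))
  }
  stopifnot(identical(dim(outputs), dim(targets)),
            length(mask) == dim(outputs)[3])
  sq <- (outputs - targets)^2
  m <- aperm(array(mask, dim = c(dim(outputs)[3], dim(outputs)[1:2])),
             c(2, 3, 1))
  loss <- sum(sq * m) / length(sq)
  if (!is.null(params) && lambda > 0)
    loss <- loss + lambda * (sum(params$W_rec^2) + sum(params$b_rec^2) +
                               sum(params$b_inp^2) + sum(params$b_out^2))
  loss
}

# Assemble the C++ task/train control lists for a given dt.
task_cpp_list <- function(task, dt_ms, tau_ms) {
  list(t_fix = onset_index(task, dt_ms),
       t_stim = n_timesteps(task, dt_ms) - onset_index(task, dt_ms),
       n_channels = task$n_input_channels,
       grace_steps = as.integer(task$grace_ms / dt_ms),
       alpha = dt_ms / tau_ms, u0 = task$u0, sigma_in = task$sigma_in,
       gain = task$gain, cue_on = task$cue_on, cue_amp = task$cue_amp,
       f_min = task$f_min, f_max = task$f_max, f_threshold = task$f_threshold,
       target_low = task$target_low, target_high = task$target_high)
}

#' Train a network in place
#'
#' Low-level trainer used by [dale_rnn()]: runs BPTT/SGD epochs on fresh
#' random batches at the training resolution until the stopping criterion or
#' the epoch budget is reached.
#'
#' @param params A [init_network()] result.
#' @param task A [task_config()] (its `dt_ms` is the training resolution).
#' @param control A [train_config()].
#' @param seed Integer seed driving batch sampling and all simulation noise.
#' @return A list: updated `params`, `converged`, `epochs_used`, and the
#'   validation `history` data frame.
#' @export
train_network <- function(params, task, control = train_config(), seed) {
  tl <- task_cpp_list(task, task$dt_ms, params$tau_ms)
  cl <- unclass(control)
  cl$sigma_rec <- params$sigma_rec
  cl$loss_scale <- if (control$loss_reduction == "time_sum")
    n_timesteps(task, task$dt_ms) else 1
  cl$valid_criterion <- control$valid_criterion
  cl$correct_criterion <- control$correct_criterion
  res <- cpp_train(params$W_in, params$W_rec, params$W_out, params$b_rec,
                   params$b_inp, params$b_out, params$n_exc,
                   isTRUE(params$dale), tl, cl, derive_seed(seed, "train"))
  if (isTRUE(res$diverged)) stop("training diverged (non-finite loss)")
  params$W_rec <- res$Wrec
  params$b_rec <- res$b_rec
  params$b_inp <- res$b_inp
  params$b_out <- res$b_out
  list(params = params, converged = res$converged,
       epochs_used = res$epochs_used, history = res$history)
}

#' Validate a network on a fresh batch
#'
#' Generates `n_trials` fresh trials, simulates them, and extracts decisions:
#' a trial is valid when no output crossing occurs before stimulus onset and
#' a decision is made during the stimulus; the correct fraction is computed
#' over valid trials only.
#'
#' @param params A `network_params` object (or a fitted [dale_rnn()]).
#' @param task A [task_config()].
#' @param n_trials Number of validation trials.
#' @param dt_ms Simulation timestep (ms).
#' @param seed Integer seed.
#' @param threshold Decision threshold.
#' @return List with `valid_fraction` and `correct_fraction`.
#' @export
validate_network <- function(params, task, n_trials = 1024,
                             dt_ms = task$dt_ms, seed = 1, threshold = 0.2) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (inherits(params, "dale_rnn")) params <- params$params
  batch <- make_batch(task, n_trials, derive_seed(seed, "valbatch"),
                      dt_ms = dt_ms, tau_ms = params$tau_ms)
  rec <- run_trials(params, batch, derive_seed(seed, "valnoise"))
  dec <- decision_table(rec, threshold = threshold)
  valid <- dec$status == "valid"
  list(valid_fraction = mean(valid),
       correct_fraction = if (any(valid))
         mean(dec$choice[valid] == batch$correct_choice[valid]) else NA_real_)
}

#' Fit a Dale-constrained rate RNN to the multisensory discrimination task
#'
#' The main model-fitting entry point: initializes an excitatory/inhibitory
#' rate network from `seed` and trains it by backpropagation through time
#' until it reaches the task criterion (at least 90% valid trials and 80%
#' correct choices on a fresh validation batch, by default) or exhausts the
#' epoch budget. Networks that fail to converge are returned with
#' `converged = FALSE` and are conventionally excluded from ensemble
#' statistics.
#'
#' @param task A [task_config()]; its `dt_ms` (20 ms by default) is the
#'   training resolution, while evaluation typically uses 2 ms.
#' @param control A [train_config()].
#' @param n_neurons,p_exc Network size and excitatory fraction.
#' @param sigma_rec Recurrent noise scale.
#' @param dale Impose Dale's law (`FALSE` gives the unconstrained control
#'   model: no sign structure, no inhibitory init scaling, no projection).
#' @param seed Integer seed covering initialization, batch sampling and
#'   simulation noise.
#' @return An object of class `"dale_rnn"` with components `params`
#'   (trained), `init` (the frozen initial parameters), `converged`,
#'   `epochs_used`, `history`, `task`, `control`, `seed`.
#' @examples
#' \donttest{
#' fit <- dale_rnn(n_neurons = 50, seed = 1,
#'                 control = train_config(max_epochs = 1000,
#'                                        validate_every = 250,
#'                                        validation_size = 256))
#' print(fit)
#' }
#' @export
dale_rnn <- function(task = task_config(), control = train_config(),
                     n_neurons = 150, p_exc = 0.8, sigma_rec = 0.15,
                     dale = TRUE, seed = 1) {
  params <- init_network(seed, N = n_neurons, p_exc = p_exc,
                         n_channels = task$n_input_channels,
                         sigma_rec = sigma_rec, dale = dale)
  init <- params
  tl <- task_cpp_list(task, task$dt_ms, params$tau_ms)
  cl <- unclass(control)
  cl$sigma_rec <- params$sigma_rec
  cl$loss_scale <- if (control$loss_reduction == "time_sum")
    n_timesteps(task, task$dt_ms) else 1
  res <- cpp_train(params$W_in, params$W_rec, params$W_out, params$b_rec,
                   params$b_inp, params$b_out, params$n_exc, dale, tl, cl,
                   derive_seed(seed, "train"))
  if (isTRUE(res$diverged)) stop("training diverged (non-finite loss)")
  params$W_rec <- res$Wrec
  params$b_rec <- res$b_rec
  params$b_inp <- res$b_inp
  params$b_out <- res$b_out
  structure(list(params = params, init = init, converged = res$converged,
                 epochs_used = res$epochs_used, history = res$history,
                 task = task, control = control, seed = seed),
            class = "dale_rnn")
}

#' @export
print.dale_rnn <- function(x, ...) {
  cat(sprintf("Dale-constrained rate RNN (%d neurons, seed %s)\n",
              x$params$N, format(x$seed)))
  cat(sprintf("  %s after %d epochs\n",
              if (x$converged) "converged" else "NOT converged",
              x$epochs_used))
  if (nrow(x$history) > 0) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final validation: %.1f%% valid, %.1f%% correct (loss %.4f)\n",
                100 * h$valid_frac, 100 * h$correct_frac, h$loss))
  }
  invisible(x)
}

#' @export
summary.dale_rnn <- function(object, ...) {
  structure(list(fit = object), class = "summary.dale_rnn")
}

#' @export
print.summary.dale_rnn <- function(x, ...) {
  print(x$fit)
  cat("\nValidation history:\n")
  print(x$fit$history, row.names = FALSE)
  ex <- x$fit$params$sign > 0
  cat(sprintf("\nRecurrent weights: %.3g (mean |exc|), %.3g (mean |inh|)\n",
              mean(abs(x$fit$params$W_rec[, ex])),
              mean(abs(x$fit$params$W_rec[, !ex]))))
  invisible(x)
}

#' @export
coef.dale_rnn <- function(object, ...) {
  p <- object$params
  list(W_in = p$W_in, W_rec = p$W_rec, W_out = p$W_out, b_rec = p$b_rec,
       b_inp = p$b_inp, b_out = p$b_out)
}

#' Simulate trials from a fitted network
#'
#' Generates `nsim` fresh task trials and runs the trained network on them.
#'
#' @param object A fitted [dale_rnn()].
#' @param nsim Number of trials.
#' @param seed Integer seed.
#' @param dt_ms Simulation timestep (ms); 2 ms is the test resolution.
#' @param ... Passed to [run_trials()] (e.g. `rates`, `select`, `perturb`).
#' @return A `trial_records` object.
#' @export
simulate.dale_rnn <- function(object, nsim = 1024, seed = 1, dt_ms = 2, ...) {
  batch <- make_batch(object$task, nsim, derive_seed(seed, "simbatch"),
                      dt_ms = dt_ms, tau_ms = object$params$tau_ms)
  run_trials(object$params, batch, derive_seed(seed, "simnoise"), ...)
}

#' Predict decisions on a batch of trials
#'
#' @param object A fitted [dale_rnn()].
#' @param batch A [make_batch()] result (fresh trials are generated when
#'   omitted).
#' @param seed Integer seed for the simulation noise.
#' @param threshold Decision threshold.
#' @param ... Unused.
#' @return The decision table (see [decision_table()]).
#' @export
predict.dale_rnn <- function(object, batch = NULL, seed = 1,
                             threshold = 0.2, ...) {
  if (is.null(batch))
    batch <- make_batch(object$task, 1024, derive_seed(seed, "predbatch"),
                        tau_ms = object$params$tau_ms)
  rec <- run_trials(object$params, batch, derive_seed(seed, "prednoise"))
  decision_table(rec, threshold = threshold)
}

#' Plot the psychometric curve of a fitted network
#'
#' @param x A fitted [dale_rnn()].
#' @param records Optional pre-computed `trial_records`; fresh trials are
#'   simulated when omitted.
#' @param nsim,seed Simulation size and seed when `records` is `NULL`.
#' @param ... Passed to [plot.behavior_summary()].
#' @export
plot.dale_rnn <- function(x, records = NULL, nsim = 2048, seed = 1, ...) {
  if (is.null(records)) records <- simulate(x, nsim = nsim, seed = seed)
  plot(behavior_summary(records), ...)
}
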