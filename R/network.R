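#' Initialize an excitatory/inhibitory rate network
#'
#' Creates the parameter set of a Dale-constrained rate RNN. Neurons are
#' ordered excitatory first; the sign vector is +1 for the first
#' `N * p_exc` neurons and -1 for the rest. Input and recurrent weights are
#' drawn from `U(-k, k)` with `k = 1/sqrt(fan_in)`; the Dale structure is
#' imposed at initialization by taking absolute values and applying the
#' column sign, after which inhibitory recurrent columns are scaled by
#' `inh_scale` (6 by default, which aids training convergence). Output
#' weights are fixed, positive, and read out from the excitatory population
#' only; they and the output bias use a magnitude bound of 0.01.
#'
#' @param seed Integer seed; identical seeds give bitwise-identical
#'   parameters.
#' @param N Number of neurons.
#' @param p_exc Excitatory fraction; `N * p_exc` must be an integer in
#'   `(0, N)`.
#' @param n_channels Number of input channels.
#' @param tau_ms Membrane time constant (ms).
#' @param sigma_rec Recurrent noise scale.
#' @param inh_scale Multiplier applied to inhibitory recurrent columns at
#'   initialization.
#' @param dale If `FALSE`, skip the sign structure and inhibitory scaling
#'   (control model without Dale's law); the sign vector is still stored and
#'   the projection becomes a no-op.
#' @return An object of class `"network_params"`.
#' @export
init_network <- function(seed, N = 150, p_exc = 0.8, n_channels = 5,
                         tau_ms = 100, sigma_rec = 0.15, inh_scale = 6,
                         dale = TRUE) {
  if (p_exc <= 0 || p_exc >= 1) stop("p_exc must be in (0, 1)")
  n_exc <- N * p_exc
  if (abs(n_exc - round(n_exc)) > 1e-9) stop("N * p_exc must be an integer")
  n_exc <- as.integer(round(n_exc))
  set.seed(derive_seed(seed, "init"))
  sign_vec <- c(rep(1L, n_exc), rep(-1L, N - n_exc))
  k_in <- 1 / sqrt(n_channels)
  k_rec <- 1 / sqrt(N)
  W_in <- matrix(runif(N * n_channels, -k_in, k_in), N, n_channels)
  W_rec <- matrix(runif(N * N, -k_rec, k_rec), N, N)
  if (dale) {
    W_rec <- abs(W_rec) * rep(sign_vec, each = N)
    W_rec[, sign_vec < 0] <- W_rec[, sign_vec < 0] * inh_scale
  }
  b_rec <- runif(N, -k_rec, k_rec)
  b_inp <- runif(N, -k_in, k_in)
  W_out <- matrix(runif(2 * n_exc, 0, 0.01), 2, n_exc)
  b_out <- runif(2, -0.01, 0.01)
  structure(list(W_in = W_in, W_rec = W_rec, W_out = W_out, b_rec = b_rec,
                 b_inp = b_inp, b_out = b_out, sign = sign_vec, N = N,
                 n_exc = n_exc, tau_ms = tau_ms, sigma_rec = sigma_rec,
                 dale = dale, seed = seed),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("E/I rate network: %d neurons (%d excitatory, %d inhibitory)\n",
              x$N, x$n_exc, x$N - x$n_exc))
  cat(sprintf("  tau = %g ms, sigma_rec = %g, Dale constraint %s (seed %s)\n",
              x$tau_ms, x$sigma_rec, if (x$dale) "on" else "off",
              format(x$seed)))
  invisible(x)
}

#' Check Dale-sign compliance of the recurrent matrix
#'
#' @param params A [init_network()] result (or trained equivalent).
#' @return `TRUE` if every excitatory column is elementwise `>= 0` and every
#'   inhibitory column `<= 0`.
#' @export
dale_compliant <- function(params) {
  exc <- params$sign > 0
  all(params$W_rec[, exc] >= 0) && all(params$W_rec[, !exc] <= 0)
}

#' Project the recurrent matrix back onto the Dale constraint
#'
#' Excitatory-column entries that became negative and inhibitory-column
#' entries that became positive are reset to exactly zero; compliant entries
#' are untouched. Idempotent. A no-op for networks built with `dale = FALSE`.
#'
#' @param params A `network_params` object.
#' @return The projected parameters.
#' @export
dale_projection <- function(params) {
  if (!isTRUE(params$dale)) return(params)
  exc <- params$sign > 0
  params$W_rec[, exc][params$W_rec[, exc] < 0] <- 0
  params$W_rec[, !exc][params$W_rec[, !exc] > 0] <- 0
  params
}

#' One Euler step of the rate dynamics (reference implementation)
#'
#' Computes `x_t = (1 - alpha) x_{t-1} + alpha (W_rec r_{t-1} + b_rec +
#' W_in u_t + b_inp) + sqrt(2 alpha sigma_rec^2) * xi` and `r_t = max(x_t, 0)`.
#' This scalar-R reference is used for small exact checks; batched
#' simulation goes through [run_trials()].
#'
#' @param state List with voltage `x` and rate `r` vectors.
#' @param params A `network_params` object.
#' @param u_t Input vector (length `n_channels`).
#' @param alpha `dt/tau`.
#' @param noise Optional pre-drawn standard-normal vector (length `N`);
#'   `NULL` for deterministic dynamics.
#' @return Updated state list.
#' @export
rnn_step <- function(state, params, u_t, alpha, noise = NULL) {
  if (length(u_t) != ncol(params$W_in)) stop("input dimension mismatch")
  drive <- params$W_rec %*% state$r + params$b_rec +
    params$W_in %*% u_t + params$b_inp
  x <- (1 - alpha) * state$x + alpha * drive
  if (!is.null(noise))
    x <- x + sqrt(2 * alpha * params$sigma_rec^2) * noise
  list(x = as.numeric(x), r = pmax(as.numeric(x), 0))
}

#' Linear readout from the excitatory population
#'
#' `z = W_out r_exc + b_out`; inhibitory rates do not enter the readout.
#'
#' @param r Rate vector of length `N`.
#' @param params A `network_params` object.
#' @return Output vector of length 2 (low, high).
#' @export
readout <- function(r, params) {
  if (length(r) != params$N) stop("rate vector has wrong length")
  as.numeric(params$W_out %*% r[seq_len(params$n_exc)] + params$b_out)
}

#' Simulate a network on a batch of trials
#'
#' Runs the rate dynamics from `x_0 = 0` over every trial of a batch and
#' records the output trajectories, optionally the full rate trajectories,
#' and optionally the per-trial summaries used by the selectivity analysis
#' (mean rate over the final `window` steps and the fixation-epoch rate
#' traces). Supports the modulatory-current and lesion perturbations via
#' `perturb`.
#'
#' @param params A `network_params` object.
#' @param batch A [make_batch()] result.
#' @param seed Integer seed for the recurrent noise.
#' @param rates If `TRUE`, return the full `N x trials x time` rate array
#'   (memory-heavy at test resolution; prefer `select` summaries).
#' @param select If `TRUE`, return `win_rates` (`N x trials`) and
#'   `fix_traces` (`N x trials x fixation steps`).
#' @param window Number of final timesteps averaged into `win_rates`.
#' @param perturb Optional list: `mode` (`"modulate"` or `"lesion"`),
#'   `target` (1-based neuron indices), and for modulation `b_per`,
#'   `sigma_per`. The modulatory bias enters inside the `alpha(...)` bracket;
#'   its private noise uses an independent stream so the shared recurrent
#'   noise is identical to the unperturbed run at the same seed. Lesioned
#'   neurons have their rates clamped to exactly zero (voltages still
#'   evolve, but transmit nothing).
#' @return An object of class `"trial_records"`: `outputs`
#'   (`2 x trials x time`), plus requested extras and the batch metadata.
#' @export
run_trials <- function(params, batch, seed, rates = FALSE, select = FALSE,
                       window = 20, perturb = NULL) {
  alpha <- batch$dt_ms / params$tau_ms
  mode <- 0L
  target <- integer(0)
  b_per <- 0
  sigma_per <- 0
  if (!is.null(perturb)) {
    mode <- switch(match.arg(perturb$mode, c("modulate", "lesion")),
                   modulate = 1L, lesion = 2L)
    target <- as.integer(perturb$target)
    if (length(target) > 0 &&
        (min(target) < 1 || max(target) > params$N))
      stop("perturbation target indices out of range")
    if (mode == 1L) {
      b_per <- if (is.null(perturb$b_per)) 0.2 else perturb$b_per
      sigma_per <- if (is.null(perturb$sigma_per)) 0.01 else perturb$sigma_per
    }
    if (length(target) == 0)
      warning("empty perturbation target set; run equals baseline")
  }
  res <- cpp_forward(params$W_in, params$W_rec, params$W_out, params$b_rec,
                     params$b_inp, params$b_out, params$n_exc, batch$inputs,
                     alpha, params$sigma_rec, derive_seed(seed, "recnoise"),
                     rates, select, batch$onset_index, as.integer(window),
                     mode, target - 1L, b_per, sigma_per)
  structure(c(res, list(onset_index = batch$onset_index, dt_ms = batch$dt_ms,
                        modality = batch$modality,
                        frequency = batch$frequency,
                        correct_choice = batch$correct_choice,
                        config = batch$config, seed = seed)),
            class = "trial_records")
}

#' @export
print.trial_records <- function(x, ...) {
  d <- dim(x$outputs)
  cat(sprintf("Trial records: %d trials x %d steps (dt = %g ms)%s\n", d[2],
              d[3], x$dt_ms,
              if (!is.null(x$rates)) ", with rate trajectories" else ""))
  invisible(x)
}

#' Save or load network parameters as JSON
#'
#' Plain-text checkpoint: all weight matrices, biases, the sign vector, and
#' scalar metadata.
#'
#' @param params A `network_params` object.
#' @param path File path.
#' @return `load_network()` returns the restored `network_params`.
#' @export
save_network <- function(params, path) {
  # digits = I(17) guarantees bit-exact double round-trips
  jsonlite::write_json(unclass(params), path, digits = I(17),
                       auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # write_json(matrix = "columnmajor") stores columns as the inner arrays,
  # which simplify back as rows; transpose to restore the original layout
  for (nm in c("W_in", "W_rec", "W_out"))
    p[[nm]] <- t(as.matrix(p[[nm]]))
  p$sign <- as.integer(p$sign)
  structure(p, class = "network_params")
}
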