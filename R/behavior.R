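#' Extract the decision from one output trajectory
#'
#' A decision is registered at the first timestep at which the two output
#' variables separate by more than `threshold`. A crossing before stimulus
#' onset invalidates the trial; no crossing at all leaves the trial without a
#' decision. Reaction time is measured from stimulus onset and shifted by
#' `rt_offset_ms` (200 ms by default) to account for sensory and motor
#' processing time outside the modeled circuit.
#'
#' @param z Matrix `T x 2` of output trajectories (columns: low, high).
#' @param threshold Positive decision threshold.
#' @param onset_index Number of fixation steps (decisions at 1-based steps
#'   `<= onset_index` are pre-stimulus).
#' @param dt_ms Timestep in ms.
#' @param rt_offset_ms Constant added to reaction times.
#' @return A list with `status` (`"valid"`, `"invalid_pre_stimulus"`,
#'   `"no_decision"`), `choice` (`"high"`, `"low"` or `NA`),
#'   `decision_step` (1-based) and `rt_ms` (defined only for valid trials).
#' @export
extract_decision <- function(z, threshold = 0.2, onset_index, dt_ms,
                             rt_offset_ms = 200) {
  if (threshold <= 0) stop("threshold must be positive")
  d <- z[, 2] - z[, 1]
  step <- which(abs(d) > threshold)[1]
  if (is.na(step))
    return(list(status = "no_decision", choice = NA_character_,
                decision_step = NA_integer_, rt_ms = NA_real_))
  choice <- if (d[step] > 0) "high" else "low"
  if (step <= onset_index)
    return(list(status = "invalid_pre_stimulus", choice = choice,
                decision_step = step, rt_ms = NA_real_))
  list(status = "valid", choice = choice, decision_step = step,
       rt_ms = (step - 1 - onset_index) * dt_ms + rt_offset_ms)
}

#' Decision table for a batch of simulated trials
#'
#' Applies the first-crossing decision rule to every trial of a
#' `trial_records` object and returns one row per trial with the condition
#' labels, decision status, choice, reaction time and correctness.
#'
#' @param records A [run_trials()] result.
#' @param threshold Decision threshold.
#' @param rt_offset_ms Constant added to reaction times (ms).
#' @return A data frame with columns `trial`, `modality`, `frequency`, `x`
#'   (signed distance to the threshold frequency), `status`, `choice`,
#'   `decision_step`, `rt_ms`, `correct`.
#' @export
decision_table <- function(records, threshold = 0.2, rt_offset_ms = 200) {
  if (threshold <= 0) stop("threshold must be positive")
  dm <- cpp_decisions(records$outputs, threshold, records$onset_index)
  status <- c("valid", "invalid_pre_stimulus", "no_decision")[dm[, 1] + 1]
  choice <- ifelse(is.na(dm[, 2]), NA_character_,
                   ifelse(dm[, 2] == 1, "high", "low"))
  rt <- ifelse(status == "valid",
               (dm[, 3] - 1 - records$onset_index) * records$dt_ms +
                 rt_offset_ms, NA_real_)
  data.frame(trial = seq_along(status), modality = records$modality,
             frequency = records$frequency,
             x = records$frequency - records$config$f_threshold,
             status = status, choice = choice,
             decision_step = as.integer(dm[, 3]), rt_ms = rt,
             correct = status == "valid" &
               choice == records$correct_choice)
}

#' Psychometric points: fraction of high choices per frequency
#'
#' Only valid decisions enter; trials without a decision or with a
#' pre-stimulus decision are excluded. Frequencies are centered on the
#' threshold, giving `x = f - f_threshold` in `[-3.5, 3.5]` for the default
#' task.
#'
#' @param decisions A [decision_table()] (optionally pre-filtered by
#'   modality).
#' @return A data frame with columns `x`, `frac_high`, `n`.
#' @export
psychometric_points <- function(decisions) {
  d <- decisions[decisions$status == "valid", ]
  xs <- sort(unique(decisions$x))
  out <- do.call(rbind, lapply(xs, function(x0) {
    di <- d[d$x == x0, ]
    if (nrow(di) == 0) {
      warning(sprintf("no valid trials at x = %g; point omitted", x0))
      return(NULL)
    }
    data.frame(x = x0, frac_high = mean(di$choice == "high"), n = nrow(di))
  }))
  out
}

#' Fit a sigmoid to psychometric points
#'
#' Nonlinear least squares of `f(x) = 1 / (1 + exp(-a (x - b)))` on the
#' centered frequencies; `a` (slope) measures accuracy, `b` (offset) measures
#' choice bias. `fit_sigmoid_lapse()` fits the extended form
#' `f(x) = (1 - gamma_r - gamma_l) / (1 + exp(-a (x - b))) + gamma_r` with
#' lapse fractions bounded in `[0, 0.5]`. Fits are unweighted.
#'
#' @param points A [psychometric_points()] data frame.
#' @return An object of class `"psychometric_fit"`: coefficients `a`, `b`
#'   (and `gamma_r`, `gamma_l` for the lapse variant), `residual` (sum of
#'   squares), `converged`, and the points.
#' @export
fit_sigmoid <- function(points) {
  if (nrow(points) < 4 || min(points$x) >= 0 || max(points$x) <= 0)
    stop("need >= 4 points spanning both signs of x")
  fit <- tryCatch(
    minpack.lm::nlsLM(frac_high ~ 1 / (1 + exp(-a * (x - b))), data = points,
                      start = list(a = 1, b = 0),
                      lower = c(a = 0, b = -10), upper = c(a = 50, b = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(a = NA_real_, b = NA_real_, residual = NA_real_,
                          converged = FALSE, lapse = FALSE, points = points),
                     class = "psychometric_fit"))
  co <- coef(fit)
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 residual = sum(residuals(fit)^2), converged = TRUE,
                 lapse = FALSE, points = points),
            class = "psychometric_fit")
}

#' @rdname fit_sigmoid
#' @export
fit_sigmoid_lapse <- function(points) {
  if (nrow(points) < 4 || min(points$x) >= 0 || max(points$x) <= 0)
    stop("need >= 4 points spanning both signs of x")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      frac_high ~ (1 - gr - gl) / (1 + exp(-a * (x - b))) + gr,
      data = points, start = list(a = 1, b = 0, gr = 0.01, gl = 0.01),
      lower = c(a = 0, b = -10, gr = 0, gl = 0),
      upper = c(a = 50, b = 10, gr = 0.5, gl = 0.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(a = NA_real_, b = NA_real_, gamma_r = NA_real_,
                          gamma_l = NA_real_, residual = NA_real_,
                          converged = FALSE, lapse = TRUE, points = points),
                     class = "psychometric_fit"))
  co <- coef(fit)
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 gamma_r = unname(co["gr"]), gamma_l = unname(co["gl"]),
                 residual = sum(residuals(fit)^2), converged = TRUE,
                 lapse = TRUE, points = points),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Psychometric fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("Psychometric fit: slope a = %.3f, bias b = %.3f Hz", x$a, x$b))
  if (x$lapse)
    cat(sprintf(", lapses (%.3f, %.3f)", x$gamma_r, x$gamma_l))
  cat(sprintf(" [RSS %.2g]\n", x$residual))
  invisible(x)
}

#' Chronometric points and overall mean reaction time
#'
#' `chronometric_points()` averages reaction times of correct trials per
#' absolute distance to the threshold frequency; `mean_rt()` pools all
#' correct trials into one mean (the decision-speed metric used for
#' strategy labeling).
#'
#' @param decisions A [decision_table()].
#' @return `chronometric_points()`: data frame `abs_x`, `mean_rt_ms`, `n`;
#'   `mean_rt()`: scalar ms (`NA` with a warning if there are no correct
#'   trials).
#' @export
chronometric_points <- function(decisions) {
  d <- decisions[decisions$correct, ]
  if (nrow(d) == 0) {
    warning("no correct trials; chronometric curve undefined")
    return(data.frame(abs_x = numeric(0), mean_rt_ms = numeric(0),
                      n = integer(0)))
  }
  ax <- abs(d$x)
  out <- aggregate(d$rt_ms, list(abs_x = ax), mean)
  names(out)[2] <- "mean_rt_ms"
  out$n <- as.integer(table(ax)[as.character(out$abs_x)])
  out
}

#' @rdname chronometric_points
#' @export
mean_rt <- function(decisions) {
  d <- decisions[decisions$correct, ]
  if (nrow(d) == 0) {
    warning("no correct trials; mean RT undefined")
    return(NA_real_)
  }
  mean(d$rt_ms)
}

#' Behavioral summary of a network
#'
#' Computes the full behavioral phenotype from a decision table or trial
#' records: psychometric fits per modality and pooled over all trials,
#' chronometric points per modality, and the pooled mean reaction time.
#'
#' @param x A `trial_records` object or a [decision_table()] data frame.
#' @param lapse Also fit the lapse-parameter sigmoid.
#' @param threshold,rt_offset_ms Passed to [decision_table()] when `x` is a
#'   `trial_records`.
#' @return An object of class `"behavior_summary"`.
#' @export
behavior_summary <- function(x, lapse = FALSE, threshold = 0.2,
                             rt_offset_ms = 200) {
  dec <- if (inherits(x, "trial_records"))
    decision_table(x, threshold = threshold, rt_offset_ms = rt_offset_ms)
  else x
  mods <- c("visual", "auditory", "multisensory")
  fits <- lapply(mods, function(m) {
    pts <- psychometric_points(dec[dec$modality == m, ])
    tryCatch(fit_sigmoid(pts), error = function(e) NULL)
  })
  names(fits) <- mods
  # degenerate decision tables (e.g. an untrained network with no valid
  # trials) yield a non-converged NA fit rather than an error
  na_fit <- structure(list(a = NA_real_, b = NA_real_, residual = NA_real_,
                           converged = FALSE, lapse = FALSE, points = NULL),
                      class = "psychometric_fit")
  pooled <- tryCatch(fit_sigmoid(psychometric_points(dec)),
                     error = function(e) na_fit)
  chrono <- lapply(mods, function(m)
    chronometric_points(dec[dec$modality == m, ]))
  names(chrono) <- mods
  rts <- vapply(mods, function(m)
    suppressWarnings(mean_rt(dec[dec$modality == m, ])), numeric(1))
  out <- list(fits = fits, pooled = pooled,
              pooled_lapse = if (lapse)
                tryCatch(fit_sigmoid_lapse(psychometric_points(dec)),
                         error = function(e) na_fit),
              chronometric = chrono, mean_rt_by_modality = rts,
              mean_rt_ms = suppressWarnings(mean_rt(dec)),
              valid_fraction = mean(dec$status == "valid"),
              n_trials = nrow(dec))
  structure(out, class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("Behavioral summary over %d trials (%.1f%% valid)\n",
              x$n_trials, 100 * x$valid_fraction))
  cat(sprintf("  pooled: slope %.3f, bias %.3f Hz, mean RT %.0f ms\n",
              x$pooled$a, x$pooled$b, x$mean_rt_ms))
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    if (!is.null(f) && f$converged)
      cat(sprintf("  %-13s slope %.3f, bias %+.3f Hz, mean RT %.0f ms\n",
                  paste0(m, ":"), f$a, f$b, x$mean_rt_by_modality[[m]]))
  }
  invisible(x)
}

#' @export
plot.behavior_summary <- function(x, ...) {
  cols <- c(visual = "#3366cc", auditory = "#dd8822",
            multisensory = "#33a02c")
  plot(NA, xlim = range(x$pooled$points$x), ylim = c(0, 1),
       xlab = "frequency - threshold (Hz)", ylab = "fraction 'high' choices",
       ...)
  abline(h = 0.5, v = 0, col = "grey80", lty = 2)
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    if (is.null(f) || !f$converged) next
    points(f$points$x, f$points$frac_high, col = cols[[m]], pch = 16)
    curve(1 / (1 + exp(-f$a * (x - f$b))), add = TRUE, col = cols[[m]])
  }
  legend("topleft", legend = names(cols), col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Label strategies across an ensemble of networks
#'
#' A network is `fast` when its pooled mean reaction time is strictly below
#' the ensemble average, `slow` otherwise; `accurate` when its pooled
#' psychometric slope is strictly above the ensemble average, `inaccurate`
#' otherwise.
#'
#' @param summaries A list of [behavior_summary()] objects (>= 2).
#' @return A data frame with columns `network`, `mean_rt_ms`, `slope`,
#'   `speed` (fast/slow) and `accuracy` (accurate/inaccurate).
#' @export
label_strategies <- function(summaries) {
  if (length(summaries) < 2) stop("need at least 2 networks")
  rt <- vapply(summaries, function(s) s$mean_rt_ms, numeric(1))
  a <- vapply(summaries, function(s) s$pooled$a, numeric(1))
  data.frame(network = seq_along(summaries), mean_rt_ms = rt, slope = a,
             speed = ifelse(rt < mean(rt), "fast", "slow"),
             accuracy = ifelse(a > mean(a), "accurate", "inaccurate"))
}
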