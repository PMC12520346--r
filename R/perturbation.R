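#' Resolve a perturbation target group to neuron indices
#'
#' Maps a named group to the neuron set of one network: a selectivity label
#' (resolved from the network's own selectivity table, computed before any
#' perturbation and frozen), a cell class (`excitatory`, `inhibitory`), or
#' `all`.
#'
#' @param params A `network_params` or fitted [dale_rnn()].
#' @param group One of `"modality"`, `"choice"`, `"mixed"`, `"silent"`,
#'   `"hyper"`, `"all"`, `"excitatory"`, `"inhibitory"`.
#' @param seltab A [selectivity_table()] (required for label groups).
#' @return Integer vector of 1-based neuron indices (possibly empty).
#' @export
resolve_target <- function(params, group, seltab = NULL) {
  if (inherits(params, "dale_rnn")) params <- params$params
  group <- match.arg(group, c("modality", "choice", "mixed", "silent",
                              "hyper", "all", "excitatory", "inhibitory"))
  switch(group,
         all = seq_len(params$N),
         excitatory = which(params$sign > 0),
         inhibitory = which(params$sign < 0),
         {
           if (is.null(seltab))
             stop("selectivity table required for label group '", group, "'")
           which(seltab$label == group)
         })
}

#' Run a perturbation experiment against a paired baseline
#'
#' Simulates the same freshly generated trial batch twice - once unperturbed
#' and once with the perturbation applied - using identical stimulus noise
#' and identical shared recurrent-noise streams, so that behavioral
#' differences are attributable to the perturbation alone. Modulation adds a
#' constant bias current `b_per` (inside the `alpha(...)` bracket of the
#' voltage update) plus private noise with scale `sigma_per` to the targeted
#' neurons at every timestep of every epoch; lesioning clamps the targeted
#' neurons' rates to exactly zero.
#'
#' @param fit A fitted [dale_rnn()].
#' @param group Target group name (see [resolve_target()]) or an integer
#'   vector of neuron indices.
#' @param mode `"modulate"` or `"lesion"`.
#' @param seltab Selectivity table for label groups (computed and frozen
#'   beforehand).
#' @param n_trials Trials per arm (2048 by default).
#' @param seed Integer seed shared by both arms.
#' @param dt_ms Simulation resolution.
#' @param b_per,sigma_per Modulatory bias and noise scale.
#' @param lapse Fit lapse-parameter psychometrics as well.
#' @return An object of class `"perturbation_experiment"`: `baseline` and
#'   `perturbed` behavior summaries, their decision tables, the target
#'   indices, and the experiment metadata.
#' @export
perturbation_experiment <- function(fit, group, mode = c("modulate", "lesion"),
                                    seltab = NULL, n_trials = 2048, seed = 1,
                                    dt_ms = 2, b_per = 0.2, sigma_per = 0.01,
                                    lapse = FALSE) {
  mode <- match.arg(mode)
  target <- if (is.numeric(group)) as.integer(group)
  else resolve_target(fit, group, seltab)
  if (length(target) == 0)
    warning("empty target set for group; perturbed arm equals baseline")
  batch <- make_batch(fit$task, n_trials, derive_seed(seed, "pertbatch"),
                      dt_ms = dt_ms, tau_ms = fit$params$tau_ms)
  base_rec <- run_trials(fit$params, batch, derive_seed(seed, "pertnoise"))
  pert_rec <- run_trials(fit$params, batch, derive_seed(seed, "pertnoise"),
                         perturb = list(mode = mode, target = target,
                                        b_per = b_per,
                                        sigma_per = sigma_per))
  base_dec <- decision_table(base_rec)
  pert_dec <- decision_table(pert_rec)
  structure(list(baseline = behavior_summary(base_dec, lapse = lapse),
                 perturbed = behavior_summary(pert_dec, lapse = lapse),
                 baseline_decisions = base_dec,
                 perturbed_decisions = pert_dec,
                 group = if (is.numeric(group)) "custom" else group,
                 mode = mode, target = target, n_trials = n_trials,
                 b_per = b_per, sigma_per = sigma_per, seed = seed),
            class = "perturbation_experiment")
}

#' @export
print.perturbation_experiment <- function(x, ...) {
  cat(sprintf("%s of %s neurons (%d targeted), %d trials per arm\n",
              if (x$mode == "modulate") "Modulation" else "Lesion",
              x$group, length(x$target), x$n_trials))
  cat(sprintf("  slope: %.3f -> %.3f | mean RT: %.0f -> %.0f ms\n",
              x$baseline$pooled$a, x$perturbed$pooled$a,
              x$baseline$mean_rt_ms, x$perturbed$mean_rt_ms))
  invisible(x)
}

#' Compare baseline and perturbed behavior across networks
#'
#' For each behavioral metric (psychometric slope, bias, pooled mean
#' reaction time), computes the across-network deltas between paired
#' baseline and perturbed summaries, a paired permutation test of the
#' difference in means, Holm-Bonferroni adjustment across the table, and a
#' signed effect classification: a slope increase, an RT decrease or a bias
#' magnitude decrease count as improvements when significant.
#'
#' @param baseline,perturbed Lists of [behavior_summary()] objects of the
#'   same networks, in the same order.
#' @param n_resamples Permutation resamples.
#' @param alpha Significance level applied to adjusted p-values.
#' @param seed Integer seed.
#' @return A data frame with one row per metric: mean delta, p-values and
#'   the `improved`/`worsened`/`no_change` call.
#' @export
compare_conditions <- function(baseline, perturbed, n_resamples = 1e5,
                               alpha = 0.05, seed = 1) {
  if (length(baseline) != length(perturbed))
    stop("baseline and perturbed summaries must pair up")
  get <- function(lst, f) vapply(lst, f, numeric(1))
  metrics <- list(
    slope = function(s) s$pooled$a,
    bias = function(s) s$pooled$b,
    mean_rt_ms = function(s) s$mean_rt_ms)
  rows <- lapply(names(metrics), function(m) {
    b <- get(baseline, metrics[[m]])
    p <- get(perturbed, metrics[[m]])
    ok <- is.finite(b) & is.finite(p)
    pt <- perm_test_paired(b[ok], p[ok], n_resamples = n_resamples,
                           seed = derive_seed(seed, m))
    data.frame(metric = m, delta = mean(p[ok] - b[ok]),
               baseline_mean = mean(b[ok]), perturbed_mean = mean(p[ok]),
               n = sum(ok), p_raw = pt$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_bonferroni(out$p_raw)
  improved <- c(slope = out$delta[out$metric == "slope"] > 0,
                bias = abs(out$perturbed_mean[out$metric == "bias"]) <
                  abs(out$baseline_mean[out$metric == "bias"]),
                mean_rt_ms = out$delta[out$metric == "mean_rt_ms"] < 0)
  out$effect <- ifelse(out$p_adj >= alpha, "no_change",
                       ifelse(improved[out$metric], "improved", "worsened"))
  out
}
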