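#' Train and analyze an ensemble of networks
#'
#' Runs the full experiment pipeline: trains `n_networks` networks from
#' deterministically derived per-network seeds, flags and excludes networks
#' that do not reach the stopping criterion, evaluates every converged
#' network on a large fresh test set at test resolution, classifies unit
#' selectivity, labels behavioral strategies, and assembles the group-level
#' tables (modality comparisons, speed-accuracy correlation, and
#' selectivity-count versus behavior correlations).
#'
#' When `checkpoint_dir` is given, each trained network is written there as
#' a JSON checkpoint (`net<i>.json`, see [save_network()]) plus a metadata
#' sidecar, and a rerun resumes from the checkpoints instead of retraining,
#' so the report is regenerable from stored artifacts.
#'
#' @param n_networks Ensemble size (scaled-down default 20; raise for
#'   publication-scale runs).
#' @param task A [task_config()].
#' @param control A [train_config()].
#' @param master_seed Integer master seed; per-network seeds are derived
#'   deterministically from it.
#' @param n_eval_trials Fresh test trials per converged network.
#' @param dt_ms Test resolution (2 ms by default).
#' @param selectivity_trials Unimodal trials for selectivity classification
#'   per network (0 skips the selectivity stage).
#' @param n_neurons,p_exc,sigma_rec,dale Network construction arguments
#'   passed to [dale_rnn()].
#' @param checkpoint_dir Optional directory for resumable JSON checkpoints.
#' @param progress Print per-network progress lines.
#' @return An object of class `"ensemble_report"`: `networks` (one row per
#'   trained network: seed, convergence, epochs, behavioral metrics and
#'   strategy labels for converged ones), `fits` (the [dale_rnn()] objects,
#'   converged or not), `summaries` and `selectivity`
#'   (per-converged-network [behavior_summary()] objects and
#'   [selectivity_table()] data frames), `counts` (per-network label
#'   counts), `modality_effects`, `speed_accuracy` and
#'   `count_correlations` group tables, and the configuration.
#' @export
run_ensemble <- function(n_networks = 20, task = task_config(),
                         control = train_config(), master_seed = 1,
                         n_eval_trials = 8192, dt_ms = 2,
                         selectivity_trials = 2048, n_neurons = 150,
                         p_exc = 0.8, sigma_rec = 0.15, dale = TRUE,
                         checkpoint_dir = NULL, progress = FALSE) {
  stopifnot(n_networks >= 1, n_eval_trials >= 1)
  fits <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    seed_i <- derive_seed(master_seed, paste0("net", i))
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, paste0("net", i, ".json"))
    meta <- if (!is.null(ck)) paste0(ck, ".meta.json")
    if (!is.null(ck) && file.exists(ck) && file.exists(meta)) {
      m <- jsonlite::read_json(meta, simplifyVector = TRUE)
      fits[[i]] <- structure(
        list(params = load_network(ck), converged = m$converged,
             epochs_used = m$epochs_used, history = as.data.frame(m$history),
             task = task, control = control, seed = m$seed),
        class = "dale_rnn")
    } else {
      fits[[i]] <- dale_rnn(task = task, control = control,
                            n_neurons = n_neurons, p_exc = p_exc,
                            sigma_rec = sigma_rec, dale = dale,
                            seed = seed_i)
      if (!is.null(ck)) {
        if (!dir.exists(checkpoint_dir))
          dir.create(checkpoint_dir, recursive = TRUE)
        save_network(fits[[i]]$params, ck)
        jsonlite::write_json(
          list(seed = seed_i, converged = fits[[i]]$converged,
               epochs_used = fits[[i]]$epochs_used,
               history = fits[[i]]$history),
          meta, digits = I(17), auto_unbox = TRUE)
      }
    }
    if (progress)
      cat(sprintf("network %d/%d (seed %d): %s after %d epochs\n", i,
                  n_networks, fits[[i]]$seed,
                  if (fits[[i]]$converged) "converged" else "NOT converged",
                  fits[[i]]$epochs_used))
  }
  converged <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(converged))
    stop("no network reached the convergence criterion; ",
         "inspect the training histories")
  idx <- which(converged)
  summaries <- vector("list", length(idx))
  seltabs <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    rec <- simulate(fits[[i]], nsim = n_eval_trials,
                    seed = derive_seed(master_seed, paste0("eval", i)),
                    dt_ms = dt_ms)
    summaries[[j]] <- behavior_summary(rec)
    if (selectivity_trials > 0) {
      cr <- condition_rates(fits[[i]], n_trials = selectivity_trials,
                            seed = derive_seed(master_seed,
                                               paste0("sel", i)),
                            dt_ms = dt_ms)
      seltabs[[j]] <- selectivity_table(cr)
    }
    if (progress)
      cat(sprintf("network %d evaluated: %.1f%% valid, slope %.2f, RT %.0f ms\n",
                  i, 100 * summaries[[j]]$valid_fraction,
                  summaries[[j]]$pooled$a, summaries[[j]]$mean_rt_ms))
  }
  strategies <- if (length(idx) >= 2) label_strategies(summaries)
  networks <- data.frame(
    network = seq_len(n_networks),
    seed = vapply(fits, function(f) as.numeric(f$seed), numeric(1)),
    converged = converged,
    epochs_used = vapply(fits, function(f) f$epochs_used, numeric(1)),
    valid_fraction = NA_real_, slope = NA_real_, bias = NA_real_,
    mean_rt_ms = NA_real_, speed = NA_character_, accuracy = NA_character_)
  networks$valid_fraction[idx] <-
    vapply(summaries, function(s) s$valid_fraction, numeric(1))
  networks$slope[idx] <- vapply(summaries, function(s) s$pooled$a, numeric(1))
  networks$bias[idx] <- vapply(summaries, function(s) s$pooled$b, numeric(1))
  networks$mean_rt_ms[idx] <-
    vapply(summaries, function(s) s$mean_rt_ms, numeric(1))
  if (!is.null(strategies)) {
    networks$speed[idx] <- strategies$speed
    networks$accuracy[idx] <- strategies$accuracy
  }
  counts <- if (selectivity_trials > 0) selectivity_counts(seltabs)
  structure(list(networks = networks, fits = fits, summaries = summaries,
                 selectivity = seltabs, counts = counts,
                 modality_effects = if (length(idx) >= 2)
                   modality_effects(summaries,
                                    seed = derive_seed(master_seed, "modfx")),
                 speed_accuracy = if (length(idx) >= 3)
                   pearson_correlation(networks$slope[idx],
                                       networks$mean_rt_ms[idx]),
                 count_correlations = if (!is.null(counts) && length(idx) >= 3)
                   count_correlations(counts, summaries),
                 master_seed = master_seed, task = task, control = control,
                 n_eval_trials = n_eval_trials, dt_ms = dt_ms),
            class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  n <- nrow(x$networks)
  nc <- sum(x$networks$converged)
  cat(sprintf("Ensemble report: %d/%d networks converged\n", nc, n))
  if (nc >= 2) {
    cat(sprintf("  slope %.2f +/- %.2f, mean RT %.0f +/- %.0f ms (ensemble)\n",
                mean(x$networks$slope, na.rm = TRUE),
                sd(x$networks$slope, na.rm = TRUE),
                mean(x$networks$mean_rt_ms, na.rm = TRUE),
                sd(x$networks$mean_rt_ms, na.rm = TRUE)))
  }
  if (!is.null(x$speed_accuracy))
    cat(sprintf("  speed-accuracy r = %.3f (p = %.3g)\n",
                x$speed_accuracy$estimate, x$speed_accuracy$p_value))
  invisible(x)
}

# Per-network counts of each selectivity label (rows = networks).
selectivity_counts <- function(seltabs) {
  lv <- c("modality", "choice", "mixed", "silent", "hyper", "unclassified")
  out <- t(vapply(seltabs, function(tb)
    as.numeric(table(factor(tb$label, levels = lv))), numeric(length(lv))))
  colnames(out) <- lv
  as.data.frame(out)
}

#' Ensemble-level modality comparisons
#'
#' For the psychometric slope and the mean reaction time, compares the
#' multisensory condition against each unisensory condition across networks
#' with paired permutation tests (each network contributes its own paired
#' values), Holm-adjusted over the table.
#'
#' @param summaries List of [behavior_summary()] objects.
#' @param n_resamples Permutation resamples.
#' @param seed Integer seed.
#' @return Data frame: metric, comparison, multisensory and unisensory
#'   means, delta, p-values.
#' @export
modality_effects <- function(summaries, n_resamples = 1e5, seed = 1) {
  slope_of <- function(s, m) {
    f <- s$fits[[m]]
    if (is.null(f) || !isTRUE(f$converged)) NA_real_ else f$a
  }
  rt_of <- function(s, m) s$mean_rt_by_modality[[m]]
  rows <- list()
  for (metric in c("slope", "mean_rt_ms")) {
    get <- if (metric == "slope") slope_of else rt_of
    multi <- vapply(summaries, get, numeric(1), m = "multisensory")
    for (uni in c("visual", "auditory")) {
      u <- vapply(summaries, get, numeric(1), m = uni)
      ok <- is.finite(multi) & is.finite(u)
      p_raw <- if (sum(ok) >= 2)
        perm_test_paired(u[ok], multi[ok], n_resamples = n_resamples,
                         seed = derive_seed(seed, paste0(metric, uni)))$p_value
      else NA_real_
      rows[[paste(metric, uni)]] <- data.frame(
        metric = metric, comparison = paste0("multisensory-", uni),
        multisensory = mean(multi[ok]), unisensory = mean(u[ok]),
        delta = mean(multi[ok] - u[ok]), n = sum(ok), p_raw = p_raw)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- holm_bonferroni(out$p_raw)
  out
}

# Spearman correlations between per-network selectivity counts and the two
# behavioral metrics (pooled mean RT, pooled psychometric slope).
count_correlations <- function(counts, summaries) {
  rt <- vapply(summaries, function(s) s$mean_rt_ms, numeric(1))
  a <- vapply(summaries, function(s) s$pooled$a, numeric(1))
  rows <- list()
  for (lab in colnames(counts)) {
    for (metric in c("mean_rt_ms", "slope")) {
      y <- if (metric == "mean_rt_ms") rt else a
      ok <- is.finite(y) & is.finite(counts[[lab]])
      r <- if (sum(ok) >= 3 && sd(counts[[lab]][ok]) > 0)
        rank_correlation(counts[[lab]][ok], y[ok])
      rows[[paste(lab, metric)]] <- data.frame(
        label = lab, metric = metric,
        rho = if (is.null(r)) NA_real_ else r$estimate,
        p_value = if (is.null(r)) NA_real_ else r$p_value, n = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decision-threshold sweep
#'
#' Simulates one fresh batch per network and re-extracts decisions at each
#' candidate threshold without retraining or re-simulating, reporting the
#' valid, correct (among valid) and no-decision trial fractions.
#'
#' @param fits A fitted [dale_rnn()] or a list of them.
#' @param thresholds Numeric vector of candidate thresholds.
#' @param n_trials Trials per network.
#' @param dt_ms Test resolution.
#' @param seed Integer seed.
#' @return Data frame: threshold, valid_frac, correct_frac,
#'   no_decision_frac (averaged over networks).
#' @export
threshold_sweep <- function(fits, thresholds = seq(0.05, 0.5, by = 0.05),
                            n_trials = 2048, dt_ms = 2, seed = 1) {
  if (inherits(fits, "dale_rnn")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "dale_rnn")),
            length(thresholds) >= 1, all(thresholds > 0))
  acc <- matrix(0, length(thresholds), 3)
  for (k in seq_along(fits)) {
    rec <- simulate(fits[[k]], nsim = n_trials,
                    seed = derive_seed(seed, paste0("sweep", k)),
                    dt_ms = dt_ms)
    for (ti in seq_along(thresholds)) {
      dec <- decision_table(rec, threshold = thresholds[ti])
      valid <- mean(dec$status == "valid")
      correct <- if (any(dec$status == "valid"))
        mean(dec$correct[dec$status == "valid"]) else NA_real_
      acc[ti, ] <- acc[ti, ] + c(valid, correct,
                                 mean(dec$status == "no_decision"))
    }
  }
  data.frame(threshold = thresholds, valid_frac = acc[, 1] / length(fits),
             correct_frac = acc[, 2] / length(fits),
             no_decision_frac = acc[, 3] / length(fits))
}
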