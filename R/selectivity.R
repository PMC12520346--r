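#' Condition-averaged firing rates for selectivity analysis
#'
#' Simulates unimodal test trials in chunks and accumulates, for every
#' neuron, the mean rate over the decision window (the final 20 timepoints
#' of the trial, 40 ms at test resolution) in each of the four correct
#' unimodal conditions (auditory-high, auditory-low, visual-high,
#' visual-low), together with the maximum of the trial-averaged rate during
#' the fixation epoch. Multisensory trials are excluded: selectivity would
#' be ambiguous when both modalities are present. Only correct trials enter.
#'
#' @param fit A fitted [dale_rnn()] (or a `network_params` plus `task`).
#' @param n_trials Total unimodal trials to simulate.
#' @param seed Integer seed.
#' @param dt_ms Test resolution (2 ms by default).
#' @param window Decision-window length in timepoints.
#' @param chunk Trials per simulation chunk (bounds memory).
#' @param task Task configuration (taken from `fit` when omitted).
#' @param perturb Optional perturbation forwarded to [run_trials()].
#' @return An object of class `"condition_rates"`: matrix `rates`
#'   (`neurons x 4`, columns `aud_high`, `aud_low`, `vis_high`, `vis_low`),
#'   `fixation_max` (length `neurons`), per-condition trial counts, and the
#'   per-trial window rates with their condition labels (used by the ROC
#'   classifier).
#' @export
condition_rates <- function(fit, n_trials = 2048, seed = 1, dt_ms = 2,
                            window = 20, chunk = 512, task = NULL,
                            perturb = NULL) {
  params <- if (inherits(fit, "dale_rnn")) fit$params else fit
  if (is.null(task)) task <- fit$task
  N <- params$N
  cond_names <- c("aud_high", "aud_low", "vis_high", "vis_low")
  rate_sum <- matrix(0, N, 4, dimnames = list(NULL, cond_names))
  n_cond <- setNames(numeric(4), cond_names)
  fix_sum <- NULL
  n_fix <- 0
  trial_rates <- list()
  trial_cond <- list()
  done <- 0
  ci <- 0
  while (done < n_trials) {
    ci <- ci + 1
    b <- min(chunk, n_trials - done)
    batch <- make_batch(task, b, derive_seed(seed, paste0("selb", ci)),
                        modality = sample(c("visual", "auditory"), b,
                                          replace = TRUE),
                        dt_ms = dt_ms, tau_ms = params$tau_ms)
    rec <- run_trials(params, batch, derive_seed(seed, paste0("seln", ci)),
                      select = TRUE, window = window, perturb = perturb)
    dec <- decision_table(rec)
    ok <- which(dec$correct)
    if (length(ok) > 0) {
      cond <- ifelse(batch$modality[ok] == "auditory",
                     ifelse(batch$correct_choice[ok] == "high",
                            "aud_high", "aud_low"),
                     ifelse(batch$correct_choice[ok] == "high",
                            "vis_high", "vis_low"))
      for (cn in cond_names) {
        sel <- ok[cond == cn]
        if (length(sel) > 0) {
          rate_sum[, cn] <- rate_sum[, cn] +
            rowSums(rec$win_rates[, sel, drop = FALSE])
          n_cond[cn] <- n_cond[cn] + length(sel)
        }
      }
      fx <- apply(rec$fix_traces[, ok, , drop = FALSE], c(1, 3), sum)
      fix_sum <- if (is.null(fix_sum)) fx else fix_sum + fx
      n_fix <- n_fix + length(ok)
      trial_rates[[ci]] <- rec$win_rates[, ok, drop = FALSE]
      trial_cond[[ci]] <- cond
    }
    done <- done + b
  }
  if (any(n_cond == 0))
    warning("conditions without correct trials: ",
            paste(cond_names[n_cond == 0], collapse = ", "))
  rates <- sweep(rate_sum, 2, pmax(n_cond, 1), "/")
  rates[, n_cond == 0] <- NA_real_
  structure(list(rates = rates,
                 fixation_max = if (n_fix > 0)
                   apply(fix_sum / n_fix, 1, max) else rep(NA_real_, N),
                 n_per_condition = n_cond,
                 trial_rates = do.call(cbind, trial_rates),
                 trial_condition = unlist(trial_cond),
                 sign = params$sign, window = window, dt_ms = dt_ms),
            class = "condition_rates")
}

#' @export
print.condition_rates <- function(x, ...) {
  cat(sprintf("Condition rates for %d neurons (window %d steps at %g ms)\n",
              nrow(x$rates), x$window, x$dt_ms))
  print(x$n_per_condition)
  invisible(x)
}

#' Rate-based selectivity classification of a single unit
#'
#' Classifies one neuron from its four condition rates and its fixation
#' maximum, with mutually exclusive labels applied in precedence order:
#'
#' * `silent` - all four condition rates below the fixation maximum;
#' * `hyper` - exactly three below the fixation maximum, one above;
#' * `modality` / `choice` - both conditions of one side of an axis strictly
#'   exceed both conditions of the other (e.g. both auditory rates above
#'   both visual rates), and the unit fails the mixed test;
#' * `mixed` - after a primary modality/choice classification, the mean
#'   difference along the other axis exceeds the gap between the 2nd and
#'   3rd largest condition rates;
#' * `unclassified` - no rule applies (including rate ties that defeat the
#'   strict comparisons).
#'
#' When both axes separate, the one with the larger between-side mean
#' difference is taken as primary and the other is tested for mixedness.
#'
#' @param rates Named numeric vector with elements `aud_high`, `aud_low`,
#'   `vis_high`, `vis_low`.
#' @param fixation_max The unit's maximum trial-averaged fixation rate.
#' @return A label string.
#' @export
classify_rate_based <- function(rates, fixation_max) {
  r <- rates[c("aud_high", "aud_low", "vis_high", "vis_low")]
  if (any(is.na(r)) || is.na(fixation_max)) return("unclassified")
  below <- r < fixation_max
  if (all(below)) return("silent")
  if (sum(below) == 3) return("hyper")
  aud <- c(r["aud_high"], r["aud_low"])
  vis <- c(r["vis_high"], r["vis_low"])
  hig <- c(r["aud_high"], r["vis_high"])
  low <- c(r["aud_low"], r["vis_low"])
  mod_sep <- min(aud) > max(vis) || min(vis) > max(aud)
  cho_sep <- min(hig) > max(low) || min(low) > max(hig)
  if (!mod_sep && !cho_sep) return("unclassified")
  mod_diff <- abs(mean(aud) - mean(vis))
  cho_diff <- abs(mean(hig) - mean(low))
  primary <- if (mod_sep && cho_sep) {
    if (mod_diff >= cho_diff) "modality" else "choice"
  } else if (mod_sep) "modality" else "choice"
  sorted <- sort(r, decreasing = TRUE)
  gap23 <- sorted[2] - sorted[3]
  other_diff <- if (primary == "modality") cho_diff else mod_diff
  if (other_diff > gap23) "mixed" else primary
}

#' Selectivity table of a network
#'
#' Applies [classify_rate_based()] (or [classify_roc()]) to every neuron.
#'
#' @param cr A [condition_rates()] result.
#' @param method `"rate"` or `"roc"`.
#' @param ... Passed to [classify_roc()] for the ROC method.
#' @return A data frame with one row per neuron: `neuron`, `is_excitatory`,
#'   `label`, the four condition rates and `fixation_max`.
#' @export
selectivity_table <- function(cr, method = c("rate", "roc"), ...) {
  method <- match.arg(method)
  N <- nrow(cr$rates)
  label <- if (method == "rate") {
    vapply(seq_len(N), function(i)
      classify_rate_based(cr$rates[i, ], cr$fixation_max[i]), character(1))
  } else {
    classify_roc(cr, ...)
  }
  data.frame(neuron = seq_len(N), is_excitatory = cr$sign > 0,
             label = label, aud_high = cr$rates[, "aud_high"],
             aud_low = cr$rates[, "aud_low"],
             vis_high = cr$rates[, "vis_high"],
             vis_low = cr$rates[, "vis_low"],
             fixation_max = cr$fixation_max)
}

# Mann-Whitney AUC of `values` for the binary labels (TRUE group scored
# against FALSE group).
auc_binary <- function(values, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  rk <- rank(values)
  (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC-based selectivity classification
#'
#' For every neuron, computes the area under the ROC curve of its
#' decision-window rates for (a) choice (high vs low, over correct unimodal
#' trials) against a null distribution from shuffling choice labels, and
#' (b) modality (auditory vs visual) within each choice split against
#' modality-shuffled nulls. A neuron is selective when its AUC falls in the
#' lowest or highest `tail` percent of the shuffled distribution; selective
#' on both axes gives `mixed`, on neither `unselective`.
#'
#' @param cr A [condition_rates()] result (its per-trial window rates are
#'   used).
#' @param n_shuffles Shuffles per null distribution.
#' @param tail Tail probability per side, in percent.
#' @param seed Integer seed.
#' @return Character vector of labels (`choice`, `modality`, `mixed`,
#'   `unselective`).
#' @export
classify_roc <- function(cr, n_shuffles = 1000, tail = 2.5, seed = 1) {
  v <- cr$trial_rates              # N x trials
  cond <- cr$trial_condition
  is_high <- cond %in% c("aud_high", "vis_high")
  is_aud <- cond %in% c("aud_high", "aud_low")
  N <- nrow(v)
  set.seed(derive_seed(seed, "roc"))
  sig_between <- function(vals, labels, nsh) {
    a <- auc_binary(vals, labels)
    if (is.na(a)) return(FALSE)
    null <- replicate(nsh, auc_binary(vals, sample(labels)))
    a < quantile(null, tail / 100, na.rm = TRUE) ||
      a > quantile(null, 1 - tail / 100, na.rm = TRUE)
  }
  vapply(seq_len(N), function(i) {
    vals <- v[i, ]
    if (sd(vals) == 0) return("unselective")
    choice_sel <- sig_between(vals, is_high, n_shuffles)
    mod_sel <- sig_between(vals[is_high], is_aud[is_high], n_shuffles) ||
      sig_between(vals[!is_high], is_aud[!is_high], n_shuffles)
    if (choice_sel && mod_sel) "mixed"
    else if (choice_sel) "choice"
    else if (mod_sel) "modality"
    else "unselective"
  }, character(1))
}

#' Count selectivity labels by excitatory/inhibitory identity
#'
#' @param table A [selectivity_table()].
#' @return A contingency table label x (excitatory, inhibitory); counts sum
#'   to the number of neurons.
#' @export
count_by_group <- function(table) {
  lv <- c("modality", "choice", "mixed", "silent", "hyper", "unclassified",
          "unselective")
  t(table(factor(ifelse(table$is_excitatory, "excitatory", "inhibitory"),
                 levels = c("excitatory", "inhibitory")),
          factor(table$label, levels = lv)))
}
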