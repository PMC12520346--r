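library(dalernn)

# Shared test helpers. Small configurations keep unit tests fast; the
# acceptance suite builds one full-size ensemble lazily and caches it for
# the session so every criterion draws on the same trained networks.

# A short task for unit tests of mechanics (not used for any scientific
# claim; study-condition defaults are exercised in the acceptance suite).
tiny_task <- function(...) {
  task_config(fixation_ms = 100, stimulus_ms = 200, ...)
}

tiny_network <- function(seed = 1, N = 10, n_channels = 5) {
  init_network(seed, N = N, p_exc = 0.8, n_channels = n_channels)
}

.cache <- new.env(parent = emptyenv())

# Full-size ensemble at study defaults, shared across acceptance tests.
acceptance_ensemble <- function() {
  if (is.null(.cache$ens)) {
    .cache$ens <- run_ensemble(
      n_networks = 12, master_seed = 20261002,
      n_eval_trials = 2048, selectivity_trials = 1024)
  }
  .cache$ens
}

# Independent brute-force transcription of the rate-based selectivity rule
# list (precedence: silent, hyper, modality/choice with strict side
# separation, mixed via the 2nd-3rd gap), used as the classifier oracle.
oracle_classify <- function(r, fx) {
  ah <- r[1]; al <- r[2]; vh <- r[3]; vl <- r[4]
  below <- c(ah, al, vh, vl) < fx
  if (sum(below) == 4) return("silent")
  if (sum(below) == 3) return("hyper")
  mod_sep <- (min(ah, al) > max(vh, vl)) || (min(vh, vl) > max(ah, al))
  cho_sep <- (min(ah, vh) > max(al, vl)) || (min(al, vl) > max(ah, vh))
  if (!mod_sep && !cho_sep) return("unclassified")
  mod_diff <- abs((ah + al) / 2 - (vh + vl) / 2)
  cho_diff <- abs((ah + vh) / 2 - (al + vl) / 2)
  primary <- if (mod_sep && cho_sep) {
    if (mod_diff >= cho_diff) "modality" else "choice"
  } else if (mod_sep) "modality" else "choice"
  s <- sort(c(ah, al, vh, vl), decreasing = TRUE)
  other <- if (primary == "modality") cho_diff else mod_diff
  if (other > s[2] - s[3]) "mixed" else primary
}

# The fitted dale_rnn objects of the converged ensemble networks.
acceptance_fits <- function() {
  ens <- acceptance_ensemble()
  ens$fits[ens$networks$converged]
}
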