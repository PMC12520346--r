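# The brute-force oracle lives in helper-dalernn.R (shared with the
# acceptance suite).

test_that("rate classifier equals the oracle on an exhaustive grid", {
  vals <- c(0, 0.25, 0.5, 0.75, 1)
  grid <- expand.grid(ah = vals, al = vals, vh = vals, vl = vals,
                      fx = c(0.1, 0.6))
  for (i in seq_len(nrow(grid))) {
    r <- c(aud_high = grid$ah[i], aud_low = grid$al[i],
           vis_high = grid$vh[i], vis_low = grid$vl[i])
    expect_identical(classify_rate_based(r, grid$fx[i]),
                     oracle_classify(unname(r), grid$fx[i]),
                     label = paste(r, collapse = ","))
  }
})

test_that("rate classifier handles canonical textbook cases", {
  fx <- 0.05
  # both auditory conditions above both visual: modality
  expect_equal(classify_rate_based(
    c(aud_high = 0.9, aud_low = 0.8, vis_high = 0.3, vis_low = 0.2), fx),
    "modality")
  # both high-choice conditions above both low: choice
  expect_equal(classify_rate_based(
    c(aud_high = 0.9, aud_low = 0.3, vis_high = 0.8, vis_low = 0.2), fx),
    "choice")
  # all four below fixation max: silent
  expect_equal(classify_rate_based(
    c(aud_high = 0.01, aud_low = 0.02, vis_high = 0.03, vis_low = 0.01),
    0.5), "silent")
  # exactly one above: hyper
  expect_equal(classify_rate_based(
    c(aud_high = 0.9, aud_low = 0.02, vis_high = 0.03, vis_low = 0.01),
    0.5), "hyper")
  # modality separation with a large choice difference: mixed
  expect_equal(classify_rate_based(
    c(aud_high = 1.0, aud_low = 0.45, vis_high = 0.4, vis_low = 0.05), fx),
    "mixed")
  # ties defeat strict separation: unclassified
  expect_equal(classify_rate_based(
    c(aud_high = 0.5, aud_low = 0.5, vis_high = 0.5, vis_low = 0.5), fx),
    "unclassified")
  # missing condition rates: unclassified
  expect_equal(classify_rate_based(
    c(aud_high = NA, aud_low = 0.5, vis_high = 0.5, vis_low = 0.5), fx),
    "unclassified")
})

test_that("AUC helper reproduces the rank-based Mann-Whitney statistic", {
  v <- c(1, 2, 3, 4, 5, 6)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(dalernn:::auc_binary(v, lab), 1)       # perfect separation
  expect_equal(dalernn:::auc_binary(v, !lab), 0)
  expect_equal(dalernn:::auc_binary(rep(1, 6), lab), 0.5)  # all tied
  # agrees with wilcox.test statistic / (n1 n0)
  set.seed(9)
  v <- rnorm(40); lab <- rep(c(TRUE, FALSE), 20)
  w <- suppressWarnings(wilcox.test(v[lab], v[!lab]))$statistic
  expect_equal(dalernn:::auc_binary(v, lab), unname(w) / (20 * 20))
  expect_true(is.na(dalernn:::auc_binary(v, rep(TRUE, 40))))
})

test_that("condition rates and both classifiers run on a trained network", {
  fits <- acceptance_fits()
  skip_if(length(fits) == 0, "no converged network available")
  cr <- condition_rates(fits[[1]], n_trials = 512, seed = 3, dt_ms = 20)
  expect_s3_class(cr, "condition_rates")
  expect_equal(colnames(cr$rates),
               c("aud_high", "aud_low", "vis_high", "vis_low"))
  expect_equal(nrow(cr$rates), 150)
  expect_true(all(cr$rates >= 0, na.rm = TRUE))
  expect_true(sum(cr$n_per_condition) <= 512)
  tab <- selectivity_table(cr)
  expect_equal(nrow(tab), 150)
  expect_true(all(tab$label %in% c("modality", "choice", "mixed", "silent",
                                   "hyper", "unclassified")))
  expect_equal(tab$is_excitatory, rep(c(TRUE, FALSE), c(120, 30)))
  counts <- count_by_group(tab)
  expect_equal(sum(counts), 150)
  roc <- selectivity_table(cr, method = "roc", n_shuffles = 100, seed = 1)
  expect_true(all(roc$label %in% c("modality", "choice", "mixed",
                                   "unselective")))
})

test_that("ROC classifier flags constructed selective units", {
  # build a fake condition_rates object with known per-trial structure
  n <- 200
  set.seed(11)
  cond <- sample(rep(c("aud_high", "aud_low", "vis_high", "vis_low"),
                     n / 4))
  is_high <- cond %in% c("aud_high", "vis_high")
  is_aud <- cond %in% c("aud_high", "aud_low")
  tr <- rbind(
    choice_unit = ifelse(is_high, 1, 0) + rnorm(n, 0, 0.1),
    modality_unit = ifelse(is_aud, 1, 0) + rnorm(n, 0, 0.1),
    mixed_unit = ifelse(is_high, 1, 0) + ifelse(is_aud, 0.8, 0) +
      rnorm(n, 0, 0.1),
    flat_unit = rnorm(n, 0, 0.1),
    dead_unit = rep(0, n))
  cr <- structure(list(trial_rates = tr, trial_condition = cond),
                  class = "condition_rates")
  lab <- classify_roc(cr, n_shuffles = 200, seed = 2)
  expect_equal(lab, c("choice", "modality", "mixed", "unselective",
                      "unselective"))
})
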