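test_that("target groups resolve to the expected neuron sets", {
  p <- init_network(1, N = 20)
  expect_equal(resolve_target(p, "all"), 1:20)
  expect_equal(resolve_target(p, "excitatory"), 1:16)
  expect_equal(resolve_target(p, "inhibitory"), 17:20)
  seltab <- data.frame(neuron = 1:20,
                       label = rep(c("choice", "silent", "mixed", "hyper"),
                                   5))
  expect_equal(resolve_target(p, "choice", seltab),
               which(seltab$label == "choice"))
  expect_equal(resolve_target(p, "mixed", seltab),
               which(seltab$label == "mixed"))
  expect_error(resolve_target(p, "choice"))       # label group needs table
  expect_error(resolve_target(p, "nonsense"))
})

test_that("lesioning clamps the targeted rates to exactly zero", {
  p <- tiny_network(4)
  b <- make_batch(tiny_task(), 6, seed = 2, tau_ms = p$tau_ms)
  target <- c(2, 5, 9)
  rec <- run_trials(p, b, seed = 3, rates = TRUE,
                    perturb = list(mode = "lesion", target = target))
  expect_true(all(rec$rates[target, , ] == 0))
  expect_true(any(rec$rates[-target, , ] > 0))
})

test_that("modulation adds current to targeted neurons only", {
  p <- tiny_network(4)
  p$sigma_rec <- 0                                   # isolate the bias term
  b <- make_batch(tiny_task(sigma_in = 0), 4, seed = 2, tau_ms = p$tau_ms)
  base <- run_trials(p, b, seed = 3, rates = TRUE)
  pert <- run_trials(p, b, seed = 3, rates = TRUE,
                     perturb = list(mode = "modulate", target = c(1, 3),
                                    b_per = 0.2, sigma_per = 0))
  # first step: only targeted neurons can differ (recurrence spreads later)
  expect_true(all(abs(pert$rates[c(2, 4:10), , 1] -
                        base$rates[c(2, 4:10), , 1]) < 1e-12))
  alpha <- b$dt_ms / p$tau_ms
  # the voltage bump at step 1 is exactly alpha * b_per where x > 0
  d1 <- pert$rates[1, , 1] - base$rates[1, , 1]
  expect_true(all(d1 >= 0 & d1 <= alpha * 0.2 + 1e-12))
})

test_that("an empty target set reproduces the baseline exactly", {
  p <- tiny_network(6)
  b <- make_batch(tiny_task(), 4, seed = 1, tau_ms = p$tau_ms)
  base <- run_trials(p, b, seed = 9)
  expect_warning(
    pert <- run_trials(p, b, seed = 9,
                       perturb = list(mode = "modulate", target = integer(0),
                                      b_per = 0.2, sigma_per = 0.01)))
  expect_identical(pert$outputs, base$outputs)
})

test_that("baseline and perturbed arms share stimuli and shared noise", {
  fits <- acceptance_fits()
  skip_if(length(fits) == 0, "no converged network available")
  # 64 trials can leave a psychometric point empty; that warning is expected
  ex <- suppressWarnings(
    perturbation_experiment(fits[[1]], group = 1:5, mode = "modulate",
                            n_trials = 64, seed = 4, dt_ms = 20))
  expect_s3_class(ex, "perturbation_experiment")
  # same trial conditions in both arms
  expect_identical(ex$baseline_decisions$frequency,
                   ex$perturbed_decisions$frequency)
  expect_identical(ex$baseline_decisions$modality,
                   ex$perturbed_decisions$modality)
  expect_equal(nrow(ex$baseline_decisions), 64)
  expect_output(print(ex), "Modulation")
})

test_that("perturbation target indices are validated", {
  p <- tiny_network(2)
  b <- make_batch(tiny_task(), 2, seed = 1, tau_ms = p$tau_ms)
  expect_error(run_trials(p, b, seed = 1,
                          perturb = list(mode = "lesion", target = 99)))
  expect_error(run_trials(p, b, seed = 1,
                          perturb = list(mode = "lesion", target = 0)))
})

test_that("compare_conditions classifies effects with Holm correction", {
  mk <- function(a, b, rt)
    structure(list(pooled = list(a = a, b = b), mean_rt_ms = rt),
              class = "behavior_summary")
  base <- lapply(1:8, function(i) mk(2 + 0.1 * i, 0.5, 500 + 5 * i))
  # strong consistent improvement: slope up, bias toward 0, RT down
  pert <- lapply(1:8, function(i) mk(3 + 0.1 * i, 0.1, 430 + 5 * i))
  out <- compare_conditions(base, pert, seed = 2)
  expect_equal(out$metric, c("slope", "bias", "mean_rt_ms"))
  expect_equal(out$effect, rep("improved", 3))
  expect_true(all(out$p_adj >= out$p_raw))
  # no change when arms are identical
  out2 <- compare_conditions(base, base, seed = 2)
  expect_equal(out2$effect, rep("no_change", 3))
  expect_error(compare_conditions(base, pert[-1]))
})
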