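test_that("task configuration validates and reports the trial geometry", {
  cfg <- task_config()
  expect_s3_class(cfg, "task_config")
  expect_equal(n_timesteps(cfg), 55L)        # (100 + 1000) / 20
  expect_equal(onset_index(cfg), 5L)         # 100 / 20
  expect_equal(n_timesteps(cfg, dt_ms = 2), 550L)
  expect_equal(onset_index(cfg, dt_ms = 2), 50L)
  expect_error(task_config(f_min = 16, f_max = 9))
  expect_error(task_config(dt_ms = 0))
  expect_error(task_config(fixation_ms = -1))
})

test_that("frequency encoding is the linear two-channel code", {
  cfg <- task_config()
  expect_equal(unname(encode_frequency(9, cfg)), c(0, 1))
  expect_equal(unname(encode_frequency(16, cfg)), c(1, 0))
  expect_equal(unname(encode_frequency(12.5, cfg)), c(0.5, 0.5))
  # amp_pos = (f - 9) / 7 for the default band
  for (f in 9:16)
    expect_equal(encode_frequency(f, cfg)[["amp_pos"]], (f - 9) / 7)
  expect_error(encode_frequency(8, cfg))
  expect_error(encode_frequency(17, cfg))
})

test_that("targets and loss mask follow the trial epochs", {
  cfg <- task_config()
  tg <- dalernn:::make_targets(cfg, frequency = c(9, 16))
  expect_equal(dim(tg$targets), c(2, 2, 55))
  # fixation: both outputs low
  expect_true(all(tg$targets[, , 1:5] == 0.2))
  # stimulus: correct output high, other low (9 Hz -> low, 16 Hz -> high)
  expect_true(all(tg$targets[1, 1, 6:55] == 1.0))
  expect_true(all(tg$targets[2, 1, 6:55] == 0.2))
  expect_true(all(tg$targets[2, 2, 6:55] == 1.0))
  expect_true(all(tg$targets[1, 2, 6:55] == 0.2))
  # grace window: zeros at the first 10 stimulus steps (200 ms / 20 ms)
  expect_equal(tg$loss_mask, c(rep(1, 5), rep(0, 10), rep(1, 40)))
})

test_that("generated inputs satisfy the batch invariants", {
  cfg <- task_config()
  b <- make_batch(cfg, 64, seed = 11)
  expect_s3_class(b, "trial_batch")
  expect_equal(dim(b$inputs), c(5, 64, 55))
  expect_true(all(b$inputs >= 0))                    # rectification
  expect_true(all(b$modality %in%
                    c("visual", "auditory", "multisensory")))
  expect_true(all(b$frequency %in% 9:16))
  expect_equal(b$correct_choice, ifelse(b$frequency > 12.5, "high", "low"))
  expect_equal(sum(b$condition_counts), 64)
})

test_that("tuned channels carry the stimulus only in the active modality", {
  cfg <- task_config(sigma_in = 0)                   # noiseless: exact values
  b <- make_batch(cfg, 3, seed = 1,
                  modality = c("visual", "auditory", "multisensory"),
                  frequency = c(16, 16, 16))
  on <- onset_index(cfg) + 1
  # channel order: vis+, vis-, aud+, aud-, cue
  expect_equal(b$inputs[1, 1, on], 0.2 + 1)          # u0 + amp_pos(16)
  expect_equal(b$inputs[2, 1, on], 0.2 + 0)
  expect_equal(b$inputs[3, 1, on], 0.2)              # inactive modality
  expect_equal(b$inputs[1, 2, on], 0.2)
  expect_equal(b$inputs[3, 2, on], 0.2 + 1)
  expect_equal(b$inputs[1, 3, on], 0.2 + 1)          # multisensory: both
  expect_equal(b$inputs[3, 3, on], 0.2 + 1)
  # fixation: all stimulus channels at baseline, cue off
  expect_true(all(b$inputs[1:4, , 1:5] == 0.2))
  expect_true(all(b$inputs[5, , 1:5] == 0))
  expect_true(all(b$inputs[5, , on:55] == 1))        # cue on during stimulus
})

test_that("batch generation is reproducible and seed-sensitive", {
  cfg <- task_config()
  b1 <- make_batch(cfg, 16, seed = 5)
  b2 <- make_batch(cfg, 16, seed = 5)
  b3 <- make_batch(cfg, 16, seed = 6)
  expect_identical(b1$inputs, b2$inputs)
  expect_false(identical(b1$inputs, b3$inputs))
})

test_that("condition sampling is uniform over the 24 conditions", {
  cfg <- task_config()
  b <- make_batch(cfg, 6000, seed = 3)
  counts <- as.vector(b$condition_counts)
  expect_length(counts, 24)
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 1e-4)
})

test_that("task config round-trips through YAML", {
  cfg <- task_config(f_min = 10, stimulus_ms = 800, cue_amp = 0.5)
  path <- tempfile(fileext = ".yaml")
  write_task_config(cfg, path)
  expect_equal(read_task_config(path), cfg)
  unlink(path)
})

test_that("condition manifest exports one labeled row per trial", {
  b <- make_batch(task_config(), 8, seed = 2)
  path <- tempfile(fileext = ".csv")
  export_condition_manifest(b, path)
  m <- read.csv(path)
  expect_equal(nrow(m), 8)
  expect_equal(m$frequency, b$frequency)
  expect_equal(m$modality, b$modality)
  unlink(path)
})

test_that("single-trial view matches the batch layout", {
  tr <- make_trial(task_config(), "visual", 14, seed = 9)
  expect_equal(dim(tr$inputs), c(55, 5))
  expect_equal(dim(tr$targets), c(55, 2))
  expect_true(all(tr$inputs >= 0))
})
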