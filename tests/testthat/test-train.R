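test_that("compute_loss matches the masked-mean definition", {
  # 1 trial, 2 steps, 2 outputs, error 0.1 everywhere, full mask -> 0.01
  z <- matrix(0.1, 2, 2)
  tg <- matrix(0, 2, 2)
  expect_equal(compute_loss(z, tg, mask = c(1, 1)), 0.01)
  # outputs identical to targets -> 0
  expect_equal(compute_loss(tg, tg, mask = c(1, 1)), 0)
  # all-zero mask -> 0 even with nonzero error
  expect_equal(compute_loss(z, tg, mask = c(0, 0)), 0)
  # masked timepoints keep the full denominator
  expect_equal(compute_loss(z, tg, mask = c(1, 0)), 0.005)
  # L2 penalty term
  p <- tiny_network(1)
  pen <- sum(p$W_rec^2) + sum(p$b_rec^2) + sum(p$b_inp^2) + sum(p$b_out^2)
  expect_equal(compute_loss(z, tg, c(1, 1), params = p, lambda = 0.1),
               0.01 + 0.1 * pen)
})

test_that("BPTT gradients match finite differences", {
  p <- tiny_network(4, N = 10)
  cfg <- tiny_task()
  b <- make_batch(cfg, 3, seed = 2, tau_ms = p$tau_ms)
  alpha <- cfg$dt_ms / p$tau_ms
  mask <- b$loss_mask
  seed <- 31
  g <- dalernn:::cpp_bptt_grads(p$W_in, p$W_rec, p$W_out, p$b_rec, p$b_inp,
                                p$b_out, p$n_exc, b$inputs, b$targets, mask,
                                alpha, p$sigma_rec, seed)
  loss_at <- function(q) {
    dalernn:::cpp_bptt_grads(q$W_in, q$W_rec, q$W_out, q$b_rec, q$b_inp,
                             q$b_out, q$n_exc, b$inputs, b$targets, mask,
                             alpha, q$sigma_rec, seed)$loss
  }
  eps <- 1e-6
  # spot-check a grid of W_rec entries and all bias entries
  for (idx in list(c(1, 1), c(2, 5), c(10, 10), c(5, 2), c(3, 9))) {
    q1 <- p; q1$W_rec[idx[1], idx[2]] <- q1$W_rec[idx[1], idx[2]] + eps
    q2 <- p; q2$W_rec[idx[1], idx[2]] <- q2$W_rec[idx[1], idx[2]] - eps
    fd <- (loss_at(q1) - loss_at(q2)) / (2 * eps)
    expect_equal(g$gWrec[idx[1], idx[2]], fd, tolerance = 1e-4)
  }
  for (i in 1:10) {
    q1 <- p; q1$b_rec[i] <- q1$b_rec[i] + eps
    q2 <- p; q2$b_rec[i] <- q2$b_rec[i] - eps
    expect_equal(g$gb_rec[i], (loss_at(q1) - loss_at(q2)) / (2 * eps),
                 tolerance = 1e-4)
  }
  for (i in 1:2) {
    q1 <- p; q1$b_out[i] <- q1$b_out[i] + eps
    q2 <- p; q2$b_out[i] <- q2$b_out[i] - eps
    expect_equal(g$gb_out[i], (loss_at(q1) - loss_at(q2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("training updates only the trainable parameters", {
  p <- tiny_network(2, N = 10)
  cfg <- tiny_task()
  res <- train_network(p, cfg, train_config(max_epochs = 50,
                                            validate_every = 50,
                                            validation_size = 32), seed = 1)
  q <- res$params
  expect_identical(q$W_in, p$W_in)      # frozen, bitwise
  expect_identical(q$W_out, p$W_out)    # frozen, bitwise
  expect_false(identical(q$W_rec, p$W_rec))
  expect_false(identical(q$b_rec, p$b_rec))
  expect_false(identical(q$b_out, p$b_out))
})

test_that("Dale compliance holds after training", {
  p <- init_network(5, N = 20)
  res <- train_network(p, tiny_task(),
                       train_config(max_epochs = 100, validate_every = 100,
                                    validation_size = 32), seed = 4)
  expect_true(dale_compliant(res$params))
})

test_that("training loss decreases over the first validations", {
  # smoke property over several seeds at reduced size
  drops <- vapply(1:5, function(s) {
    p <- init_network(s, N = 40)
    res <- train_network(p, task_config(),
                         train_config(max_epochs = 300, validate_every = 100,
                                      validation_size = 64), seed = s)
    h <- res$history
    h$loss[nrow(h)] < h$loss[1]
  }, logical(1))
  expect_gte(mean(drops), 0.8)
})

test_that("validation computes valid and correct fractions", {
  p <- tiny_network(3)
  v <- validate_network(p, tiny_task(), n_trials = 128, seed = 2)
  expect_true(v$valid_fraction >= 0 && v$valid_fraction <= 1)
  # correct fraction is undefined (NA) when no trial is valid
  expect_true(is.na(v$correct_fraction) ||
                (v$correct_fraction >= 0 && v$correct_fraction <= 1))
  expect_error(validate_network(p, tiny_task(), n_trials = 0))
})

test_that("the fitter returns a complete classed model object", {
  fit <- dale_rnn(task = tiny_task(),
                  control = train_config(max_epochs = 100,
                                         validate_every = 100,
                                         validation_size = 32),
                  n_neurons = 20, seed = 1)
  expect_s3_class(fit, "dale_rnn")
  expect_named(coef(fit), c("W_in", "W_rec", "W_out", "b_rec", "b_inp",
                            "b_out"))
  expect_output(print(fit), "rate RNN")
  expect_output(print(summary(fit)), "epochs")
  rec <- simulate(fit, nsim = 8, seed = 2)
  expect_s3_class(rec, "trial_records")
  expect_equal(dim(rec$outputs)[2], 8)
  dec <- predict(fit, seed = 3,
                 batch = make_batch(fit$task, 16, seed = 3))
  expect_equal(nrow(dec), 16)
  # deterministic refit
  fit2 <- dale_rnn(task = tiny_task(),
                   control = train_config(max_epochs = 100,
                                          validate_every = 100,
                                          validation_size = 32),
                   n_neurons = 20, seed = 1)
  expect_equal(fit2$params$W_rec, fit$params$W_rec, tolerance = 0)
})
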