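# Build a synthetic T x 2 output trajectory with a controlled crossing.
make_z <- function(T_all, cross_step = NA, sign = +1, gap = 0.5) {
  z <- matrix(0.2, T_all, 2)
  if (!is.na(cross_step)) z[cross_step:T_all, 2] <- 0.2 + sign * gap
  z
}

test_that("decision extraction follows the first-crossing rule", {
  on <- 5; dt <- 20
  # valid high decision at step 12
  d <- extract_decision(make_z(55, 12), onset_index = on, dt_ms = dt)
  expect_equal(d$status, "valid")
  expect_equal(d$choice, "high")
  expect_equal(d$decision_step, 12)
  expect_equal(d$rt_ms, (12 - 1 - on) * dt + 200)
  # low decision
  d <- extract_decision(make_z(55, 12, sign = -1), onset_index = on,
                        dt_ms = dt)
  expect_equal(d$choice, "low")
  # crossing before onset invalidates
  d <- extract_decision(make_z(55, 3), onset_index = on, dt_ms = dt)
  expect_equal(d$status, "invalid_pre_stimulus")
  expect_true(is.na(d$rt_ms))
  # no crossing at all
  d <- extract_decision(make_z(55), onset_index = on, dt_ms = dt)
  expect_equal(d$status, "no_decision")
  # separation exactly at threshold does not count (strict >)
  z <- make_z(55, 12, gap = 0.2)
  expect_equal(extract_decision(z, onset_index = on, dt_ms = dt)$status,
               "no_decision")
  expect_error(extract_decision(z, threshold = 0, onset_index = on,
                                dt_ms = dt))
})

test_that("the compiled decision table agrees with the R extractor", {
  p <- tiny_network(7)
  b <- make_batch(tiny_task(), 32, seed = 5, tau_ms = p$tau_ms)
  rec <- run_trials(p, b, seed = 6)
  tab <- decision_table(rec)
  expect_equal(nrow(tab), 32)
  for (i in seq_len(32)) {
    d <- extract_decision(t(rec$outputs[, i, ]),
                          onset_index = rec$onset_index,
                          dt_ms = rec$dt_ms)
    expect_equal(tab$status[i], d$status)
    if (d$status == "valid") {
      expect_equal(tab$choice[i], d$choice)
      expect_equal(tab$rt_ms[i], d$rt_ms)
    }
  }
  # correctness only for valid trials matching the condition label
  ok <- tab$status == "valid"
  expect_equal(tab$correct[ok], (tab$choice == rec$correct_choice)[ok])
  expect_true(all(!tab$correct[!ok]))
})

test_that("psychometric points use valid trials and center frequencies", {
  dec <- data.frame(
    x = rep(c(-1.5, 1.5), each = 4),
    status = c("valid", "valid", "valid", "no_decision",
               rep("valid", 4)),
    choice = c("high", "low", "low", NA, "high", "high", "high", "low"))
  pts <- psychometric_points(dec)
  expect_equal(pts$x, c(-1.5, 1.5))
  expect_equal(pts$frac_high, c(1 / 3, 3 / 4))
  expect_equal(pts$n, c(3, 4))
})

test_that("sigmoid fitting recovers known parameters", {
  xs <- seq(-3.5, 3.5, by = 1)
  a_true <- 1.8; b_true <- 0.4
  pts <- data.frame(x = xs,
                    frac_high = 1 / (1 + exp(-a_true * (xs - b_true))),
                    n = 100)
  f <- fit_sigmoid(pts)
  expect_true(f$converged)
  expect_equal(f$a, a_true, tolerance = 1e-4)
  expect_equal(f$b, b_true, tolerance = 1e-4)
  # grid-search oracle agrees on noisy data
  set.seed(1)
  pts$frac_high <- pmin(pmax(pts$frac_high +
                               rnorm(length(xs), 0, 0.03), 0), 1)
  f2 <- fit_sigmoid(pts)
  grid <- expand.grid(a = seq(0.2, 5, by = 0.02),
                      b = seq(-2, 2, by = 0.02))
  sse <- mapply(function(a, b)
    sum((pts$frac_high - 1 / (1 + exp(-a * (pts$x - b))))^2),
    grid$a, grid$b)
  best <- grid[which.min(sse), ]
  expect_equal(f2$a, best$a, tolerance = 0.05)
  expect_equal(f2$b, best$b, tolerance = 0.05)
  expect_lte(sum((pts$frac_high -
                    1 / (1 + exp(-f2$a * (pts$x - f2$b))))^2), min(sse))
})

test_that("lapse-variant fit recovers lapse rates within bounds", {
  xs <- seq(-3.5, 3.5, by = 0.5)
  gl <- 0.1; gr <- 0.05; a_true <- 2; b_true <- -0.3
  pts <- data.frame(
    x = xs,
    frac_high = (1 - gr - gl) / (1 + exp(-a_true * (xs - b_true))) + gr,
    n = 100)
  f <- fit_sigmoid_lapse(pts)
  expect_true(f$converged)
  expect_equal(f$a, a_true, tolerance = 0.01)
  expect_equal(f$gamma_r, gr, tolerance = 0.01)
  expect_equal(f$gamma_l, gl, tolerance = 0.01)
  expect_true(f$gamma_r >= 0 && f$gamma_r <= 0.5)
  expect_true(f$gamma_l >= 0 && f$gamma_l <= 0.5)
})

test_that("chronometric summaries average correct trials only", {
  dec <- data.frame(x = c(-2, 2, 2, 1), status = "valid",
                    choice = c("low", "high", "high", "low"),
                    rt_ms = c(300, 400, 500, 900),
                    correct = c(TRUE, TRUE, TRUE, FALSE))
  ch <- chronometric_points(dec)
  expect_equal(ch$abs_x, 2)              # only |x| = 2 has correct trials
  expect_equal(ch$mean_rt_ms, 400)       # (300 + 400 + 500) / 3
  expect_equal(ch$n, 3L)
  expect_equal(mean_rt(dec), 400)
  empty <- dec[dec$correct == FALSE & FALSE, ]
  expect_warning(out <- mean_rt(empty))
  expect_true(is.na(out))
})

test_that("strategy labels use strict ensemble-mean splits", {
  mk <- function(rt, a)
    structure(list(mean_rt_ms = rt, pooled = list(a = a)),
              class = "behavior_summary")
  s <- list(mk(400, 3), mk(500, 1), mk(600, 2))
  lab <- label_strategies(s)            # mean rt 500, mean slope 2
  expect_equal(lab$speed, c("fast", "slow", "slow"))     # 500 is not < 500
  expect_equal(lab$accuracy, c("accurate", "inaccurate",
                               "inaccurate"))            # 2 is not > 2
  expect_error(label_strategies(s[1]))
})

test_that("behavior summary assembles per-modality and pooled fits", {
  fits <- acceptance_fits()
  skip_if(length(fits) == 0, "no converged network available")
  s <- behavior_summary(simulate(fits[[1]], nsim = 1024, seed = 5))
  expect_s3_class(s, "behavior_summary")
  expect_named(s$fits, c("visual", "auditory", "multisensory"))
  expect_true(s$valid_fraction > 0.5)
  expect_true(is.finite(s$pooled$a))
  expect_true(is.finite(s$mean_rt_ms))
  expect_output(print(s), "pooled")
})
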