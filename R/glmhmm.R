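#' Simulate choices from a GLM-HMM
#'
#' Draws a latent Markov state path from `(pi, A)` and, in each state `k`,
#' a Bernoulli choice with success probability
#' `plogis(X %*% w_k)`. Used for parameter-recovery testing of
#' [glmhmm()].
#'
#' @param params List with `A` (`K x K` row-stochastic transition matrix),
#'   `w` (`K x M` per-state weights), `pi` (initial distribution).
#' @param X Covariate matrix `n x M` (e.g. signed stimulus strength and a
#'   constant bias column).
#' @param seed Integer seed.
#' @return List with `choices` (0/1 vector) and `states` (1-based).
#' @export
simulate_glmhmm <- function(params, X, seed = 1) {
  K <- nrow(params$A)
  stopifnot(ncol(params$A) == K, nrow(params$w) == K,
            ncol(X) == ncol(params$w), length(params$pi) == K,
            all(abs(rowSums(params$A) - 1) < 1e-8),
            abs(sum(params$pi) - 1) < 1e-8)
  n <- nrow(X)
  set.seed(derive_seed(seed, "hmmsim"))
  states <- integer(n)
  states[1] <- sample.int(K, 1, prob = params$pi)
  for (t in seq_len(n - 1))
    states[t + 1] <- sample.int(K, 1, prob = params$A[states[t], ])
  p <- plogis(rowSums(X * params$w[states, , drop = FALSE]))
  list(choices = rbinom(n, 1, p), states = states)
}

# Penalized weighted logistic log-likelihood + damped Newton update; the
# Gaussian prior sd bounds the weights when a state captures few trials,
# and step halving guards against divergence on near-separable data.
fit_weighted_logistic <- function(X, y, w_obs, w0, prior_sd, max_iter = 50) {
  M <- ncol(X)
  obj <- function(w) {
    eta <- as.numeric(X %*% w)
    sum(w_obs * (y * eta - log1p(exp(pmin(eta, 700))))) -
      sum(w^2) / (2 * prior_sd^2)
  }
  w <- w0
  f <- obj(w)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% w)
    p <- plogis(eta)
    grad <- as.numeric(crossprod(X, w_obs * (y - p))) - w / prior_sd^2
    W <- w_obs * p * (1 - p)
    H <- crossprod(X, X * W) + diag(1 / prior_sd^2, M)
    step <- tryCatch(solve(H, grad), error = function(e) grad * 0)
    # backtrack until the penalized objective does not decrease
    t_scale <- 1
    repeat {
      w_new <- w + t_scale * step
      f_new <- obj(w_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      t_scale <- t_scale / 2
      if (t_scale < 1e-8) { w_new <- w; f_new <- f; break }
    }
    if (max(abs(w_new - w)) < 1e-8) { w <- w_new; break }
    w <- w_new
    f <- f_new
  }
  w
}

# Per-trial emission likelihoods, n x K.
glmhmm_emissions <- function(X, choices, w) {
  eta <- X %*% t(w)                       # n x K
  p <- plogis(eta)
  ifelse(matrix(choices, nrow(p), ncol(p)) == 1, p, 1 - p)
}

# Scaled forward-backward. Returns gamma (n x K), xi_sum (K x K), loglik.
glmhmm_forward_backward <- function(emis, A, pi0) {
  n <- nrow(emis); K <- ncol(emis)
  a <- matrix(0, n, K); b <- matrix(0, n, K); cval <- numeric(n)
  a[1, ] <- pi0 * emis[1, ]
  cval[1] <- sum(a[1, ]); a[1, ] <- a[1, ] / cval[1]
  for (t in seq_len(n - 1)) {
    a[t + 1, ] <- (a[t, ] %*% A) * emis[t + 1, ]
    cval[t + 1] <- sum(a[t + 1, ])
    a[t + 1, ] <- a[t + 1, ] / cval[t + 1]
  }
  b[n, ] <- 1
  for (t in seq(n - 1, 1, length.out = max(n - 1, 0))) {
    b[t, ] <- as.numeric(A %*% (emis[t + 1, ] * b[t + 1, ])) / cval[t + 1]
  }
  gamma <- a * b
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  for (t in seq_len(n - 1)) {
    m <- (a[t, ] %o% (emis[t + 1, ] * b[t + 1, ])) * A / cval[t + 1]
    xi <- xi + m
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cval)))
}

#' Fit a GLM-HMM to a choice sequence by MAP-EM
#'
#' Infers the transition matrix, per-state logistic choice weights and
#' initial state distribution of a hidden Markov model whose emissions are
#' per-state logistic regressions of the binary choice on trial covariates.
#' Estimation is maximum a posteriori via EM (forward-backward E-step;
#' penalized weighted-logistic and Dirichlet-regularized transition
#' M-steps), with multiple random restarts. Priors: a sticky Dirichlet on
#' each transition row (concentration `dir_alpha` plus `dir_kappa` on the
#' diagonal, favoring state persistence) and a zero-mean Gaussian with sd
#' `prior_sd` on the weights.
#'
#' @param choices Binary choice vector (1 = high).
#' @param X Covariate matrix `n x M`; by convention column 1 is the signed
#'   stimulus strength and column 2 a constant bias term.
#' @param K Number of latent states.
#' @param n_starts Random restarts; the best posterior wins.
#' @param max_iter,tol EM iteration budget and objective tolerance.
#' @param dir_alpha,dir_kappa,prior_sd Prior hyperparameters.
#' @param seed Integer seed.
#' @return An object of class `"glmhmm"`: `A`, `w` (`K x M`), `pi`,
#'   `logposterior`, `loglik`, `trace` (objective per EM iteration of the
#'   winning start), `K`, and the data dimensions.
#' @export
glmhmm <- function(choices, X, K = 3, n_starts = 20, max_iter = 200,
                   tol = 1e-4, dir_alpha = 1, dir_kappa = 10, prior_sd = 2,
                   seed = 1) {
  choices <- as.integer(choices)
  stopifnot(all(choices %in% 0:1), nrow(X) == length(choices), K >= 1)
  n <- length(choices); M <- ncol(X)
  log_prior <- function(A, w) {
    conc <- matrix(dir_alpha, K, K) + diag(dir_kappa, K)
    sum((conc - 1) * log(pmax(A, 1e-12))) + sum(dnorm(w, 0, prior_sd,
                                                      log = TRUE))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(derive_seed(seed, paste0("hmmstart", s)))
    w <- matrix(rnorm(K * M, 0, 1), K, M)
    A <- matrix(1, K, K) + diag(5, K)
    A <- A / rowSums(A)
    pi0 <- rep(1 / K, K)
    obj_trace <- numeric(0)
    obj_old <- -Inf
    for (it in seq_len(max_iter)) {
      emis <- glmhmm_emissions(X, choices, w)
      fb <- glmhmm_forward_backward(emis, A, pi0)
      obj <- fb$loglik + log_prior(A, w)
      obj_trace <- c(obj_trace, obj)
      if (is.finite(obj_old) && obj - obj_old < tol && it > 2) break
      obj_old <- obj
      # M-step
      conc <- matrix(dir_alpha, K, K) + diag(dir_kappa, K)
      Anew <- fb$xi + conc - 1
      Anew[Anew < 1e-12] <- 1e-12
      A <- Anew / rowSums(Anew)
      pi0 <- fb$gamma[1, ] + 1e-12
      pi0 <- pi0 / sum(pi0)
      for (k in seq_len(K))
        w[k, ] <- fit_weighted_logistic(X, choices, fb$gamma[, k], w[k, ],
                                        prior_sd)
    }
    if (is.null(best) || obj > best$logposterior) {
      best <- list(A = A, w = w, pi = pi0, logposterior = obj,
                   loglik = fb$loglik, trace = obj_trace)
    }
  }
  structure(c(best, list(K = K, n = n, M = M, choices = choices, X = X)),
            class = "glmhmm")
}

#' @export
print.glmhmm <- function(x, ...) {
  cat(sprintf("GLM-HMM: %d states, %d covariates, %d trials\n",
              x$K, x$M, x$n))
  cat(sprintf("  log posterior %.2f (log likelihood %.2f)\n",
              x$logposterior, x$loglik))
  cat("  state weights (rows = states):\n")
  print(round(x$w, 3))
  cat("  transition matrix:\n")
  print(round(x$A, 3))
  invisible(x)
}

#' @export
logLik.glmhmm <- function(object, ...) {
  structure(object$loglik, df = object$K * (object$K - 1) +
              object$K * object$M + object$K - 1, class = "logLik")
}

#' Posterior state probabilities
#'
#' Forward-backward smoothed probabilities of each latent state per trial.
#'
#' @param object A fitted [glmhmm()].
#' @param choices,X Optional new data (defaults to the training sequence).
#' @return Matrix `n x K`; rows sum to 1.
#' @export
posterior_states <- function(object, choices = NULL, X = NULL) {
  if (is.null(choices)) choices <- object$choices
  if (is.null(X)) X <- object$X
  emis <- glmhmm_emissions(X, as.integer(choices), object$w)
  glmhmm_forward_backward(emis, object$A, object$pi)$gamma
}

#' Exact HMM log-likelihood by path enumeration
#'
#' Brute-force sum over all `K^n` state paths; only feasible for very short
#' sequences. Serves as an independent check of the forward algorithm.
#'
#' @param params List with `A`, `w`, `pi`.
#' @param choices,X Data as in [glmhmm()].
#' @return Log-likelihood.
#' @export
glmhmm_loglik_bruteforce <- function(params, choices, X) {
  K <- nrow(params$A); n <- length(choices)
  if (K^n > 1e6) stop("sequence too long for enumeration")
  emis <- glmhmm_emissions(X, as.integer(choices), params$w)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- params$pi[s[1]] * emis[1, s[1]]
    for (t in seq_len(n - 1))
      pr <- pr * params$A[s[t], s[t + 1]] * emis[t + 1, s[t + 1]]
    tot <- tot + pr
  }
  log(tot)
}

#' Build GLM-HMM covariates from a decision table
#'
#' Trials without a valid decision are dropped (consistent with the
#' psychometric exclusions); covariates are the signed stimulus strength
#' `x = f - f_threshold` and a constant bias term.
#'
#' @param decisions A [decision_table()].
#' @return List with `choices` (1 = high) and `X` (`n x 2`).
#' @export
glmhmm_data <- function(decisions) {
  d <- decisions[decisions$status == "valid", ]
  list(choices = as.integer(d$choice == "high"),
       X = cbind(stimulus = d$x, bias = 1))
}
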