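#' Permutation test for a difference in means (independent samples)
#'
#' Tests the null hypothesis that the two samples come from the same
#' distribution, using the difference in means as the statistic. When the
#' number of distinct group relabelings `choose(nx + ny, nx)` does not
#' exceed `n_resamples` the null distribution is enumerated exhaustively and
#' the p-value is exact; otherwise Monte-Carlo resampling is used with the
#' observed statistic included in the null set (the `(k + 1)/(n + 1)`
#' convention, which avoids p = 0).
#'
#' @param x,y Numeric samples.
#' @param n_resamples Number of resamples (100,000 by default).
#' @param alternative `"two.sided"`, `"greater"` (mean(x) > mean(y)) or
#'   `"less"`.
#' @param seed Integer seed for the Monte-Carlo branch.
#' @return An object of class `"perm_test"`: `statistic` (mean(x) -
#'   mean(y)), `p_value`, `n_resamples`, `exact`, `test_kind`,
#'   `alternative`.
#' @export
perm_test_independent <- function(x, y, n_resamples = 1e5,
                                  alternative = c("two.sided", "greater",
                                                  "less"), seed = 1) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  nx <- length(x)
  pool <- c(x, y)
  obs <- mean(x) - mean(y)
  n_arr <- choose(length(pool), nx)
  if (n_arr <= n_resamples) {
    idx <- utils::combn(length(pool), nx)
    stats <- apply(idx, 2, function(i)
      mean(pool[i]) - mean(pool[-i]))
    p <- perm_pvalue(stats, obs, alternative, exact = TRUE)
    n_used <- ncol(idx)
    exact <- TRUE
  } else {
    set.seed(derive_seed(seed, "permind"))
    stats <- replicate(n_resamples, {
      i <- sample.int(length(pool), nx)
      mean(pool[i]) - mean(pool[-i])
    })
    p <- perm_pvalue(stats, obs, alternative, exact = FALSE)
    n_used <- n_resamples
    exact <- FALSE
  }
  structure(list(statistic = obs, p_value = p, n_resamples = n_used,
                 exact = exact, test_kind = "independent",
                 alternative = alternative), class = "perm_test")
}

#' Paired permutation test (sign-flip) for a difference in means
#'
#' Tests the null that within each pair the two observations are
#' exchangeable, by randomly flipping the signs of the paired differences.
#' Exhaustive over all `2^n` sign patterns when that does not exceed
#' `n_resamples`; Monte-Carlo with the `(k + 1)/(n + 1)` convention
#' otherwise.
#'
#' @param before,after Paired numeric samples of equal length.
#' @inheritParams perm_test_independent
#' @return A `"perm_test"` object; `statistic` is `mean(after - before)`.
#' @export
perm_test_paired <- function(before, after, n_resamples = 1e5,
                             alternative = c("two.sided", "greater", "less"),
                             seed = 1) {
  alternative <- match.arg(alternative)
  if (length(before) != length(after)) stop("paired samples differ in length")
  if (length(before) == 0) stop("samples must be non-empty")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  d <- after - before
  n <- length(d)
  obs <- mean(d)
  if (2^n <= n_resamples) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- as.numeric(signs %*% d) / n
    p <- perm_pvalue(stats, obs, alternative, exact = TRUE)
    n_used <- nrow(signs)
    exact <- TRUE
  } else {
    set.seed(derive_seed(seed, "permpair"))
    stats <- replicate(n_resamples,
                       mean(d * sample(c(-1, 1), n, replace = TRUE)))
    p <- perm_pvalue(stats, obs, alternative, exact = FALSE)
    n_used <- n_resamples
    exact <- FALSE
  }
  structure(list(statistic = obs, p_value = p, n_resamples = n_used,
                 exact = exact, test_kind = "paired",
                 alternative = alternative), class = "perm_test")
}

# Shared p-value computation with a tolerance guarding against ties lost to
# floating-point error.
perm_pvalue <- function(stats, obs, alternative, exact) {
  eps <- 1e-12 * max(1, abs(obs))
  ge <- sum(stats >= obs - eps)
  le <- sum(stats <= obs + eps)
  two <- sum(abs(stats) >= abs(obs) - eps)
  n <- length(stats)
  k <- switch(alternative, two.sided = two, greater = ge, less = le)
  if (exact) k / n else (k + 1) / (n + 1)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s permutation test (%s): diff in means = %.4g, p = %.4g\n",
              x$test_kind, if (x$exact) "exact" else
                sprintf("%d resamples", x$n_resamples),
              x$statistic, x$p_value))
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order, monotone and capped
#'   at 1.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Rank (Spearman) and Pearson correlation with p-values
#'
#' Thin wrappers returning the coefficient and two-sided p-value.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List with `estimate` and `p_value`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' @rdname rank_correlation
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' PCA trajectories of population activity
#'
#' Stacks the rate trajectories of correct trials into a
#' `(trials * time) x neurons` matrix, extracts the leading principal
#' components (centered, unscaled), and averages the projected trajectories
#' within each of the six modality-by-choice conditions.
#'
#' @param records A [run_trials()] result with `rates = TRUE`.
#' @param decisions The matching [decision_table()]; only correct trials
#'   enter.
#' @param n_components Number of components (3 by default).
#' @return An object of class `"trajectory_set"`: `trajectories` (array
#'   `conditions x time x components`), `condition` labels,
#'   `explained_variance` fractions, and the number of trials used.
#' @export
pca_trajectories <- function(records, decisions, n_components = 3) {
  if (is.null(records$rates)) stop("records lack rate trajectories")
  keep <- which(decisions$correct)
  if (length(keep) == 0) stop("no correct trials")
  r <- records$rates[, keep, , drop = FALSE]  # N x trials x T
  N <- dim(r)[1]; n <- dim(r)[2]; T_all <- dim(r)[3]
  flat <- matrix(aperm(r, c(2, 3, 1)), nrow = n * T_all, ncol = N)
  pc <- prcomp(flat, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  if (k < n_components)
    warning(sprintf("data rank supports only %d components", k))
  proj <- array(pc$x[, seq_len(k)], dim = c(n, T_all, k))
  mod <- decisions$modality[keep]
  cho <- decisions$choice[keep]
  conds <- expand.grid(modality = c("visual", "auditory", "multisensory"),
                       choice = c("low", "high"), stringsAsFactors = FALSE)
  traj <- array(NA_real_, dim = c(nrow(conds), T_all, k))
  for (ci in seq_len(nrow(conds))) {
    sel <- mod == conds$modality[ci] & cho == conds$choice[ci]
    if (any(sel))
      traj[ci, , ] <- apply(proj[sel, , , drop = FALSE], c(2, 3), mean)
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(trajectories = traj, condition = conds,
                 explained_variance = ev[seq_len(k)],
                 n_trials = length(keep)),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("PCA trajectories: %d conditions x %d steps, %d components\n",
              dim(x$trajectories)[1], dim(x$trajectories)[2],
              dim(x$trajectories)[3]))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}
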