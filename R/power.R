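#' Directional Bayes factor for a two-group mean difference
#'
#' Evidence that the second group's mean exceeds the first's, computed
#' under an improper flat prior on the mean difference with the pooled-
#' variance posterior t-distribution: BF = p / (1 - p) with
#' p = P(mu2 - mu1 > 0 | data). With prior odds 1:1, BF >= 19 is
#' equivalent to posterior probability >= 0.95.
#'
#' @param x,y Numeric samples of the two groups (first and second).
#' @return The directional Bayes factor (nonnegative, possibly `Inf`).
#' @export
directional_bf <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- stats::pt((mean(y) - mean(x)) / se, df)
  p / (1 - p)
}

#' Monte-Carlo Bayesian power for a two-condition design
#'
#' Simulates experiments with two conditions whose outcomes are standard
#' normal with a true mean difference `delta`, computes the directional
#' Bayes factor for the second mean exceeding the first in each simulated
#' experiment, and reports the fraction of simulations in which the Bayes
#' factor reaches `bf_threshold`. At the reference design (n = 129 per
#' condition, delta = 0.3, threshold 19) the power is about 0.78 and
#' matches the closed form \eqn{\Phi(\delta\sqrt{n/2} - z_{0.95})}.
#'
#' @param n_per_cond Observations per condition (>= 2).
#' @param delta True difference between the condition means (outcome SD 1).
#' @param n_sims Number of simulated experiments (default 500).
#' @param bf_threshold Bayes-factor success threshold (default 19).
#' @param seed Optional seed.
#' @return An object of class `power_result`: list with `power`,
#'   `n_per_condition`, `n_sims`, `bf_threshold`, `delta`, `seed`.
#' @export
bayes_power <- function(n_per_cond, delta, n_sims = 500L, bf_threshold = 19,
                        seed = NULL) {
  stopifnot(n_per_cond >= 2L, n_sims >= 1L, bf_threshold > 0)
  if (!is.null(seed)) set.seed(seed)
  hits <- vapply(seq_len(n_sims), function(i) {
    x <- stats::rnorm(n_per_cond)
    y <- stats::rnorm(n_per_cond, mean = delta)
    directional_bf(x, y) >= bf_threshold
  }, logical(1))
  structure(list(power = mean(hits), n_per_condition = as.integer(n_per_cond),
                 n_sims = as.integer(n_sims), bf_threshold = bf_threshold,
                 delta = delta, seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("Monte-Carlo Bayesian power: ", x$power, "\n",
      "  n per condition = ", x$n_per_condition,
      ", delta = ", x$delta, ", BF threshold = ", x$bf_threshold,
      ", simulations = ", x$n_sims, "\n", sep = "")
  invisible(x)
}

# Cohen's L: the noncentrality needed for the F test of u predictors to
# reach the target power at level alpha, in the large-error-df limit
# (noncentral chi-square), which is the convention behind the printed
# tables (u = 3, power .80 -> L = 10.90).
cohen_L <- function(u, power, alpha) {
  f <- function(l) {
    stats::pchisq(stats::qchisq(1 - alpha, u), u, ncp = l,
                  lower.tail = FALSE) - power
  }
  stats::uniroot(f, c(1e-8, 1000), tol = 1e-10)$root
}

#' Required sample size for multiple regression (Cohen's rule)
#'
#' Total sample size needed to detect an effect of size f-squared with
#' `n_predictors` predictors at the given alpha and power, using Cohen's
#' tabled noncentrality L: n = ceiling(L / f^2 + u). With three
#' predictors, a medium effect (f^2 = 0.15), alpha 0.05 and power 0.80
#' this gives 76; `n_actions` scales the result for designs that need the
#' sample per action (5 actions give 380). The alternative textbook
#' convention n = ceiling(L / f^2 + u + 1) is available via `rounding`.
#'
#' @param n_predictors Number of predictors u.
#' @param effect `"small"`, `"medium"`, `"large"` (f^2 = 0.02, 0.15,
#'   0.35), or a numeric f-squared via `f2`.
#' @param f2 Effect size f-squared; overrides `effect` when given.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80), must exceed `alpha`.
#' @param n_actions Multiplier for per-action designs (default 1).
#' @param rounding `"cohen"` (n = ceil(L/f2 + u)) or `"plus_one"`.
#' @return Required total sample size (integer), at least u + 2.
#' @export
regression_sample_size <- function(n_predictors,
                                   effect = c("medium", "small", "large"),
                                   f2 = NULL, alpha = 0.05, power = 0.80,
                                   n_actions = 1L,
                                   rounding = c("cohen", "plus_one")) {
  rounding <- match.arg(rounding)
  if (is.null(f2)) {
    effect <- match.arg(effect)
    f2 <- c(small = 0.02, medium = 0.15, large = 0.35)[[effect]]
  }
  stopifnot(n_predictors >= 1L, f2 > 0, alpha > 0, alpha < 1)
  if (power <= alpha || power >= 1) {
    stop("power must lie in (alpha, 1)")
  }
  L <- cohen_L(n_predictors, power, alpha)
  extra <- if (rounding == "cohen") n_predictors else n_predictors + 1L
  n <- max(ceiling(L / f2 + extra), n_predictors + 2L)
  as.integer(n * n_actions)
}

#' Sample size versus Q-value estimation error
#'
#' Treats the Q-values estimated from the full dataset as the reference
#' ("true") Q-function, then repeatedly re-estimates Q from uniform
#' random subsamples of each requested size and records two L1 errors:
#' the mean absolute difference between estimated and reference Q over
#' all 40 state-action cells, and the mean (over states) reference-Q gap
#' between the estimated-optimal and the reference-optimal action. The
#' second error measures how much value is lost by acting on the
#' estimated policy; it is 0 whenever the estimated argmax matches the
#' reference argmax.
#'
#' @param samples A samples data frame (the full dataset).
#' @param sizes Integer vector of subsample sizes, each at most
#'   `nrow(samples)`.
#' @param reps Repetitions per size (default 100).
#' @param gamma Discount factor.
#' @param seed Optional seed; results are reproducible bit-for-bit.
#' @return An object of class `l1_study`: list with `summary` (data frame
#'   of per-size mean errors `size`, `mean_l1_q`, `mean_l1_action`),
#'   `reps`, `gamma`, and `reference_q`.
#' @export
q_error_study <- function(samples, sizes, reps = 100L, gamma = 0.85,
                          seed = NULL) {
  samples <- as_samples(samples)
  n <- nrow(samples)
  stopifnot(all(sizes >= 1L), reps >= 1L)
  if (any(sizes > n)) stop("subsample size exceeds the dataset (", n, ")")
  if (!is.null(seed)) set.seed(seed)

  q_ref <- value_iteration(estimate_models(samples), gamma = gamma)$q
  a_ref <- apply(q_ref, 1, which.max)  # canonical tie-break
  v_ref <- q_ref[cbind(seq_len(nrow(q_ref)), a_ref)]

  summary <- data.frame(size = as.integer(sizes), mean_l1_q = NA_real_,
                        mean_l1_action = NA_real_)
  for (j in seq_along(sizes)) {
    l1q <- numeric(reps); l1a <- numeric(reps)
    for (r in seq_len(reps)) {
      sub <- samples[sample.int(n, sizes[j]), ]
      q_hat <- value_iteration(estimate_models(sub), gamma = gamma)$q
      l1q[r] <- mean(abs(q_hat - q_ref))
      a_hat <- apply(q_hat, 1, which.max)
      l1a[r] <- mean(v_ref - q_ref[cbind(seq_len(nrow(q_ref)), a_hat)])
    }
    summary$mean_l1_q[j] <- mean(l1q)
    summary$mean_l1_action[j] <- mean(l1a)
  }
  structure(list(summary = summary, reps = as.integer(reps), gamma = gamma,
                 reference_q = q_ref),
            class = "l1_study")
}

#' @export
print.l1_study <- function(x, ...) {
  cat("Q-estimation L1 error by sample size (", x$reps, " repetitions)\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
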