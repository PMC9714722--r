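#' Reward from a self-reported effort score
#'
#' Maps an effort response on the 0--10 scale to a reward in \[-1, 1\],
#' anchored at the mean effort of the training batch: effort equal to the
#' mean earns 0, efforts below the mean are spaced evenly down to -1 at
#' effort 0, and efforts above the mean evenly up to +1 at effort 10,
#'
#' \deqn{r = \begin{cases}-1 + e/\bar e & e < \bar e\\
#'   1 - (10 - e)/(10 - \bar e) & e > \bar e\\ 0 & e = \bar e\end{cases}}
#'
#' so that the reward scale is symmetric around the cohort's typical effort
#' even when the effort distribution is skewed.
#'
#' @param effort Numeric vector of effort responses in \[0, 10\].
#' @param mean_effort The frozen training-batch mean effort, strictly inside
#'   (0, 10). The formula degenerates at the boundaries.
#' @return Numeric vector of rewards in \[-1, 1\].
#' @export
#' @examples
#' compute_reward(7, mean_effort = 5)   # 0.4
#' compute_reward(0:10, mean_effort = 5.5)
compute_reward <- function(effort, mean_effort) {
  if (length(mean_effort) != 1L || !is.finite(mean_effort) ||
      mean_effort <= 0 || mean_effort >= 10) {
    stop("mean_effort must be a single value strictly inside (0, 10)")
  }
  if (anyNA(effort) || any(effort < 0) || any(effort > 10)) {
    stop("effort must be in [0, 10]")
  }
  r <- numeric(length(effort))
  lo <- effort < mean_effort
  hi <- effort > mean_effort
  r[lo] <- -1 + effort[lo] / mean_effort
  r[hi] <- 1 - (10 - effort[hi]) / (10 - mean_effort)
  r
}

#' Mean effort of a training batch
#'
#' The arithmetic mean effort over a batch of samples. This value anchors
#' [compute_reward()] at zero and is frozen once the training batch is
#' fixed: later data do not move it, so that rewards (and hence policies)
#' computed at different times remain comparable.
#'
#' @param samples A samples data frame (see [as_samples()]) or a numeric
#'   vector of effort scores.
#' @return The mean effort, a single number in \[0, 10\].
#' @export
compute_mean_effort <- function(samples) {
  effort <- if (is.data.frame(samples)) samples$effort else samples
  if (length(effort) == 0L) stop("cannot compute mean effort of an empty batch")
  if (anyNA(effort) || any(effort < 0) || any(effort > 10)) {
    stop("effort values must be in [0, 10]")
  }
  mean(effort)
}
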