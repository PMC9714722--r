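#' Binarization thresholds for the raw state features
#'
#' Each session a person answers ten questions (seven COM-B self-evaluation
#' items plus self-efficacy, smoker identity and physical-activity identity)
#' on 5-point scales. To keep the state space learnable from a small
#' training batch, each feature is split at its training-set mean. The
#' thresholds are fit once on the training batch and frozen thereafter,
#' mirroring the handling of the mean effort.
#'
#' @param raw A numeric matrix or data frame, one row per observation, one
#'   column per raw state feature.
#' @return Numeric vector of per-feature means (the thresholds).
#' @export
fit_thresholds <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) == 0L) stop("cannot fit thresholds on an empty training set")
  if (anyNA(raw)) stop("raw state answers contain missing values")
  colMeans(raw)
}

#' Binarize raw state answers at the frozen thresholds
#'
#' A feature becomes 1 when the raw answer is greater than or equal to its
#' threshold and 0 otherwise.
#'
#' @param raw Numeric vector (one observation) or matrix/data frame (one
#'   row per observation) of raw answers.
#' @param thresholds Per-feature thresholds from [fit_thresholds()].
#' @return Integer 0/1 matrix with the same number of rows as `raw` and a
#'   `"thresholds"` attribute.
#' @export
binarize <- function(raw, thresholds) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  raw <- as.matrix(raw)
  if (ncol(raw) != length(thresholds)) {
    stop("number of features (", ncol(raw), ") does not match the ",
         length(thresholds), " thresholds")
  }
  bits <- matrix(as.integer(sweep(raw, 2L, thresholds, `>=`)),
                 nrow = nrow(raw), dimnames = dimnames(raw))
  attr(bits, "thresholds") <- thresholds
  bits
}

#' Select the three state features defining the 8-state space
#'
#' Greedy one-shot feature scoring in the spirit of the G-algorithm's test
#' of whether a bit discriminates action values. For each candidate feature
#' f, the samples are collapsed onto the 2-state MDP induced by f alone and
#' the feature is scored by how much its value separates the actions:
#' \deqn{score(f) = \sum_{a} |V(f{=}1, a) - V(f{=}0, a)|}
#' where V is the state-conditional mean reward at complexity level 2 and
#' the single-feature Q-value at the given discount for levels 3 and 4. A
#' feature that is constant in the data carries no state information and
#' scores 0. The top three features are returned ordered by score
#' descending (most significant bit first); score ties are broken by the
#' lower feature index for determinism.
#'
#' @param bits 0/1 matrix of binarized state answers, one row per sample.
#' @param action Per-sample persuasion type.
#' @param reward Per-sample reward in \[-1, 1\].
#' @param next_bits 0/1 matrix of the next session's binarized answers.
#' @param level Complexity level 2, 3 or 4.
#' @param gamma Discount factor used for levels 3--4.
#' @return An object of class `feature_selection`: list with `chosen`
#'   (3 feature indices, bit-significance order), `scores` (all features),
#'   and `level`.
#' @export
select_features <- function(bits, action, reward, next_bits, level,
                            gamma = 0.85) {
  stopifnot(length(level) == 1L, level %in% 2:4)
  bits <- as.matrix(bits); next_bits <- as.matrix(next_bits)
  p <- ncol(bits)
  if (p < 3L) stop("need at least 3 candidate features")
  stopifnot(nrow(bits) == length(action), nrow(bits) == length(reward),
            all(dim(bits) == dim(next_bits)))
  a_idx <- action_index(action)
  A <- n_actions()

  scores <- vapply(seq_len(p), function(f) {
    b <- bits[, f]
    if (length(unique(b)) < 2L) return(0)  # constant: no state information
    if (level == 2L) {
      v <- matrix(0, nrow = 2L, ncol = A)
      for (s in 0:1) for (a in seq_len(A)) {
        r <- reward[b == s & a_idx == a]
        if (length(r) > 0L) v[s + 1L, a] <- mean(r)
      }
    } else {
      two <- data.frame(state = b, action = action, reward = reward,
                        next_state = next_bits[, f])
      models <- estimate_models_generic(two, n_s = 2L)
      v <- value_iteration(models$reward, gamma = gamma,
                           transition = models$transition)$q
    }
    sum(abs(v[2L, ] - v[1L, ]))
  }, numeric(1))

  ord <- order(-scores, seq_len(p))
  structure(list(chosen = ord[1:3], scores = scores, level = as.integer(level)),
            class = "feature_selection")
}

# estimate_models over an arbitrary number of states (used for the
# single-feature 2-state MDPs during selection); same defaults as the
# 8-state estimator.
estimate_models_generic <- function(df, n_s) {
  A <- n_actions()
  a_idx <- action_index(df$action)
  cell <- df$state + n_s * (a_idx - 1L) + n_s * A * df$next_state + 1L
  f <- factor(cell, levels = seq_len(n_s * A * n_s))
  wsum <- as.numeric(tapply(rep(1, nrow(df)), f, sum, default = 0))
  rwsum <- as.numeric(tapply(df$reward, f, sum, default = 0))
  support <- array(wsum, dim = c(n_s, A, n_s))
  reward <- array(0, dim = c(n_s, A, n_s))
  reward[support > 0] <- rwsum[wsum > 0] / wsum[wsum > 0]
  transition <- array(1 / n_s, dim = c(n_s, A, n_s))
  pair <- apply(support, c(1, 2), sum)
  for (s in seq_len(n_s)) for (a in seq_len(A)) {
    if (pair[s, a] > 0) transition[s, a, ] <- support[s, a, ] / pair[s, a]
  }
  list(reward = reward, transition = transition)
}

#' Encode selected feature bits as a state index
#'
#' Maps the three selected binary features to a state index in 0--7, with
#' the first selected feature as the most significant bit:
#' index = 4 b1 + 2 b2 + b3. The encoding is a bijection between bit
#' triples and state indices.
#'
#' @param bits A 0/1 vector of length 3, a full binarized answer vector
#'   (with `selection` picking out the three features), or a matrix of
#'   rows thereof.
#' @param selection Optional `feature_selection`; when given, `bits` may
#'   contain all features and the chosen three are extracted in
#'   significance order.
#' @return Integer state index/indices in 0--7.
#' @export
encode_state <- function(bits, selection = NULL) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  bits <- as.matrix(bits)
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "feature_selection"))
    bits <- bits[, selection$chosen, drop = FALSE]
  }
  if (ncol(bits) != 3L) stop("state encoding requires exactly 3 bits")
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0 or 1")
  idx <- as.integer(bits %*% c(4L, 2L, 1L))
  if (nrow(bits) == 1L) idx[[1]] else idx
}

#' Decode a state index back to its bit triple
#' @param index Integer state index in 0--7.
#' @return Integer matrix of bits (most significant first), one row per index.
#' @export
decode_state <- function(index) {
  index <- check_state_index(index)
  cbind(b1 = index %/% 4L, b2 = (index %/% 2L) %% 2L, b3 = index %% 2L)
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("Feature selection (complexity level ", x$level, ")\n", sep = "")
  cat("chosen (MSB first):", paste(x$chosen, collapse = ", "), "\n")
  cat("scores:", paste(signif(x$scores, 4), collapse = ", "), "\n")
  invisible(x)
}
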