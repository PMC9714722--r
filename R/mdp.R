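#' Estimate reward and transition models from samples
#'
#' Tabular, optionally weighted estimation of the reward function
#' R(s, a, s') and transition function T(s, a, s') over the 8-state,
#' 5-action space. Each reward cell is the weighted mean reward of the
#' samples matching (s, a, s'); each transition row (s, a) is the weighted
#' relative frequency of observed next states. Weights come from the
#' similarity module for the personalized complexity level; absent weights
#' mean uniform weighting.
#'
#' Cells never visited in the data are given the neutral defaults: reward 0
#' (the reward of a mean-effort response) and a uniform distribution over
#' the 8 next states, which keeps value iteration well defined without
#' biasing action values up or down.
#'
#' @param samples A samples data frame (see [as_samples()]).
#' @param weights Optional positive per-sample weights, aligned 1:1 with
#'   the rows of `samples`. `NULL` means uniform.
#' @return An object of class `mdp_models`: a list with `reward` and
#'   `transition` (8 x 5 x 8 arrays, dimensions state x action x next
#'   state) and `support` (the weight mass behind each cell).
#' @export
estimate_models <- function(samples, weights = NULL) {
  samples <- as_samples(samples)
  n <- nrow(samples)
  if (n == 0L) stop("cannot estimate models from zero samples")
  w <- check_weights(weights, n)

  S <- n_states(); A <- n_actions()
  # linear cell index over (s, a, s')
  cell <- samples$state + S * (action_index(samples$action) - 1L) +
    S * A * samples$next_state + 1L
  ncell <- S * A * S
  f <- factor(cell, levels = seq_len(ncell))
  wsum <- as.numeric(tapply(w, f, sum, default = 0))
  rwsum <- as.numeric(tapply(w * samples$reward, f, sum, default = 0))

  dn <- list(state = as.character(0:7), action = persuasion_types(),
             next_state = as.character(0:7))
  support <- array(wsum, dim = c(S, A, S), dimnames = dn)
  reward <- array(0, dim = c(S, A, S), dimnames = dn)
  reward[support > 0] <- rwsum[wsum > 0] / wsum[wsum > 0]
  stopifnot(all(reward >= -1 - 1e-9), all(reward <= 1 + 1e-9))

  transition <- array(0, dim = c(S, A, S), dimnames = dn)
  pair_mass <- apply(support, c(1, 2), sum)
  for (s in seq_len(S)) {
    for (a in seq_len(A)) {
      if (pair_mass[s, a] > 0) {
        transition[s, a, ] <- support[s, a, ] / pair_mass[s, a]
      } else {
        transition[s, a, ] <- 1 / S
      }
    }
  }
  structure(list(reward = reward, transition = transition, support = support),
            class = "mdp_models")
}

#' Q-values by value iteration
#'
#' Computes the fixed point of the Bellman optimality equation
#' \deqn{Q(s,a) = \sum_{s'} T(s,a,s')\,[R(s,a,s') + \gamma \max_{a'} Q(s',a')]}
#' by synchronous value iteration from Q = 0, stopping when the sup-norm
#' change falls below `tol`. With rewards bounded by 1 the iteration is a
#' gamma-contraction, so the result is deterministic for fixed inputs.
#'
#' @param models An `mdp_models` object from [estimate_models()], or a
#'   reward array if `transition` is supplied separately.
#' @param gamma Discount factor in \[0, 1). Default 0.85, favoring rewards
#'   in the near future: an early failed persuasive attempt risks losing
#'   the person entirely.
#' @param tol Bound on the sup-norm distance between the returned Q and the
#'   true fixed point (> 0); the stopping rule accounts for the
#'   contraction factor, so the guarantee is on the answer, not on the
#'   last sweep. The default 1e-9 is far below any decision margin at
#'   this scale.
#' @param transition Transition array when `models` is a raw reward array.
#' @param max_iter Safety cap on sweeps.
#' @return An object of class `q_function`: list with `q` (8 x 5 matrix),
#'   `gamma`, and `iterations`.
#' @export
value_iteration <- function(models, gamma = 0.85, tol = 1e-9,
                            transition = NULL, max_iter = 100000L) {
  if (inherits(models, "mdp_models")) {
    R <- models$reward; Tr <- models$transition
  } else {
    R <- models; Tr <- transition
    if (is.null(Tr)) stop("transition array required")
  }
  S <- dim(Tr)[1]; A <- dim(Tr)[2]
  if (!is.finite(gamma) || gamma < 0 || gamma >= 1) {
    stop("gamma must lie in [0, 1)")
  }
  if (tol <= 0) stop("tol must be > 0")
  rowsums <- apply(Tr, c(1, 2), sum)
  if (any(abs(rowsums - 1) > 1e-9) || any(Tr < 0)) {
    stop("every transition row T(s, a, .) must be a probability vector")
  }

  # flatten (s, a) to rows for fast sweeps
  Tm <- matrix(Tr, nrow = S * A, ncol = S)          # row (s,a), col s'
  er <- rowSums(Tm * matrix(R, nrow = S * A))       # expected immediate reward
  q <- matrix(0, nrow = S, ncol = A,
              dimnames = list(state = as.character(seq_len(S) - 1L),
                              action = persuasion_types()[seq_len(A)]))
  # a sweep change of delta leaves at most delta * gamma / (1 - gamma)
  # between q and the fixed point
  thr <- if (gamma > 0) tol * (1 - gamma) / gamma else tol
  for (it in seq_len(max_iter)) {
    v <- apply(q, 1, max)
    q_new <- matrix(er + gamma * as.numeric(Tm %*% v), nrow = S, ncol = A,
                    dimnames = dimnames(q))
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < thr) break
  }
  structure(list(q = q, gamma = gamma, iterations = it), class = "q_function")
}

# Argmax sets of a state x action value matrix: all actions within tol of
# the row maximum, in canonical order.
argmax_sets <- function(values, tol = 1e-9) {
  acts <- colnames(values)
  lapply(seq_len(nrow(values)), function(s) {
    acts[values[s, ] >= max(values[s, ]) - tol]
  })
}

#' Greedy policy for one of the four algorithm complexity levels
#'
#' The four nested levels differ in what is maximized when choosing a
#' persuasion type:
#' \describe{
#'   \item{Level 1}{the overall average reward of an action, ignoring
#'     state: the resulting policy is constant across states.}
#'   \item{Level 2}{the average reward of an action in the person's current
#'     state.}
#'   \item{Level 3}{the Q-value of an action in the current state, i.e.
#'     current plus discounted future rewards, from [value_iteration()] on
#'     uniformly weighted model estimates.}
#'   \item{Level 4}{the similarity-weighted Q-value: the same computation
#'     on models estimated with per-sample weights that up-weight data from
#'     people similar to the target person (see [similarity_weights()]).}
#' }
#'
#' State/action cells with no data fall back to the neutral value 0 and
#' never raise an error. Ties among maximizing actions are recorded in
#' `argmax_set`; the single `mapping` action is chosen either by canonical
#' action order (`tie_break = "canonical"`, reproducible) or uniformly at
#' random (`tie_break = "random"`, as used in the resampled policy-
#' agreement analysis).
#'
#' @param level Integer 1--4.
#' @param samples A samples data frame.
#' @param gamma Discount factor for levels 3--4.
#' @param weights Per-sample similarity weights; required at level 4 and
#'   disallowed at levels 1--3, where uniform weighting is part of the
#'   level's definition.
#' @param tie_break `"canonical"` or `"random"`.
#' @param tol Numeric tolerance for declaring a tie.
#' @return An object of class `persuasion_policy`: list with `level`,
#'   `mapping` (action per state 0--7), `argmax_set` (all maximizers per
#'   state), `values` (the 8 x 5 criterion matrix), `gamma`, `tie_break`.
#' @export
policy_for_level <- function(level, samples, gamma = 0.85, weights = NULL,
                             tie_break = c("canonical", "random"),
                             tol = 1e-9) {
  tie_break <- match.arg(tie_break)
  stopifnot(length(level) == 1L, level %in% 1:4)
  samples <- as_samples(samples)
  if (nrow(samples) == 0L) stop("no samples to learn a policy from")
  if (level == 4 && is.null(weights)) {
    stop("level 4 requires similarity weights; see similarity_weights()")
  }
  if (level < 4 && !is.null(weights)) {
    stop("levels 1-3 use uniform weighting; weights are only valid at level 4")
  }

  S <- n_states(); A <- n_actions()
  if (level == 1) {
    a_idx <- action_index(samples$action)
    means <- vapply(seq_len(A), function(a) {
      r <- samples$reward[a_idx == a]
      if (length(r) == 0L) 0 else mean(r)
    }, numeric(1))
    values <- matrix(rep(means, each = S), nrow = S,
                     dimnames = list(state = as.character(0:7),
                                     action = persuasion_types()))
  } else if (level == 2) {
    values <- state_action_mean_reward(samples)
  } else {
    models <- estimate_models(samples, weights = weights)
    values <- value_iteration(models, gamma = gamma)$q
  }

  sets <- argmax_sets(values, tol = tol)
  mapping <- vapply(sets, function(set) {
    if (tie_break == "canonical" || length(set) == 1L) set[[1]]
    else sample(set, 1L)
  }, character(1))
  names(mapping) <- as.character(0:7)
  structure(list(level = as.integer(level), mapping = mapping,
                 argmax_set = sets, values = values, gamma = gamma,
                 tie_break = tie_break),
            class = "persuasion_policy")
}

# Weighted mean reward per (state, action); unvisited cells default to 0.
state_action_mean_reward <- function(samples, weights = NULL) {
  samples <- as_samples(samples)
  w <- check_weights(weights, nrow(samples))
  S <- n_states(); A <- n_actions()
  cell <- samples$state + S * (action_index(samples$action) - 1L) + 1L
  f <- factor(cell, levels = seq_len(S * A))
  wsum <- as.numeric(tapply(w, f, sum, default = 0))
  rwsum <- as.numeric(tapply(w * samples$reward, f, sum, default = 0))
  values <- matrix(0, nrow = S, ncol = A,
                   dimnames = list(state = as.character(0:7),
                                   action = persuasion_types()))
  values[wsum > 0] <- rwsum[wsum > 0] / wsum[wsum > 0]
  values
}

#' @export
print.persuasion_policy <- function(x, ...) {
  cat("Persuasion policy, complexity level", x$level, "\n")
  ab <- action_abbrev()
  tab <- data.frame(state = names(x$mapping),
                    action = unname(ab[x$mapping]),
                    ties = vapply(x$argmax_set, length, integer(1)))
  print(tab, row.names = FALSE)
  invisible(x)
}
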