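# Shared simulation helpers for the test suite. All fixtures are built in
# code; nothing is read from disk.

# Ground truth with one planted best action per state: the planted action's
# mean effort exceeds every other action's by `margin` effort points.
# Transitions are action-independent so that the greedy-on-Q policy and the
# greedy-on-immediate-reward policy share the same optimum.
planted_truth <- function(best_actions, base = 4, margin = 2,
                          noise_sd = 1, person_sd = 0) {
  stopifnot(length(best_actions) == 8L)
  rm <- matrix(base, 8, 5, dimnames = list(NULL, persuasion_types()))
  for (s in 1:8) rm[s, best_actions[s]] <- base + margin
  ground_truth(rm, bitwise_transition(persuasion_boost = 0),
               noise_sd = noise_sd, person_sd = person_sd)
}

# A small hand-rolled samples table.
make_samples <- function(state, action, reward, next_state,
                         person_id = NULL, activity_type = NULL) {
  n <- length(state)
  df <- data.frame(state = state, action = action, reward = reward,
                   next_state = next_state, stringsAsFactors = FALSE)
  if (!is.null(person_id)) df$person_id <- person_id
  if (!is.null(activity_type)) df$activity_type <- activity_type
  as_samples(df)
}

# Random MDP over 8 states and 5 actions: rewards uniform in [-1, 1],
# transition rows from normalized exponential draws.
random_mdp <- function() {
  R <- array(runif(8 * 5 * 8, -1, 1), dim = c(8, 5, 8))
  Tr <- array(rexp(8 * 5 * 8), dim = c(8, 5, 8))
  for (s in 1:8) for (a in 1:5) {
    Tr[s, a, ] <- Tr[s, a, ] / sum(Tr[s, a, ])
  }
  list(R = R, T = Tr)
}

# Independent oracle: finite-horizon backward induction with explicit
# loops, sharing no code with value_iteration().
backward_induction_q <- function(R, Tr, gamma, horizon) {
  S <- dim(Tr)[1]; A <- dim(Tr)[2]
  q <- matrix(0, S, A)
  for (h in seq_len(horizon)) {
    v <- numeric(S)
    for (s in seq_len(S)) v[s] <- max(q[s, ])
    q_new <- matrix(0, S, A)
    for (s in seq_len(S)) {
      for (a in seq_len(A)) {
        q_new[s, a] <- sum(Tr[s, a, ] * (R[s, a, ] + gamma * v))
      }
    }
    q <- q_new
  }
  q
}
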