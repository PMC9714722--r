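#' Default pool of preparatory activities
#'
#' Twenty-four preparatory activities of similar duration, twelve for
#' quitting smoking and twelve for increasing physical activity, identified
#' by id and type only (no natural-language content). A few cross-type
#' pairs are declared "very similar" via a shared similarity group (for
#' example a personal rule for not smoking and a personal rule for being
#' more active); an activity from a group already assigned to a person is
#' never assigned again.
#'
#' @return Data frame with columns `activity_id`, `activity_type`,
#'   `similarity_group`.
#' @export
default_activity_pool <- function() {
  smoking <- sprintf("S%02d", 1:12)
  physical <- sprintf("P%02d", 1:12)
  grp <- c(paste0("g", 1:12), paste0("g", c(1, 2, 3, 13:21)))
  data.frame(
    activity_id = c(smoking, physical),
    activity_type = rep(activity_types(), each = 12L),
    similarity_group = grp,
    stringsAsFactors = FALSE
  )
}

#' Ground truth driving the synthetic cohort
#'
#' Defines the data-generating process a simulated cohort follows: the
#' mean effort a person in state s produces after persuasion type a, the
#' true next-state distribution, effort noise, and (optionally) a trait
#' effect splitting the population into two clusters whose action
#' effectiveness differs.
#'
#' @param reward_mean 8 x 5 matrix of true mean efforts (0--10), rows =
#'   states 0--7, columns = [persuasion_types()].
#' @param transition 8 x 5 x 8 array of true next-state probabilities;
#'   every row (s, a, .) must sum to 1.
#' @param noise_sd Standard deviation of the Gaussian effort noise added
#'   per response before rounding and clipping to 0--10.
#' @param person_sd Standard deviation of a per-person Gaussian effort
#'   offset (stable across sessions).
#' @param trait_effect Optional list with elements `delta_low` and
#'   `delta_high` (8 x 5 matrices added to `reward_mean` for the two trait
#'   clusters) and `p_high` (probability of the high cluster, default
#'   0.5). When active, people are assigned to a cluster and their traits
#'   are drawn from the cluster's side of the instrument scales, so that
#'   trait similarity is informative about action effectiveness.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(reward_mean, transition, noise_sd = 2.5,
                         person_sd = 1, trait_effect = NULL) {
  reward_mean <- as.matrix(reward_mean)
  stopifnot(all(dim(reward_mean) == c(8L, 5L)),
            all(reward_mean >= 0), all(reward_mean <= 10),
            all(dim(transition) == c(8L, 5L, 8L)),
            noise_sd >= 0, person_sd >= 0)
  rows <- apply(transition, c(1, 2), sum)
  if (any(abs(rows - 1) > 1e-9) || any(transition < 0)) {
    stop("every transition row must be a probability vector")
  }
  if (!is.null(trait_effect)) {
    stopifnot(is.list(trait_effect),
              all(dim(trait_effect$delta_low) == c(8L, 5L)),
              all(dim(trait_effect$delta_high) == c(8L, 5L)))
    if (is.null(trait_effect$p_high)) trait_effect$p_high <- 0.5
    for (side in c("delta_low", "delta_high")) {
      shifted <- reward_mean + trait_effect[[side]]
      if (any(shifted < 0) || any(shifted > 10)) {
        stop(side, " pushes mean efforts outside [0, 10]")
      }
    }
  }
  colnames(reward_mean) <- persuasion_types()
  structure(list(reward_mean = reward_mean, transition = transition,
                 noise_sd = noise_sd, person_sd = person_sd,
                 trait_effect = trait_effect),
            class = "ground_truth")
}

#' A plausible default ground truth
#'
#' Mean efforts around the middle of the 0--10 scale with a mild
#' state-by-action structure (action planning works best for people in
#' low-motivation states, commitment for people in high-motivation states)
#' and bit-wise state dynamics in which persuasive messages slightly raise
#' the chance that a state bit turns on. Effort noise and person spread
#' are set so simulated efforts have mean near 5.5 and standard deviation
#' near 2.7, the scale typical of self-reported effort data.
#'
#' @param noise_sd,person_sd Override the effort noise components.
#' @param trait_effect Optional trait effect, see [ground_truth()].
#' @return A `ground_truth` object.
#' @export
default_ground_truth <- function(noise_sd = 2.5, person_sd = 1,
                                 trait_effect = NULL) {
  reward_mean <- matrix(5.0, 8, 5, dimnames = list(NULL, persuasion_types()))
  msb <- decode_state(0:7)[, "b1"]
  reward_mean[msb == 1L, "COMMITMENT"] <- 5.8
  reward_mean[msb == 0L, "ACTION_PLANNING"] <- 5.8
  reward_mean[, "CONSENSUS"] <- 5.4
  ground_truth(reward_mean,
               bitwise_transition(p_up = 0.35, p_stay = 0.65,
                                  persuasion_boost = 0.05),
               noise_sd = noise_sd, person_sd = person_sd,
               trait_effect = trait_effect)
}

#' Transition array from independent bit dynamics
#'
#' Builds an 8 x 5 x 8 transition array in which each of the three state
#' bits evolves independently: a bit that is 0 turns on with probability
#' `p_up`, a bit that is 1 stays on with probability `p_stay`, and any
#' persuasion type other than NO_PERSUASION adds `persuasion_boost` to
#' both probabilities (capped at 1).
#'
#' @param p_up,p_stay,persuasion_boost Bit dynamics parameters in \[0, 1\].
#' @return An 8 x 5 x 8 transition array with normalized rows.
#' @export
bitwise_transition <- function(p_up = 0.35, p_stay = 0.65,
                               persuasion_boost = 0.05) {
  tr <- array(0, dim = c(8L, 5L, 8L))
  bits <- decode_state(0:7)
  for (a in seq_len(5L)) {
    boost <- if (persuasion_types()[a] == "NO_PERSUASION") 0 else persuasion_boost
    p1_if0 <- min(p_up + boost, 1)
    p1_if1 <- min(p_stay + boost, 1)
    for (s in 0:7) {
      p_on <- ifelse(bits[s + 1L, ] == 1L, p1_if1, p1_if0)
      for (s2 in 0:7) {
        b2 <- decode_state(s2)[1, ]
        tr[s + 1L, a, s2 + 1L] <- prod(ifelse(b2 == 1L, p_on, 1 - p_on))
      }
    }
  }
  tr
}

#' Configuration of a synthetic cohort
#'
#' @param n_people Number of people to simulate.
#' @param n_sessions Sessions per person (1--5); the study schema has 5.
#' @param seed Optional integer seed making the cohort reproducible.
#' @param dropout_rate Per-session Bernoulli probability of dropping out
#'   before each session after the first; sessions after dropout are
#'   absent. Default 0.
#' @param activity_pool Activity pool data frame; see
#'   [default_activity_pool()].
#' @param signal_features Indices (in 1--10) of the three raw questionnaire
#'   features that carry the true state bits, most significant first. The
#'   remaining features are uninformative noise.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_people, n_sessions = 5L, seed = NULL,
                          dropout_rate = 0,
                          activity_pool = default_activity_pool(),
                          signal_features = c(5L, 4L, 8L)) {
  stopifnot(n_people >= 1, n_sessions >= 1, n_sessions <= 5,
            dropout_rate >= 0, dropout_rate < 1,
            length(signal_features) == 3L,
            all(signal_features %in% 1:10))
  counts <- table(factor(activity_pool$activity_type, levels = activity_types()))
  if (!all(counts == 12L)) {
    stop("activity pool must contain 12 activities per type")
  }
  structure(list(n_people = as.integer(n_people),
                 n_sessions = as.integer(n_sessions),
                 seed = seed, dropout_rate = dropout_rate,
                 activity_pool = activity_pool,
                 signal_features = as.integer(signal_features)),
            class = "cohort_config")
}

#' Assign a preparatory activity for a session
#'
#' Implements the assignment rules: sessions 1--2 together cover both
#' activity types in random order, sessions 3--4 likewise, and the type of
#' the fifth session is chosen uniformly at random. Within the chosen
#' type, an activity is drawn uniformly from the pool members that have
#' not been assigned to this person before and whose similarity group has
#' not been used either.
#'
#' @param history Character vector of this person's previously assigned
#'   activity ids, in session order.
#' @param session Session number 1--5.
#' @param pool Activity pool data frame.
#' @return List with `activity_id` and `activity_type`.
#' @export
assign_activity <- function(history, session, pool = default_activity_pool()) {
  stopifnot(session >= 1, session <= 5, length(history) == session - 1L)
  if (session %in% c(2L, 4L)) {
    prev <- pool$activity_type[match(history[session - 1L], pool$activity_id)]
    type <- setdiff(activity_types(), prev)
  } else {
    type <- sample(activity_types(), 1L)
  }
  used_groups <- pool$similarity_group[match(history, pool$activity_id)]
  eligible <- pool$activity_id[pool$activity_type == type &
                                 !(pool$activity_id %in% history) &
                                 !(pool$similarity_group %in% used_groups)]
  if (length(eligible) == 0L) {
    stop("no eligible ", type, " activity left for session ", session)
  }
  id <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  list(activity_id = id, activity_type = type)
}

#' Generate a synthetic longitudinal persuasion cohort
#'
#' Simulates people interacting with the virtual coach under a known
#' ground truth, producing session records in the published-data schema:
#' one row per session with the person's ten raw 5-point state answers,
#' the assigned activity (id and type), the persuasion type used, and the
#' effort later reported for that activity. Effort for a session's
#' activity is observed only if the person completes the following
#' session (it is reported there), so the last completed session of each
#' person carries `NA` effort.
#'
#' Persuasion types are chosen uniformly at random in sessions 1--2 (the
#' training phase) and by the supplied `policy` afterwards; without a
#' policy all sessions are random. Raw answers are generated so that the
#' three configured signal features reproduce the true state bits after
#' mean-split binarization (answers 3--5 for an active bit, 1--2
#' otherwise) while the remaining seven features are uniform noise.
#'
#' @param config A [cohort_config()].
#' @param truth A [ground_truth()]; defaults to [default_ground_truth()].
#' @param policy Optional `persuasion_policy` used from session 3 on.
#' @return An object of class `synthetic_cohort`: list with `records`
#'   (session table, including the simulator's hidden `state_index`),
#'   `traits` (per-person raw trait table with columns `person_id`,
#'   `personality_1..5`, `ttm_stage`, and `cluster` when a trait effect is
#'   active), `config` and `truth`.
#' @export
generate_cohort <- function(config, truth = default_ground_truth(),
                            policy = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "ground_truth"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_people
  ids <- sprintf("p%05d", seq_len(n))
  te <- truth$trait_effect

  # traits (and trait clusters when a trait effect is active)
  if (is.null(te)) {
    cluster <- rep(NA_character_, n)
    pers <- matrix(round(runif(5L * n, 1, 7), 2), nrow = n)
    ttm <- sample(1:5, n, replace = TRUE)
  } else {
    cluster <- ifelse(runif(n) < te$p_high, "high", "low")
    pers <- matrix(0, nrow = n, ncol = 5L)
    ttm <- integer(n)
    lo <- cluster == "low"
    pers[lo, ] <- round(runif(5L * sum(lo), 1, 3.8), 2)
    pers[!lo, ] <- round(runif(5L * sum(!lo), 4.2, 7), 2)
    ttm[lo] <- sample(1:2, sum(lo), replace = TRUE)
    ttm[!lo] <- sample(4:5, sum(!lo), replace = TRUE)
  }
  offsets <- rnorm(n, 0, truth$person_sd)

  sig <- config$signal_features
  answers_for <- function(bits) {
    ans <- sample(1:5, 10L, replace = TRUE)
    ans[sig] <- ifelse(bits == 1L, sample(3:5, 3L, replace = TRUE),
                       sample(1:2, 3L, replace = TRUE))
    ans
  }

  nmax <- n * config$n_sessions
  col_person <- character(nmax); col_session <- integer(nmax)
  col_ans <- matrix(NA_integer_, nrow = nmax, ncol = 10L,
                    dimnames = list(NULL, paste0("ans_", 1:10)))
  col_act_id <- character(nmax); col_act_type <- character(nmax)
  col_action <- character(nmax); col_effort <- integer(nmax)
  col_state <- integer(nmax)
  k <- 0L
  for (i in seq_len(n)) {
    rm_i <- truth$reward_mean
    if (!is.null(te)) {
      rm_i <- rm_i + if (cluster[i] == "high") te$delta_high else te$delta_low
    }
    state <- encode_state(stats::rbinom(3L, 1L, 0.5))
    history <- character(0)
    for (sess in seq_len(config$n_sessions)) {
      if (sess > 1L && config$dropout_rate > 0 &&
          runif(1) < config$dropout_rate) break
      act <- assign_activity(history, sess, config$activity_pool)
      history <- c(history, act$activity_id)
      if (sess <= 2L || is.null(policy)) {
        action <- sample(persuasion_types(), 1L)
      } else {
        action <- unname(policy$mapping[as.character(state)])
      }
      mu <- rm_i[state + 1L, action] + offsets[i]
      k <- k + 1L
      col_person[k] <- ids[i]; col_session[k] <- sess
      col_ans[k, ] <- answers_for(decode_state(state)[1, ])
      col_act_id[k] <- act$activity_id; col_act_type[k] <- act$activity_type
      col_action[k] <- action
      col_effort[k] <- min(max(round(mu + rnorm(1, 0, truth$noise_sd)), 0), 10)
      col_state[k] <- state
      state <- sample(0:7, 1L, prob = truth$transition[state + 1L,
                                                       action_index(action), ])
    }
    # effort is reported in the following session; the last completed
    # session's activity has no report
    col_effort[k] <- NA_integer_
  }
  keep <- seq_len(k)
  records <- data.frame(person_id = col_person[keep],
                        session = col_session[keep],
                        col_ans[keep, , drop = FALSE],
                        activity_id = col_act_id[keep],
                        activity_type = col_act_type[keep],
                        action = col_action[keep], effort = col_effort[keep],
                        state_index = col_state[keep],
                        stringsAsFactors = FALSE)
  traits <- data.frame(person_id = ids, pers, ttm_stage = ttm,
                       cluster = cluster, stringsAsFactors = FALSE)
  names(traits)[2:6] <- paste0("personality_", 1:5)
  if (is.null(te)) traits$cluster <- NULL
  structure(list(records = records, traits = traits, config = config,
                 truth = truth),
            class = "synthetic_cohort")
}

#' Learning samples from session records
#'
#' Pairs each session with the next completed session of the same person
#' to form one learning sample per persuasive attempt: the state at the
#' session, the persuasion type sent, the reward from the effort reported
#' afterwards, and the next state. States are taken from the simulator's
#' `state_index` column unless `thresholds` and `selection` are supplied,
#' in which case they are recomputed from the raw answers by mean-split
#' binarization and 3-feature encoding (the route real data takes).
#'
#' @param cohort A `synthetic_cohort` or a records data frame.
#' @param mean_effort Anchor for [compute_reward()]; default is the mean of
#'   the observed efforts entering the samples (the training-batch mean).
#' @param thresholds,selection Optional frozen binarization thresholds and
#'   `feature_selection` used to derive states from raw answers.
#' @return A samples data frame (class `rl_samples`) with columns
#'   `person_id`, `session`, `state`, `action`, `effort`, `reward`,
#'   `next_state`, `activity_type`, plus attribute `"mean_effort"`.
#' @export
cohort_samples <- function(cohort, mean_effort = NULL, thresholds = NULL,
                           selection = NULL) {
  records <- if (inherits(cohort, "synthetic_cohort")) cohort$records else cohort
  records <- records[order(records$person_id, records$session), ]
  nxt <- match(paste(records$person_id, records$session + 1L),
               paste(records$person_id, records$session))
  has_next <- !is.na(nxt) & !is.na(records$effort)
  cur <- records[has_next, ]
  fol <- records[nxt[has_next], ]

  if (!is.null(thresholds) && !is.null(selection)) {
    ans_cols <- paste0("ans_", 1:10)
    state <- encode_state(binarize(as.matrix(cur[, ans_cols]), thresholds),
                          selection)
    next_state <- encode_state(binarize(as.matrix(fol[, ans_cols]),
                                        thresholds), selection)
  } else {
    state <- cur$state_index
    next_state <- fol$state_index
  }
  if (is.null(mean_effort)) mean_effort <- mean(cur$effort)
  out <- data.frame(person_id = cur$person_id, session = cur$session,
                    state = state, action = cur$action, effort = cur$effort,
                    reward = compute_reward(cur$effort, mean_effort),
                    next_state = next_state,
                    activity_type = cur$activity_type,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- as_samples(out)
  attr(out, "mean_effort") <- mean_effort
  out
}
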