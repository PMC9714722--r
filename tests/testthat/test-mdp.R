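test_that("model estimation on single samples gives point masses", {
  s <- make_samples(0, "COMMITMENT", 0.4, 1)
  m <- estimate_models(s)
  expect_equal(m$reward[1, "COMMITMENT", 2], 0.4)
  expect_equal(m$transition[1, "COMMITMENT", ], c(0, 1, rep(0, 6)),
               ignore_attr = TRUE)
  # two equal-weight samples split the transition mass
  s2 <- make_samples(c(0, 0), rep("COMMITMENT", 2), c(0, 0), c(1, 2))
  m2 <- estimate_models(s2)
  expect_equal(m2$transition[1, "COMMITMENT", 2], 0.5)
  expect_equal(m2$transition[1, "COMMITMENT", 3], 0.5)
})

test_that("reward cells are weighted means of matching samples", {
  s <- make_samples(c(0, 0), rep("CONSENSUS", 2), c(1, -1), c(3, 3))
  m <- estimate_models(s, weights = c(3, 1))
  expect_equal(m$reward[1, "CONSENSUS", 4], 0.5)  # (3*1 + 1*(-1)) / 4
})

test_that("unvisited cells carry neutral defaults", {
  s <- make_samples(0, "COMMITMENT", 0.4, 1)
  m <- estimate_models(s)
  expect_equal(m$reward[3, "AUTHORITY", 5], 0)
  expect_equal(m$transition[3, "AUTHORITY", ], rep(1 / 8, 8),
               ignore_attr = TRUE)
})

test_that("every transition row is a probability vector", {
  set.seed(11)
  coh <- generate_cohort(cohort_config(150, seed = 11))
  m <- estimate_models(cohort_samples(coh))
  rows <- apply(m$transition, c(1, 2), sum)
  expect_true(all(abs(rows - 1) < 1e-9))
  expect_true(all(m$transition >= 0))
})

test_that("weight validation and scale invariance hold", {
  s <- make_samples(c(0, 1), c("COMMITMENT", "AUTHORITY"), c(0.2, -0.2),
                    c(1, 2))
  expect_error(estimate_models(s, weights = 1), "align")
  expect_error(estimate_models(s, weights = c(1, 0)), "positive")
  m1 <- estimate_models(s, weights = c(2, 5))
  m2 <- estimate_models(s, weights = c(2, 5) * 37.5)
  expect_equal(m1$reward, m2$reward)
  expect_equal(m1$transition, m2$transition)
})

test_that("value iteration solves the one-state geometric series exactly", {
  R <- array(0.3, dim = c(1, 1, 1))
  Tr <- array(1, dim = c(1, 1, 1))
  q <- value_iteration(R, gamma = 0.85, transition = Tr)
  expect_equal(as.numeric(q$q), 0.3 / 0.15, tolerance = 1e-7)
})

test_that("gamma = 0 reduces Q to the expected immediate reward", {
  set.seed(21)
  mdp <- random_mdp()
  q <- value_iteration(mdp$R, gamma = 0, transition = mdp$T)
  expected <- matrix(0, 8, 5)
  for (s in 1:8) for (a in 1:5) {
    expected[s, a] <- sum(mdp$T[s, a, ] * mdp$R[s, a, ])
  }
  expect_equal(unname(q$q), expected, tolerance = 1e-12)
})

test_that("value iteration agrees with the backward-induction oracle", {
  set.seed(31)
  gamma <- 0.85
  for (i in 1:10) {
    mdp <- random_mdp()
    q <- value_iteration(mdp$R, gamma = gamma, transition = mdp$T)
    oracle <- backward_induction_q(mdp$R, mdp$T, gamma, horizon = 200)
    bound <- gamma^200 / (1 - gamma) + 1e-9
    expect_lt(max(abs(unname(q$q) - oracle)), bound)
  }
})

test_that("value iteration validates its inputs", {
  mdp <- random_mdp()
  expect_error(value_iteration(mdp$R, gamma = 1, transition = mdp$T), "gamma")
  bad <- mdp$T; bad[1, 1, ] <- bad[1, 1, ] * 2
  expect_error(value_iteration(mdp$R, gamma = 0.85, transition = bad),
               "probability")
  expect_error(value_iteration(mdp$R, gamma = 0.85, transition = mdp$T,
                               tol = 0), "tol")
})

test_that("value iteration is invariant to sample ordering", {
  set.seed(41)
  coh <- generate_cohort(cohort_config(100, seed = 41))
  smp <- cohort_samples(coh)
  q1 <- value_iteration(estimate_models(smp))$q
  q2 <- value_iteration(estimate_models(smp[sample(nrow(smp)), ]))$q
  expect_identical(q1, q2)
})

test_that("identical rewards make every action a maximizer at all levels", {
  set.seed(51)
  grid <- expand.grid(state = 0:7, action = persuasion_types(),
                      stringsAsFactors = FALSE)
  s <- make_samples(grid$state, grid$action, rep(0.25, nrow(grid)),
                    sample(0:7, nrow(grid), TRUE))
  for (lv in 1:3) {
    pol <- policy_for_level(lv, s)
    expect_true(all(vapply(pol$argmax_set, length, integer(1)) == 5L))
  }
})

test_that("level-1 policies are constant across states", {
  set.seed(61)
  coh <- generate_cohort(cohort_config(120, seed = 61))
  pol <- policy_for_level(1, cohort_samples(coh))
  expect_length(unique(pol$mapping), 1L)
})

test_that("gamma = 0 makes level 3 reproduce level 2's argmax sets", {
  set.seed(71)
  # deterministic next states: every (s, a) pair always lands in one state
  n <- 400
  st <- sample(0:7, n, TRUE)
  ac <- sample(persuasion_types(), n, TRUE)
  nxt <- (st * 3 + action_index(ac)) %% 8
  s <- make_samples(st, ac, runif(n, -1, 1), nxt)
  p2 <- policy_for_level(2, s)
  p3 <- policy_for_level(3, s, gamma = 0)
  expect_identical(p2$argmax_set, p3$argmax_set)
})

test_that("policy construction enforces its preconditions", {
  s <- make_samples(0, "COMMITMENT", 0.1, 1)
  empty <- s[0, ]
  expect_error(policy_for_level(1, empty), "no samples")
  expect_error(policy_for_level(4, s), "weights")
  expect_error(policy_for_level(2, s, weights = 1), "uniform")
})

test_that("estimated models converge to the simulator's ground truth", {
  truth <- planted_truth(best_actions = c(4, 4, 4, 4, 1, 1, 1, 1))
  l1 <- vapply(c(60, 600, 4000), function(np) {
    coh <- generate_cohort(cohort_config(np, n_sessions = 5, seed = 81),
                           truth = truth)
    m <- estimate_models(cohort_samples(coh))
    mean(abs(m$transition - truth$transition))
  }, numeric(1))
  expect_true(all(diff(l1) < 0))
})
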