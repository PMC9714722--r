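test_that("the same seed reproduces the cohort exactly", {
  c1 <- generate_cohort(cohort_config(40, seed = 123))
  c2 <- generate_cohort(cohort_config(40, seed = 123))
  expect_identical(c1$records, c2$records)
  expect_identical(c1$traits, c2$traits)
})

test_that("without noise, efforts equal the rounded true means", {
  truth <- planted_truth(best_actions = rep(2, 8), base = 4.3, margin = 2,
                         noise_sd = 0, person_sd = 0)
  coh <- generate_cohort(cohort_config(60, n_sessions = 3, seed = 7),
                         truth = truth)
  smp <- cohort_samples(coh)
  idx <- cbind(smp$state + 1L, match(smp$action, persuasion_types()))
  expect_equal(smp$effort, round(truth$reward_mean[idx]))
})

test_that("activity types pair up within sessions 1-2 and 3-4", {
  for (seed in 1:20) {
    set.seed(seed)
    history <- character(0)
    types <- character(5)
    for (sess in 1:5) {
      act <- assign_activity(history, sess)
      history <- c(history, act$activity_id)
      types[sess] <- act$activity_type
    }
    expect_setequal(types[1:2], activity_types())
    expect_setequal(types[3:4], activity_types())
    expect_true(types[5] %in% activity_types())
    expect_equal(anyDuplicated(history), 0L)
  }
})

test_that("a used similarity group is never assigned again", {
  pool <- default_activity_pool()
  grp <- pool$similarity_group[match("S01", pool$activity_id)]
  twin <- setdiff(pool$activity_id[pool$similarity_group == grp], "S01")
  expect_length(twin, 1)  # the cross-type near-duplicate of S01
  for (seed in 1:200) {
    set.seed(seed)
    history <- "S01"
    for (sess in 2:5) {
      act <- assign_activity(history, sess, pool)
      history <- c(history, act$activity_id)
    }
    expect_false(twin %in% history)
    groups <- pool$similarity_group[match(history, pool$activity_id)]
    expect_equal(anyDuplicated(groups), 0L)
  }
})

test_that("assignment errors once the eligible pool is exhausted", {
  pool <- default_activity_pool()
  smoking <- pool$activity_id[pool$activity_type == "SMOKING"]
  expect_error(assign_activity(smoking[1:2], 3,
                               pool[pool$activity_id %in% smoking[1:3], ]),
               "eligible")
})

test_that("cohort and trait tables round-trip through CSV", {
  coh <- generate_cohort(cohort_config(25, seed = 77))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(coh$records, f1)
  write_traits(coh$traits, f2)
  expect_equal(read_cohort(f1), coh$records)
  expect_equal(read_traits(f2), coh$traits)
  expect_error(read_cohort(f2), "cohort")
  unlink(c(f1, f2))
})

test_that("dropout truncates sessions and removes later records", {
  coh <- generate_cohort(cohort_config(300, seed = 5, dropout_rate = 0.3))
  per_person <- table(coh$records$person_id)
  expect_true(any(per_person < 5))
  # sessions are contiguous from 1
  by_p <- split(coh$records$session, coh$records$person_id)
  expect_true(all(vapply(by_p, function(s) all(s == seq_along(s)),
                         logical(1))))
})

test_that("empirical transitions approach the generating transition", {
  truth <- default_ground_truth()
  coh <- generate_cohort(cohort_config(6000, n_sessions = 5, seed = 13),
                         truth = truth)
  m <- estimate_models(cohort_samples(coh))
  tv <- apply(abs(m$transition - truth$transition), c(1, 2), sum) / 2
  # ~600 draws per (s, a) on average; rare cells carry the largest
  # binomial error, so the max is bounded more loosely than the mean
  expect_lt(max(tv), 0.12)
  expect_lt(mean(tv), 0.05)
})

test_that("states recomputed from raw answers match the simulator's states", {
  coh <- generate_cohort(cohort_config(250, seed = 31))
  ans <- as.matrix(coh$records[, paste0("ans_", 1:10)])
  thr <- fit_thresholds(ans)
  sig <- coh$config$signal_features
  sel <- structure(list(chosen = sig, scores = rep(NA_real_, 10),
                        level = 2L), class = "feature_selection")
  states <- encode_state(binarize(ans, thr), sel)
  expect_equal(states, coh$records$state_index)
})
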