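test_that("kappa is 1 for identical lists and symmetric", {
  set.seed(3)
  a <- sample(persuasion_types(), 40, TRUE)
  b <- sample(persuasion_types(), 40, TRUE)
  expect_equal(cohens_kappa(a, a), 1)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  expect_error(cohens_kappa(a, b[1:10]), "length")
})

test_that("kappa matches the hand-computed reference cases", {
  # disjoint constant lists: observed and expected agreement both 0
  expect_equal(cohens_kappa(rep("COMMITMENT", 8), rep("CONSENSUS", 8)), 0)
  # crossed 2x2 lists: p_o = 0.5 = p_e
  expect_equal(cohens_kappa(c("x", "x", "y", "y"), c("x", "y", "x", "y")), 0)
  # both constant and identical: defined as 1
  expect_equal(cohens_kappa(rep("AP", 5), rep("AP", 5)), 1)
})

test_that("Landis-Koch bands label kappa values as in the guidelines", {
  expect_equal(interpret_kappa(0.33), "fair")
  expect_equal(interpret_kappa(0.49), "moderate")
  expect_equal(interpret_kappa(1.0), "almost perfect")
  expect_equal(interpret_kappa(-0.2), "poor")
  expect_equal(interpret_kappa(c(0.1, 0.7)), c("slight", "substantial"))
  expect_error(interpret_kappa(1.2), "-1, 1")
})

test_that("a strict unique argmax makes one repetition deterministic", {
  set.seed(13)
  n <- 600
  st <- sample(0:7, n, TRUE)
  ac <- sample(persuasion_types(), n, TRUE)
  # planted unique best action per state with a wide margin
  rew <- ifelse(ac == persuasion_types()[st %% 5 + 1], 0.9, -0.9) +
    runif(n, -0.01, 0.01)
  smp <- make_samples(st, ac, rew, sample(0:7, n, TRUE),
                      activity_type = sample(activity_types(), n, TRUE))
  pl <- resample_policies(smp, "BOTH", level = 2, n_per_type = 250,
                          reps = 1)
  direct <- policy_for_level(2, smp)
  # with this margin, the resample still recovers the planted policy
  expect_equal(pl$labels, unname(persuasion_types()[(0:7) %% 5 + 1]))
  expect_equal(unname(direct$mapping), persuasion_types()[(0:7) %% 5 + 1])
})

test_that("resampling is reproducible and validates pool sizes", {
  set.seed(23)
  coh <- generate_cohort(cohort_config(200, seed = 23))
  smp <- cohort_samples(coh)
  set.seed(99)
  a <- resample_policies(smp, "SMOKING", 2, n_per_type = 100, reps = 5)
  set.seed(99)
  b <- resample_policies(smp, "SMOKING", 2, n_per_type = 100, reps = 5)
  expect_identical(a$labels, b$labels)
  expect_error(resample_policies(smp, "SMOKING", 2, n_per_type = 1e5),
               "fewer than")
})

test_that("same-type agreement exceeds cross-type agreement on split truths", {
  # the two activity types are generated under different optimal policies,
  # so resamples of the same type should agree more than resamples across
  # types, averaged over seeded replications
  same <- numeric(0); cross <- numeric(0)
  for (seed in 1:8) {
    set.seed(seed)
    n <- 1200
    st <- sample(0:7, n, TRUE)
    ac <- sample(persuasion_types(), n, TRUE)
    tp <- sample(activity_types(), n, TRUE)
    best <- ifelse(tp == "SMOKING", persuasion_types()[st %% 5 + 1],
                   persuasion_types()[(st + 2) %% 5 + 1])
    rew <- ifelse(ac == best, 0.6, -0.2) + runif(n, -0.3, 0.3)
    smp <- make_samples(st, ac, pmin(pmax(rew, -1), 1), sample(0:7, n, TRUE),
                        activity_type = tp)
    s1 <- resample_policies(smp, "SMOKING", 2, n_per_type = 300, reps = 10)
    s2 <- resample_policies(smp, "SMOKING", 2, n_per_type = 300, reps = 10)
    p1 <- resample_policies(smp, "PHYSICAL_ACTIVITY", 2, n_per_type = 300,
                            reps = 10)
    same <- c(same, cohens_kappa(s1, s2))
    cross <- c(cross, cohens_kappa(s1, p1))
  }
  expect_gt(mean(same), mean(cross))
})

test_that("cross-type agreement approaches 1 under identical ground truth", {
  set.seed(43)
  n <- 4000
  st <- sample(0:7, n, TRUE)
  ac <- sample(persuasion_types(), n, TRUE)
  tp <- sample(activity_types(), n, TRUE)
  best <- persuasion_types()[st %% 5 + 1]
  rew <- ifelse(ac == best, 0.7, -0.3) + runif(n, -0.2, 0.2)
  smp <- make_samples(st, ac, pmin(pmax(rew, -1), 1), sample(0:7, n, TRUE),
                      activity_type = tp)
  s <- resample_policies(smp, "SMOKING", 2, n_per_type = 1500, reps = 20)
  p <- resample_policies(smp, "PHYSICAL_ACTIVITY", 2, n_per_type = 1500,
                         reps = 20)
  expect_gt(cohens_kappa(s, p), 0.95)
})

test_that("the agreement report covers main and reference comparisons", {
  set.seed(53)
  coh <- generate_cohort(cohort_config(150, seed = 53))
  smp <- cohort_samples(coh)
  traits <- scale_traits(as.matrix(coh$traits[, paste0("personality_", 1:5)]),
                         coh$traits$ttm_stage)
  rownames(traits) <- coh$traits$person_id
  rep <- agreement_report(smp, levels = c(2, 4), n_per_type = 80, reps = 4,
                          traits = traits, seed = 1)
  expect_equal(nrow(rep), 10)
  expect_setequal(unique(rep$analysis), c("main", "reference"))
  expect_true(all(rep$kappa >= -1 & rep$kappa <= 1))
  expect_equal(rep$interpretation, interpret_kappa(rep$kappa))
})
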