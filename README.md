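# persuadeRL

Personalized tabular reinforcement learning for choosing persuasive
message types in digital behavior-change interventions — plus the
evaluation machinery such algorithms need.

## The problem

A virtual coach assigns its users small preparatory activities for
quitting smoking or becoming more physically active, and accompanies each
assignment with one of five persuasion types: **commitment**,
**consensus**, **authority** (the Cialdini principles), **action
planning** (if-then plans), or **no persuasion**. Which type should it
send to this person, in this state, now? persuadeRL is for researchers
building and stress-testing algorithms that answer that question from
longitudinal persuasion logs.

## The model

The coach faces an MDP ⟨S, A, R, T, γ⟩ with γ = 0.85:

- **S**: 8 states from ten 5-point questionnaire answers (COM-B
  self-evaluation items, self-efficacy, identity items), mean-split
  binarized and reduced to three selected features (2³ = 8).
- **A**: the five persuasion types.
- **R**: self-reported effort e ∈ [0, 10] mapped to [−1, 1] around the
  frozen training-batch mean effort ē:
  r = −1 + e/ē if e < ē; 1 − (10−e)/(10−ē) if e > ē; 0 at ē.
- **T, R(s,a,s′)**: tabular (optionally similarity-weighted) estimates;
  Q-values by value iteration.

Four nested policy complexity levels: (1) best average reward, (2) best
average reward in the person's state, (3) best Q-value, (4) best
similarity-weighted Q-value, where each sample is weighted by
w_ij = max(s_ij / Σ_k s_ik, 0.0001) with similarities from Euclidean
distances between six-dimensional scaled trait vectors (Big-Five +
TTM stage).

Around this core the package provides a synthetic-cohort simulator with
configurable ground truth (the published-data schema, no download
needed), a resampled policy-agreement analysis with Cohen's κ and
Landis–Koch interpretation, Monte-Carlo Bayesian power analysis, Cohen's
regression sample-size rule, and a sample-size versus Q-error study.
See `vignette("persuasion-algorithm")` for the full methods account.

## Worked example

```r
library(persuadeRL)

# simulate a 500-person cohort under the default ground truth
coh <- generate_cohort(cohort_config(n_people = 500, seed = 42))
smp <- cohort_samples(coh)
attr(smp, "mean_effort")   # 5.208 — the frozen reward anchor

# level-3 policy: greedy on Q-values from value iteration
pol <- policy_for_level(3, smp, gamma = 0.85)
writeLines(render_policy(pol))
#> Complexity level 3 policy
#> State feature                               1    2    3    4    5    6    7    8
#> F1                                          0    0    0    0    1    1    1    1
#> F2                                          0    0    1    1    0    0    1    1
#> F3                                          0    1    0    1    0    1    0    1
#> Action                                      AP   AP   AP   AP   Com. AP   Com. Com.
```

The default ground truth makes action planning (AP) most effective in
low-motivation states (first bit 0) and commitment (Com.) in
high-motivation states (first bit 1); the learned policy recovers that
structure from 2,000 noisy samples, with one state (bits 101) still
misassigned at this sample size.

```r
# design-time calculations
bayes_power(n_per_cond = 129, delta = 0.3, n_sims = 500,
            bf_threshold = 19, seed = 1)
#> Monte-Carlo Bayesian power: 0.76
#>   n per condition = 129, delta = 0.3, BF threshold = 19, simulations = 500
regression_sample_size(3, "medium")                # 76
regression_sample_size(3, "medium", n_actions = 5) # 380
```

The Monte-Carlo power fluctuates around its closed form
Φ(0.3·√(129/2) − z₀.₉₅) ≈ 0.78 with a standard error of ~0.019 at 500
simulations.

A command-line surface over the same functions ships in
`inst/cli/persuadeRL.R` (subcommands `simulate`, `preprocess`, `train`,
`recommend`, `agreement`, `power`, `samplesize`, `render-policy`).

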