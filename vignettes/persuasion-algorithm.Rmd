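---
title: "Choosing persuasive messages with a personalized tabular RL algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing persuasive messages with a personalized tabular RL algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persuadeRL)
```

## The problem

Digital behavior-change applications assign their users small preparatory
activities — write down your reasons for quitting smoking, plan a walking
route — and accompany each assignment with a persuasive message. The message
can invoke commitment, social consensus, or expert authority; it can prompt
an if-then action plan; or it can be omitted entirely. Which of these five
*persuasion types* should a virtual coach send to this person, now?

persuadeRL implements a tabular reinforcement-learning answer with four
nested complexity levels, each adding one consideration:

1. **Best average reward** — send the persuasion type with the highest mean
   reward overall.
2. **Best average reward in state** — condition on the person's current
   state.
3. **Best Q-value** — also weigh the states a persuasion type leads to,
   because a message that pays off less today can put the person in a state
   where tomorrow's message works better.
4. **Best similarity-weighted Q-value** — additionally weight every observed
   sample by how similar its contributor is to the person being persuaded.

The package also carries the evaluation machinery such an algorithm needs:
a synthetic-cohort simulator with configurable ground truth, a resampled
policy-agreement analysis (Cohen's $\kappa$), and the Monte-Carlo power and
regression sample-size computations used to design studies of this kind.

## The decision model

Formally the coach faces an MDP $\langle S, A, R, T, \gamma\rangle$.

**Action space.** Five persuasion types: commitment, consensus, authority,
action planning, no persuasion. This order is canonical: it is the
deterministic tie-break order and the serialization order.

**Reward.** After each session the person reports the effort they put into
the assigned activity on a 0–10 scale. With $\bar e$ the mean effort of the
training batch,

$$r = \begin{cases}
  -1 + e/\bar e & e < \bar e\\
  1 - (10-e)/(10-\bar e) & e > \bar e\\
  0 & e = \bar e,
\end{cases}$$

so a typical effort earns 0 and the spacing below and above the mean is
even. $\bar e$ is *frozen* once the training batch is fixed; recomputing it
as data accrue would silently re-scale old rewards and make policies
incomparable across time. The formula degenerates at $\bar e \in \{0, 10\}$,
which `compute_reward()` rejects.

**State space.** Ten questionnaire answers per session (seven COM-B
self-evaluation items, self-efficacy, smoker identity, physical-activity
identity, all on 5-point scales) are reduced in two steps. First each
feature is split at its training-set mean (answer $\ge$ mean $\to$ 1). The
smoker-identity item's extra "Smoker" option is mapped onto an ordered
1–5 code beforehand, so all ten features are treated uniformly. Second,
three features are selected, giving $2^3 = 8$ states.

The selection score is a one-shot variant of the G-algorithm's question
"does this bit change action values": for each feature $f$ we collapse the
data onto the 2-state MDP induced by $f$ alone and score
$\sum_a |V(f{=}1,a) - V(f{=}0,a)|$, with $V$ the state-conditional mean
reward at level 2 and the single-feature Q-value at levels 3–4. We chose
this flat score over the G-algorithm's recursive tree because the target
state space is flat (three bits, jointly selected) and the recursive
variant needs far more data than two training sessions provide. A constant
feature scores exactly 0 by definition rather than by arithmetic accident,
and score ties break toward the lower feature index so selection is
deterministic.

**Model estimation.** $R(s,a,s')$ is the (weighted) mean reward of the
samples matching the cell and $T(s,a,\cdot)$ the (weighted) relative
frequency of next states. Cells with no data get reward 0 — the neutral
value of a mean-effort response — and a uniform next-state distribution.
With 516-sample training batches and 40 state–action pairs, empty cells
are a real possibility, and these defaults keep value iteration well
defined without pushing any action's value up or down. Estimated cell
means are asserted (not clipped) to lie in $[-1,1]$: a violation would
indicate corrupted rewards, not rounding.

**Planning.** Q-values solve
$Q(s,a) = \sum_{s'} T(s,a,s')\,[R(s,a,s') + \gamma \max_{a'} Q(s',a')]$
by synchronous value iteration from $Q=0$. The discount $\gamma = 0.85$
favors near-future rewards: an early failed persuasive attempt risks the
person disengaging entirely, so small early wins matter more than distant
ones. The tolerance (default $10^{-9}$) bounds the sup-norm distance of
the returned Q to the true fixed point — the stopping rule divides by the
contraction factor $\gamma/(1-\gamma)$ rather than testing the raw sweep
change — which is orders of magnitude below any decision margin here.

**Personalization.** For level 4, each person has a six-dimensional trait
vector: the five Big-Five dimensions and the TTM stage of change for
physical activity, each min–max scaled to $[0,1]$ using the instrument
bounds (1–7 and 1–5). We scale by instrument bounds rather than the
observed sample range so that a new extreme respondent does not re-scale
everyone else. Euclidean distances to the people in the sample bank are
mapped linearly to similarities — smallest distance $\to$ 1, largest
$\to$ 0 — and per-person weights are

$$w_{ij} = \max\!\left(\frac{s_{ij}}{\sum_k s_{ik}},\ 0.0001\right),$$

the floor guaranteeing every sample a voice. The linear distance-to-
similarity map is the simplest reading of "largest distance to 0, smallest
to 1" and is isolated in `pairwise_similarity()` should a different shape
be wanted. When all distances are equal (including a single contributor)
there is no information to discriminate, every similarity is set to 1, and
level 4 gracefully reduces to level 3. A person's own samples enter at
distance 0, hence maximal similarity.

## The synthetic cohort

`generate_cohort()` emulates the longitudinal persuasion-log schema: per
person up to five sessions, each with ten raw 5-point answers, an assigned
activity (id and type), the persuasion type sent, and the effort reported
at the following session. Ground truth is explicit: a true mean-effort
matrix over (state, action), a true transition array, Gaussian effort
noise rounded and clipped to the 0–10 integer scale, and a per-person
effort offset. The default truth places mean efforts around 5 with modest
action-by-state structure and noise chosen so simulated efforts have mean
≈ 5.3 and SD ≈ 2.6, the scale typical of self-reported effort data.

Activity assignment follows the protocol rules: sessions 1–2 cover both
activity types in random order, sessions 3–4 likewise, the fifth session's
type is uniform random, and an activity — or any member of its declared
similarity group — is never assigned twice. "Very similar" activities are
modeled as explicit similarity groups in the pool table, since similarity
of content is a curation judgment, not a computable rule. Dropout, when
enabled, is a per-session Bernoulli event that truncates the person's
record.

Three raw features (configurable; by default features 5, 4 and 8) carry
the true state bits — answers 3–5 when the bit is on, 1–2 when off — so
the mean-split binarization recovers the generating state, while the other
seven features are uniform noise. When a trait effect is configured, the
population splits into two clusters with different action effectiveness,
and traits are drawn from the cluster's side of the instrument scales so
that trait similarity is genuinely informative.

What the simulator does *not* emulate: ordinal response quirks (acquiescence,
floor/ceiling clustering), time-varying preferences, informative dropout,
and any correlation between traits and state dynamics beyond the
configured cluster effect. Tests passing on this cohort therefore certify
the algorithmic machinery — estimation, planning, weighting, agreement
arithmetic — not effectiveness on human data.

## The agreement analysis

To ask whether the optimal policy transfers between activity types, the
package draws `n_per_type` samples per included type (without replacement
by default; with ~1,000 draws from pools of ~1,200 the with-replacement
variant is nearly identical and available via a flag), computes the
optimal policy at the chosen level, resolves tied maxima *uniformly at
random*, and concatenates the eight state actions over 100 repetitions.
Cohen's $\kappa$ between two such lists, with expected agreement from the
lists' marginal action frequencies, measures chance-corrected policy
agreement; Landis–Koch bands give the qualitative label. Both lists
constant and identical is defined as $\kappa = 1$.

Level-4 policies are per-person, so the analysis needs a convention for
whose policy enters the list: we compute it for a single reference trait
vector, by default the component-wise median of the cohort. This is an
explicit configuration choice, not a claim about how any particular study
collapsed per-person policies.

## Design-time calculations

**Bayesian Monte-Carlo power.** Two conditions with standard-normal
outcomes and true mean difference 0.3 (a medium effect), $n$ per
condition; per simulated experiment we compute a directional Bayes factor
for the second mean exceeding the first and count successes at BF ≥ 19.
The BF construction is the flat-prior one: $BF = p/(1-p)$ with $p$ the
posterior probability of a positive difference under an improper uniform
prior and the pooled-variance posterior $t$. With prior odds 1:1 this
makes BF ≥ 19 equivalent to posterior probability ≥ 0.95, so the
Monte-Carlo power has the closed form
$\Phi(\delta\sqrt{n/2} - z_{0.95})$ as a cross-check — about 0.78 at
$n = 129$, $\delta = 0.3$:

```{r power, eval = FALSE}
bayes_power(n_per_cond = 129, delta = 0.3, n_sims = 500,
            bf_threshold = 19, seed = 1)
#> Monte-Carlo Bayesian power: 0.76
pnorm(0.3 * sqrt(129 / 2) - qnorm(0.95))
#> [1] 0.7777163
```

**Regression sample size.** Cohen's rule $n = \lceil L/f^2 + u\rceil$ with
the tabled noncentrality $L$, computed here from the noncentral
chi-square (large-error-df) limit that reproduces the printed tables
($u = 3$, power 0.80 $\Rightarrow L = 10.90$). A medium effect
($f^2 = 0.15$), $\alpha = 0.05$, power 0.80 and three predictors give
$n = 76$; scaling by the five actions gives 380. The alternative
convention $n = \lceil L/f^2 + u + 1\rceil$ is exposed as a flag; we
default to the one matching the published table values. A lower bound of
$u + 2$ keeps the limit of huge effects identifiable.

**Sample size versus Q-error.** `q_error_study()` treats the full-data
Q-function as reference, re-estimates Q from random subsamples, and
reports (i) the mean absolute Q difference over the 40 cells and (ii) the
mean reference-Q gap between estimated-optimal and reference-optimal
actions — the value actually lost by acting on the estimated policy. Both
are exactly 0 at full size (subsampling is without replacement) and
shrink with subsample size.

## Numerical conventions, in one place

- Unvisited (s, a, s′) cells: reward 0, uniform next-state row.
- Tie-breaks: canonical action order when determinism matters
  (serialization, reproducible training); uniform random in the agreement
  analysis, as that analysis requires. The mode is always an explicit
  argument, never ambient state.
- Value iteration: synchronous sweeps, $Q_0 = 0$, tolerance interpreted
  as a fixed-point error bound.
- Degenerate similarity spread: all similarities 1.
- Weight validation: weights must be strictly positive and aligned 1:1
  with samples; scaling all weights by a constant provably changes
  nothing, and the tests pin that invariance.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the expected
behavior sharp rather than marginal: planted-policy recovery uses 10,000
one-transition people with a 2-effort-point margin and noise SD 1 (the
per-cell standard error is then ~0.06 effort points, so recovery in 8/8
states is the expected outcome, not luck); the trait-cluster experiment
uses 2,000 people with a 3-point cluster effect; the Q-error study uses a
2,366-sample cohort with 30 repetitions per size; value iteration is
checked against a 200-step backward-induction oracle on 100 random MDPs,
where the analytic tail bound $\gamma^{200}/(1-\gamma)$ is ~7·10⁻¹⁵.
Cross-type agreement contracts are verified over 8 seeded replications of
a split-truth cohort.

## Known limitations

- The algorithm is strictly batch: models are estimated once from a frozen
  training set. There is no online updating, exploration strategy, or
  function approximation.
- The 8-state abstraction is only as good as the three selected features;
  the selection score is greedy and one-shot by design.
- The similarity metric is Euclidean on six traits; other distances are an
  extension point, not implemented.
- Synthetic-cohort results certify machinery, not human effectiveness;
  see the simulator section for the fidelity boundary.
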