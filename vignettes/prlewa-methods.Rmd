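---
title: "Models and methods behind prlewa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prlewa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlewa)
```

`prlewa` studies two decision-making capacities that dissociate in
psychosis: goal-directed action (probed by outcome devaluation) and
flexible value updating (probed by probabilistic serial-reversal
learning). This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and
does not emulate. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The task environments

The serial-reversal task (`prl_task()`) has 11 stages with a fixed
stimulus pair. The target option pays with probability 0.80 throughout;
the nontarget pays 0.20 in stages 1–7 (discrimination, first reversal,
SRL1) and 0.40 in the four SRL2 stages, which also pay 2 or 6 credits
per win with equal probability (stages 1–7 pay 1 credit). A stage
completes after 6 consecutive target choices, and the target reverses
at every stage boundary. Reward draws are independent across trials:
the design specifies only marginal probabilities, so no
reward-matching or debiasing schedule is imposed.

Human testing imposes no trial cap, but simulations need one:
`max_trials` defaults to 80 per stage. A truncated stage marks the
session "incomplete from stage k" and, by default, later stages are
not run — mirroring the attrition visible in real cohorts, where some
participants never produce SRL2 data. Two designs need the opposite
behaviour and set `advance_on_truncation = TRUE`: the substitution
study (impaired agents truncate often, and dropping them would bias
condition comparisons) and `recovery_task()`, which makes the
completion criterion equal to the per-stage cap to produce
fixed-length sessions for estimator certification.

The devaluation procedure (`deval_config()`) reproduces the published
constants: token earning needs a uniform draw of 5–10 consecutive
responses; a comprehension question follows every third earning round
and training ends at six consecutive correct answers; the choice test
runs 10 blocks of 12 s with no feedback. Choice-test responding is
modelled as two independent Poisson processes. That is a contract
about counts and rates, not a claim about participants' motor
dynamics; it gives the right first two moments for free-operant counts
and makes the response bias estimable. Probe questions are Bernoulli
with a configurable accuracy; their content is not simulated.

## The models

The experience-weighted attraction (EWA) model keeps, per option, an
attraction $A_j$ and an experience weight $n_j$, both starting at 0.
Choosing option $c$ with payoff $r$ updates only that option:

$$n_c \leftarrow \rho\, n_c + 1, \qquad
  A_c \leftarrow \frac{\phi\, n_c^{old} A_c + r}{n_c^{new}},$$

with softmax choice $P(j) \propto \exp(\beta A_j)$. The first update
reduces to $A_c = r$, so no initialization constant is needed. $\rho$
is the parameter that matters only when contingencies change: a high
$\rho$ lets $n_c$ grow, so each new payoff moves the attraction little
and reversals are absorbed slowly. $\phi$ decays prior attractions
(figures conventionally report $1-\phi$ as a learning rate;
`coef(fit, "reported")` applies that transform, the internal math
never does). The experience weight is per option and only the chosen
option's weight updates; that is the convention of the reversal
learning variant this model family descends from. The
reward/punishment (RP) model is a Rescorla–Wagner learner with
separate rates for positive and negative prediction errors and, by
default, a fictive update of the unchosen option toward the negated
payoff with the opposite-valence rate. Both the fictive update and a
chosen-only switch are exposed because published descriptions of this
model rarely print the equations.

**Payoff coding.** How 0/1 and 0/2/6 credit outcomes enter the models
is genuinely underdetermined in the source designs. The default codes
win as +1 and loss as −1 regardless of magnitude — the standard coding
in this model family. A `"magnitude"` coding (credits divided by the
stage's expected win credit, losses −1) ships for sensitivity
analysis. Tests and defaults use the sign coding.

Likelihoods are computed in compiled code (`src/loglik.cpp`) for
fitting speed; the exported single-step functions `ewa_update()`,
`rp_update()` and `choice_probabilities()` are the reference
implementation, and the test suite asserts the two routes agree to
1e−10 on random sessions. The compiled agent simulator consumes the
RNG stream in exactly the same order as the R policy path, so
`simulate_agent()` and `run_session()` + `make_agent_policy()` produce
bit-identical sessions under one seed — also asserted.

## Fitting

`prl_fit()` performs MAP estimation: unit-interval parameters are
logit-transformed with Normal(0, 1.5²) priors on the transformed
scale, $\beta$ is log-transformed with a Normal(log 2, 1²) prior and a
hard cap at 20 — beyond that the softmax saturates and the likelihood
is flat, which produces optimizer drift rather than information.
Optimization is multi-start L-BFGS-B (first start at the prior mode,
the rest drawn from the prior; 10 starts by default), and ties between
equal optima are broken by the lexicographically smallest parameter
vector so fits are reproducible. A fit whose starts all fail returns a
flagged object, never an exception, so cohort loops don't die on one
subject.

MAP point estimates replace the hierarchical Bayesian machinery often
used for this model family deliberately: every quantity consumed
downstream (group parameter means, substitution-study inputs) is a
point summary, and the package stays dependency-light.
`read_params()`/`write_params()` accept externally fitted posterior
means in the same parameter-file format if a user prefers them. No
attempt is made to match any particular published posterior — the
priors and diagnostics of those fits are not public.

`parameter_recovery()` certifies the estimator by simulate-and-refit.
On the default 500-trial design (20 reversal blocks of 25 trials, 40
subjects) the suite requires Pearson r ≥ 0.7 for $\beta$ and ≥ 0.6 for
$\rho$. The 11-stage task yields far fewer trials and noisier
recovery; the recovery report exposes that rather than hiding it, and
the suite checks that correlations do not decrease when sessions
lengthen from 100 to 500 trials.

## Behavioural metrics

Trials to criterion counts the trial at which the trailing run of
correct choices first reaches the criterion (the criterion trials are
included, so 6 is the floor). Perseverative errors count incorrect
choices in the first 6 trials after each reversal. Win-stay/lose-shift
proportions are computed over applicable consecutive trial pairs with
their denominators always reported; an empty denominator yields `NA`,
never 0/0. Pairs spanning a stage boundary count by default: reversals
are silent and the stimulus pair never changes, so the t → t+1
transition is a genuine strategy observation even when the
contingencies flipped in between (a `within_stage` switch exists
because the alternative reading is defensible). Phase summaries are
per-stage means; incomplete stages contribute their observed trials to
win-stay/lose-shift but are excluded from trials-to-criterion means
and counted separately — attrition in the source designs was handled
by exclusion, not imputation. Win-stay by credit magnitude is only
defined in SRL2, the only phase with {2, 6} wins.

## Subgrouping

`classify_goal_directed()` z-scores the devaluation response bias and
the valued-action response rate (sample-SD convention, fixed and
documented so solutions are tool-independent), runs Ward's-method
agglomerative clustering on squared Euclidean distances — the classical
SPSS pairing, `hclust(dist(x)^2, method = "ward.D")` — cuts at k = 2
(k is fixed by design, not chosen by criterion), and labels the
higher-mean-bias cluster "intact". Clustering is run on the pooled
cohort rather than per group, which is what lets impaired control
subjects surface. Subjects with undefined bias (zero responses) are
excluded and listed in the result. The empirical boundary interval
(maximum impaired bias, minimum intact bias) is reported because the
split point, not the cluster means, is the scientifically portable
quantity.

## The substitution study

`substitution_conditions()` builds nine conditions: three group
baselines plus, on the control background, the three single and three
pairwise substitutions of impaired-group parameter values (the triple
substitution is the impaired baseline and is not duplicated). Each
condition simulates 20 agents by default through the full 11-stage
task, all agents using the group's point parameters — the study design
describes simulations from extracted group parameters, not from
subject-level draws (a dispersion option exists on the generator side
for sensitivity work). Outcomes are the SRL1 mean trials-to-criterion
(truncated stages contribute the cap, 80) and SRL1 win-stay, mirroring
the two panels such studies report.

Every condition is compared to the control simulation with Dunnett's
many-to-one procedure. Adjusted p-values come from numerically
integrating the joint distribution of the correlated t statistics
(Genz–Bretz quasi-Monte-Carlo via `mvtnorm::pmvt`, absolute tolerance
1e−4, integration RNG fixed so results are reproducible; the
unbalanced generalization applies when group sizes differ). At k = 1
this reduces exactly to the pooled two-sample t-test, which the suite
asserts, and with identical parameter sets for all conditions the
familywise false-positive rate over 200 seeded replications must sit
near the nominal 5%.

## The synthetic cohort generator

`generate_cohort()` stands in for undeposited participant data. What
it emulates: (i) reversal sessions generated by EWA agents whose
parameters have group structure; (ii) a bimodal devaluation bias across
the pooled cohort — a two-component Beta mixture with the intact
component centred at 0.95 (concentration 40) and the impaired at 0.50
(concentration 20), flanking the boundary region where real cohorts
split; (iii) the 34 control / 45 psychosis composition with 6/34 and
27/45 impaired fractions. A subject's impairment component drives both
its bias draw and which EWA parameter set it plays the task with —
impaired controls draw from the impaired set, which is exactly the
structure that makes pooled clustering find them. Devaluation response
rates are the subject's total rate (Gamma, CV 0.30 around 1.5
responses/s) split by its bias; ratings drop by about 3 Likert points
for the devalued token (one point less in impaired subjects, mirroring
blunted re-rating).

The default group parameter sets are configuration, not estimates:
control-intact (φ = 0.60, ρ = 0.30, β = 3.0), psychosis-intact
(0.75, 0.35, 2.5), impaired (0.75, 0.75, 2.0). They were chosen once,
by simulation during design, to reproduce the qualitative orderings
the empirical literature reports — both psychosis sets decay prior
attraction more (lower reported learning rate), the impaired set has
markedly higher experience decay and lower inverse temperature — and to
place behaviour in a realistic regime: β much above 4 pins control
win-stay to its ceiling, where every contrast trivially separates,
and ρ near 0.9 makes the ρ-substitution alone reproduce the full
deficit pattern, which contradicts the pattern these studies actually
report. With these defaults the full pipeline — generate, summarize,
cluster, fit, substitute, compare — reproduces the headline structure:
the impaired-labelled subgroup is slower to criterion and stays after
wins less, and only the joint ρ + β substitution of *fitted* group
parameters is significant on both outcomes.

What the generator does not emulate: reaction times, session-level
fatigue or attention drift, symptom scales, IQ, medication, or any
correlation between devaluation performance and reversal parameters
beyond the shared component label. Passing pipeline tests therefore
demonstrates that the machinery recovers structure that is present by
construction — not that real cohorts contain that structure.

## Numerical choices and degenerate inputs

- Softmax and log-likelihoods use log-sum-exp / `log1pexp` forms; no
  overflow up to |β·A| in the hundreds.
- Zero-variance feature columns abort z-scoring with the column named;
  a cohort of identical subjects therefore has no two-cluster
  structure and is rejected rather than split arbitrarily.
- Undefined proportions (no applicable pairs, zero responses) are `NA`
  with their zero denominators reported.
- Dunnett comparisons reject zero within-group variance.
- Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state; sub-seeds for loops are derived, kept below
  2³¹, and recorded in outputs (cohort manifests and study manifests
  embed the seed and a spec fingerprint).
- Problem sizes in the shipped suite: 100,000 draws per contingency
  check, 200 replications for type-I control, 40 subjects × 500 trials
  for recovery, one 79-subject cohort for the end-to-end pipeline —
  sizes at which each check's sampling error is small relative to the
  tolerance it is tested against.

## Known limitations

- MAP summaries understate uncertainty; no posterior intervals are
  produced. Group comparisons on fitted parameters inherit shrinkage
  toward the prior (visible as compressed group differences).
- The Ward split occasionally (a few percent of seeds) partitions
  along the response-rate axis rather than the bias axis in borderline
  cohorts; the boundary interval in the result makes such solutions
  easy to spot.
- Win-stay in high-β regimes sits near 1.0, so small absolute
  differences there are large in test-statistic terms; interpret
  effect sizes, not only p-values.
- The devaluation and reversal halves of a synthetic subject are
  linked only through the component label; joint modelling of the two
  tasks is out of scope.
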