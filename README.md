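# prlewa

Decision-making phenotyping for psychosis research: serial-reversal
learning and outcome devaluation, in one reusable pipeline.

A consistent finding in persistent psychosis is that a *subgroup* of
individuals shows broad decision-making deficits: they fail to bias
responding toward a still-valued outcome after devaluation (impaired
goal-directed action), and the same people adapt poorly when reward
contingencies reverse. `prlewa` implements the computational core of
that research program so it can be run, tested and extended without
access to participant data:

- **Task environments** — an 11-stage probabilistic serial-reversal
  task (discrimination, first reversal, five SRL1 stages at 80/20
  contingencies, four SRL2 stages at 80/40 with 2-or-6-credit wins,
  six-in-a-row completion criterion) and an outcome-devaluation
  procedure (instrumental training to a six-correct-questions
  criterion, then a 10 x 12 s free-operant choice test with no
  feedback).
- **Reinforcement-learning models** — the experience-weighted
  attraction (EWA) model and a dual-learning-rate reward/punishment
  (RP) model, as update rules, likelihoods, and generative agents.
- **Model fitting** — per-subject MAP estimation with multi-start
  quasi-Newton optimization under weakly informative priors, plus
  parameter-recovery diagnostics that certify the estimator.
- **Behavioural metrics** — trials to criterion, perseverative errors,
  win-stay/lose-shift (overall, per phase, and by win magnitude), and
  devaluation response bias/rates.
- **Subgrouping** — Ward hierarchical clustering (squared Euclidean
  distance, z-scored features) splitting a cohort into intact and
  impaired goal-directed action.
- **Parameter-substitution simulations** — group baselines plus every
  single and pairwise substitution of impaired-group parameters into
  the control background, compared against control simulations with
  Dunnett's many-to-one test.
- **Synthetic cohorts** — a generator producing reversal sessions from
  group-structured EWA agents and bimodal devaluation performance, so
  the whole pipeline is testable end to end.

## The model

Each option j keeps an attraction A_j and an experience weight n_j.
After choosing option c and receiving payoff r (wins coded +1, losses
-1 by default):

    n_c <- rho * n_c + 1
    A_c <- (phi * n_c_old * A_c + r) / n_c_new

and choices follow a softmax, P(j) proportional to exp(beta * A_j).
`phi` is the decay of prior attraction (reported as a learning rate
1 - phi), `rho` the experience decay (higher = accumulated experience
dilutes new outcomes, so value updating is sluggish after reversals),
and `beta` the inverse temperature. The RP model replaces the
experience-weighted average with valence-specific prediction-error
updates (`a_rew`, `a_pun`) and a fictive update of the unchosen option.

## Worked example

```r
library(prlewa)

# a study-sized synthetic cohort: sessions, devaluation tests, ground truth
co <- generate_cohort(default_cohort_spec(seed = 1))
co
#> Synthetic cohort: 79 subjects, seed 1
#>             impaired intact
#>   control         11     23
#>   psychosis       24     21

# behavioural summaries and goal-directed-action subgrouping
summ <- cohort_summary(co$sessions, co$devals)
cl <- classify_goal_directed(summ)
cl
#> Goal-directed action subgroups: 43 intact / 36 impaired
#> bias boundary interval: [0.822, 0.837]

# per-subject EWA fits and group-level parameter sets
fits <- fit_cohort(co$sessions, model = "ewa", seed = 2)
grp <- fitted_group_params(co, fits)
grp$pp_impaired
#> <ewa_params>
#>       phi       rho      beta
#> 0.7229323 0.6744570 1.8951656

# which parameters drive the deficit? substitute impaired values into
# the control background and compare every condition to control
st <- run_simulation_study(grp$control_intact, grp$pp_intact,
                           grp$pp_impaired, n_agents = 20, seed = 7)
st
#> Parameter-substitution simulation study: 9 conditions x 20 agents
#>       condition        metric   mean   sem    p_adj
#>  control_intact      ttc_srl1 11.840 0.382       NA
#>     pp_impaired      ttc_srl1 15.560 0.718 4.11e-04
#>         sub_rho      ttc_srl1 13.830 0.496 1.53e-01
#>        sub_beta      ttc_srl1 13.000 0.339 6.98e-01
#>    sub_rho_beta      ttc_srl1 16.560 0.994 2.98e-06
#>  control_intact win_stay_srl1  0.992 0.004       NA
#>     pp_impaired win_stay_srl1  0.826 0.014 0.00e+00
#>         sub_rho win_stay_srl1  0.923 0.009 9.19e-05
#>        sub_beta win_stay_srl1  0.930 0.011 6.98e-04
#>    sub_rho_beta win_stay_srl1  0.812 0.016 0.00e+00
#> (remaining conditions elided)
```

Reading the output: the impaired baseline takes about four more trials
to reach criterion per SRL1 stage than control and stays after wins far
less often. Substituting the impaired `rho` alone, or `beta` alone,
into the control background reproduces only the win-stay reduction —
neither moves trials-to-criterion significantly. Only the joint
`rho` + `beta` substitution reproduces both deficits, implicating
sluggish experience updating combined with less deterministic choice.

Single-subject fits are ordinary modelling objects:

```r
fit <- prl_fit(co$sessions[[1]], model = "ewa", seed = 2)
summary(fit)   # raw and reporting-convention (1 - phi) parameters
predict(fit)   # per-trial choice probabilities
simulate(fit, nsim = 2, seed = 9)
```

## Package layout

- `R/task.R` — reversal-task and devaluation environments
- `R/models.R` — EWA/RP updates, softmax, likelihoods, agents
  (`src/` holds the compiled likelihood and simulation kernels)
- `R/fit.R` — `prl_fit()` and methods, cohort fitting, recovery
- `R/metrics.R` — behavioural summaries
- `R/cluster.R` — goal-directed-action subgrouping
- `R/simstudy.R` — substitution study and Dunnett comparisons
- `R/cohort.R` — synthetic cohort generator
- `R/io.R` — CSV/JSON interchange (trial tables, devaluation tables,
  parameter and task-config files)

See `vignettes/prlewa-methods.Rmd` for the modelling assumptions,
numerical choices and limitations.
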