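# plgt

Reinforcement-learning modelling of the **probabilistic learning go/no-go
task (PLGT)** — a balanced 2 × 2 design crossing the required action (go vs
no-go) with motivational valence (win money vs avoid an electric shock),
under 80/20 probabilistic feedback.

The package is for researchers who analyse trial-level choice data from this
family of tasks: it simulates the task, fits a family of Q-learning models
hierarchically, compares them, summarizes behavior, and runs mediation
analyses linking subject-level covariates (e.g. extracted regional
activation estimates), model parameters, and performance.

## The model

Each cue `s` carries action values updated by a prediction-error rule, with
softmax choice over action weights:

```
Q_{t+1}(a, s) = Q_t(a, s) + ε δ_t,       δ_t = ρ r_t − Q_t(a, s)
W_t(go, s)    = Q_t(go, s) + b + π V_t(s)
W_t(nogo, s)  = Q_t(nogo, s)
p_t(go)       = exp(W_go) / (exp(W_go) + exp(W_nogo))
V_{t+1}(s)    = V_t(s) + ε (ρ r_t − V_t(s))
```

with outcomes `r ∈ {−1, 0, +1}` (shock, null, reward), learning rate
`ε ∈ (0,1)`, subjective outcome impact `ρ > 0`, action bias `b`, and
Pavlovian factor `π` coupling the stimulus value `V` into action initiation.
Model variants free different subsets of the 12 candidate parameters: `ε`
may be split by prediction-error sign and/or valence (`ε_WP, ε_WN, ε_AP,
ε_AN`), `ρ` by valence (`ρ_W, ρ_A`); `b` and `π` are optional
(`enumerate_models()` lists the default 14-member family).

Estimation is hierarchical type-II maximum likelihood: subject parameters
are normal random effects on an unconstrained scale, fitted by
expectation–maximization with per-subject MAP modes and Laplace curvature
(`em_fit()`), and models are compared by the integrated BIC with
Monte-Carlo marginal likelihoods (`ibic()`, `stepwise_select()`). See the
methods vignette (`vignettes/methods.Rmd`) for the estimation details,
conventions and known limitations.

## Worked example

Simulate a small cohort from a 4-parameter model and refit it:

```r
library(plgt)
spec   <- model_spec("single", "single", bias = TRUE, pavlovian = TRUE)
cohort <- simulate_cohort(default_prior(spec), spec,
                          n_subjects = 12, n_per_cue = 25, n_runs = 2,
                          seed = 42)
fit <- em_fit(cohort$trials, spec, seed = 1)
fit
#> <plgt hierarchical fit> model eps+rho+b+pi
#>   12 subjects, 2400 choices; 32 EM iterations (converged)
#>   total Laplace log evidence: -1350.4178
#>             mu     sigma
#> eps -1.6404929 0.3196471
#> rho  0.8661068 0.4303599
#> b    0.4166402 0.5464687
#> pi   0.1218062 0.4257077

ibic(fit, cohort$trials, n_mc = 1000, seed = 2)
#> <iBIC> 2761.3448  (log marginal -1349.5395, penalty 62.2658, MC se 1.41, n_mc 1000)
```

The population table is on the unconstrained scale (`ε` via logit, `ρ` via
log): `mu = -1.64` for `eps` corresponds to a median learning rate of
`plogis(-1.64) ≈ 0.16`, and `mu = 0.87` for `rho` to a median outcome
impact of `exp(0.87) ≈ 2.4`. The iBIC is −2 × the Monte-Carlo group log
marginal likelihood plus a `k log N` complexity cost; smaller is better.

Behavioral summaries of the same cohort:

```r
acc <- accuracy_by_condition(cohort$trials)
round(tapply(acc$accuracy, acc$condition, mean), 3)
#>   go_to_avoid     go_to_win nogo_to_avoid   nogo_to_win
#>         0.665         0.800         0.592         0.547

sw <- stay_switch_index(cohort$trials)
round(tapply(sw$switch_pct, sw$condition, mean, na.rm = TRUE), 1)
#>   go_to_avoid     go_to_win nogo_to_avoid   nogo_to_win
#>          59.4          39.6          51.6          49.7
```

With a positive go bias and Pavlovian factor in the generating population,
go-to-win is the easiest condition (accuracy 0.80) — the qualitative
signature this task design elicits. The stay/switch index is the percentage
of unfavorable outcomes followed by a response reversal on the next
presentation of the same cue; high values mean inconsistent responding.

Mediation analysis of a subject-level chain X → M → Y with covariate
adjustment and a bootstrap test of the indirect effect:

```r
mediate(data, x = "activation", m = "eps", y = "accuracy",
        covariates = c("sex", "age", "total_shocks"),
        n_boot = 5000, seed = 1)
```

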