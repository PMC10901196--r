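---
title: "Models and methods: reinforcement learning in the probabilistic go/no-go task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plgt)
```

## The task

The probabilistic learning go/no-go task (PLGT) crosses the required action
(go vs no-go) with motivational valence (win money vs avoid an electric
shock) in a balanced 2 x 2 design, with two fractal images per condition
(eight cues). On each trial the subject sees one cue and decides whether to
press (go) or withhold (no-go). Feedback is probabilistic: a correct
response yields the favorable outcome 80% of the time, an incorrect one 20%
of the time. On win cues the favorable outcome is a reward (`+1`), the
unfavorable one null (`0`); on avoid cues the favorable outcome is null and
the unfavorable one a shock (`-1`). When shock feedback is displayed the
shock is physically delivered only half of the time; the models learn from
the displayed feedback, so delivered and omitted shocks enter the likelihood
identically (`shock_delivered` is carried as a flag only, and it feeds the
`total_shocks` covariate).

`cue_conditions()`, `build_schedule()` and `sample_feedback()` encode this
structure once; the simulator and all scoring functions build on them.
Trials are distributed over runs by blocked shuffling (each run receives an
approximately equal share of every image, order randomized within run).
Cue order is otherwise unconstrained, and cue-image assignments are
randomized per simulated subject (each subject gets an independently
shuffled schedule).

## The model family

Every model is a Q-learning observation model with softmax choice. For cue
$s$ and chosen action $a$:

$$Q_{t+1}(a, s) = Q_t(a, s) + \varepsilon\,\delta_t, \qquad
  \delta_t = \rho\, r_t - Q_t(a, s),$$

with outcome $r_t \in \{-1, 0, +1\}$, learning rate $\varepsilon \in (0,1)$
and outcome impact $\rho > 0$. The go weight may add a constant action bias
$b$ and a Pavlovian term $\pi V_t(s)$ coupling the stimulus value into
action initiation:

$$W_t(go, s) = Q_t(go, s) + b + \pi V_t(s), \qquad
  W_t(nogo, s) = Q_t(nogo, s),$$

$$p_t(go) = \frac{e^{W_t(go,s)}}{e^{W_t(go,s)} + e^{W_t(nogo,s)}}, \qquad
  V_{t+1}(s) = V_t(s) + \varepsilon\,(\rho\, r_t - V_t(s)).$$

There is no separate inverse temperature: $\rho$ absorbs the value scale.
Members of the family differ in which of the 12 candidate parameters they
free: the learning rate can be shared, split by prediction-error sign
($\varepsilon_P, \varepsilon_N$), or split by valence and sign
($\varepsilon_{WP}, \varepsilon_{WN}, \varepsilon_{AP}, \varepsilon_{AN}$);
the outcome impact can be shared or split by valence
($\rho_W, \rho_A$); $b$ and $\pi$ are optional. `enumerate_models()` returns
the default 14-member registry, from the 2-parameter base model
($\varepsilon, \rho$) to the full 8-parameter model. The membership is a
convention covering the expansions the stepwise search can visit; it is a
plain list and can be replaced.

Three conventions the equations leave open:

* **Zero prediction error.** The sign split defines rates for
  $\delta > 0$ and $\delta < 0$; at $\delta = 0$ the update is a no-op, and
  we file it under the positive-sign rate (this only matters for the
  bookkeeping of which rate was "used").
* **Stimulus-value updates** use the same parameters as the action values,
  with the learning rate selected by the sign of the stimulus value's own
  prediction error $\rho r - V$, not the action value's.
* **Scales.** $\varepsilon$-parameters live in $(0,1)$ via the logistic,
  $\rho$-parameters in $(0,\infty)$ via the exponential, and $b$, $\pi$ are
  unbounded — a negative Pavlovian coupling is expressible. Constraining
  $\rho$ positive treats it as a reinforcement magnitude.

`sequence_loglik()` evaluates the whole recursion in compiled code (with an
analytic gradient kernel for fitting); `action_weights()` and
`apply_update()` expose the same recursion one trial at a time, and the test
suite uses a replay through those single-step operations as an independent
oracle for the compiled path.

## Hierarchical estimation

Subject parameters are random effects: each free parameter has a normal
population distribution on the unconstrained scale. `em_fit()` maximizes the
group marginal likelihood by expectation-maximization:

* **E-step** — `map_fit()` maximizes each subject's log posterior
  (data log-likelihood plus population log-density) by BFGS with the
  analytic gradient, from the population mean plus 4 random (prior-draw)
  restarts in the first sweep; later sweeps warm-start from the subject's
  previous mode. The curvature at the mode (central differences of the
  gradient, step `1e-3`) gives the Laplace approximation to the subject's
  evidence. The step size is chosen so that rounding error in the
  second differences stays orders of magnitude below the Laplace
  approximation error itself; on exactly quadratic log posteriors the
  evidence is accurate to better than `1e-8`.
* **M-step** — the population mean becomes the mean of the modes, and the
  variance the mean of (mode² + posterior variance) minus the squared mean,
  i.e. moment matching of the Laplace posteriors. Variances are floored at
  `1e-6`.
* **Convergence** — when the total evidence changes by less than `tol`
  (default `1e-3`) or `max_iter` sweeps elapse. The total-evidence creep of
  EM is slow in its tail; in the validation runs we cap sweeps (25–40
  depending on the cohort size) after verifying that the recovery metrics
  and population means are stable well before the cap.

Non-positive-definite curvature triggers one refit from a perturbed start
and otherwise a growing ridge (from `1e-6`) with a flag on the subject.

**Model evidence.** `ibic()` estimates each subject's marginal likelihood by
Monte Carlo: draw `n_mc = 1000` parameter vectors from the fitted population
distributions, average the data likelihood over draws (log-sum-exp), sum the
log averages over subjects, and add a complexity penalty. The penalty is
$k \log N$ with $k$ = the number of population-level parameters (a mean and
a variance per free parameter) and $N$ = the total number of choices; the
penalty convention is not uniquely determined for hierarchical models, so
this choice follows the hierarchical-RL literature and is reported alongside
the value, together with the Monte-Carlo standard error. `stepwise_select()`
runs the greedy forward search: starting from the base model, fit every
admissible single expansion (add $\pi$, add $b$, split $\varepsilon$ by sign
or by valence x sign, split $\rho$ by valence), accept the largest iBIC
decrease, stop when nothing decreases.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: 82 subjects, about 50
presentations per cue image over 4 runs, 80/20 feedback, 50% shock
delivery. The default generating prior (`default_prior()`) places
natural-space population medians at $\varepsilon \approx 0.2$,
$\rho \approx 2$, $b \approx 0.3$, $\pi \approx 0.3$ with standard deviation
0.5 on the unconstrained scale — learnable but non-degenerate behavior.
These defaults are a repository convention for simulation studies, chosen
once; they are not estimates from any real cohort. The covariate table carries sex (Bernoulli 34/82),
age (normal, 35.9 ± 11.2 years), the simulated count of delivered shocks,
and a synthetic "activation" variable
$\alpha \cdot z(\text{parameter}) + \text{noise}$ for exercising the
mediation module end to end.

What the generator does *not* emulate: response times, within-session
drift or lapses, perseveration (a known limitation of this model family),
cue-order constraints, or any fMRI-related noise. Tests passing on these
cohorts show that the estimation machinery is correct and calibrated under
the model's own assumptions; they cannot show that real subjects satisfy
those assumptions.

## Behavioral metrics

* `accuracy_by_condition()` scores a response correct when it equals the
  cue's required action — independent of the sampled outcome.
* `stay_switch_index()` is the percentage of unfavorable-feedback events
  followed by a response reversal on the next presentation of the *same cue
  image* (default). Because responses are cue-conditional, the literal next
  trial almost always shows a different cue, for which "switching" is
  undefined; a same-category variant (`match = "category"`) is provided;
  neither convention is canonical.
* `value_difference_trajectory()` replays a sequence under given parameters
  and records the required-minus-alternative action-value difference before
  each choice, so learning is positive-going for all four cue types.

## Mediation

`fit_paths()` fits the three single-mediator regressions by least squares,
with adjustment covariates included as regressors in all three equations
(numerically identical to residualizing first, which the tests verify).
Variables are z-scored by default; raw-scale paths are returned alongside.
The identity $c - c' = ab$ holds algebraically for least-squares fits and is
asserted to `1e-10`. `bootstrap_indirect()` case-resamples subjects
(default `n_boot = 5000`; percentile 95% interval; two-sided
$p = 2\min(\Pr(ab^* \le 0), \Pr(ab^* \ge 0))$). Percentile intervals are the
simplest form of the cited bootstrap approach; the replicate count and CI
type are conventions, as the source does not state them. Calibration is
checked under the null in which the mediator is unrelated to the predictor
but still drives the outcome ($a = 0$, $b \ne 0$), where the indirect
estimate is asymptotically normal and the interval attains close to nominal
coverage. Under the double null ($a = b = 0$) the product statistic is
spiked at zero and the percentile interval is markedly conservative
(coverage near 100%) — a well-known property of the product test, not a
defect of the implementation.

## Validation scale and known limitations

The validation suite runs entirely on simulated cohorts: recovery uses 60
subjects x 400 trials from the full model under the default prior;
selection-consistency uses 10 replicate cohorts of 30 subjects x 200 trials
per scenario; bootstrap calibration uses 1,000 null datasets of n = 82.

Two limitations are worth stating plainly:

* **Four-way learning-rate splits are weakly identified at ~400 trials.**
  Each $\varepsilon_{\cdot\cdot}$ is informed only by the subset of trials
  with the matching valence and prediction-error sign, and it trades off
  against the corresponding $\rho$. In our recovery simulations the
  $\rho$, $b$ and $\pi$ parameters recover with subject-level correlations
  around 0.85–0.96, while the four learning rates sit near 0.4–0.5, with
  population-mean biases of a few population standard errors that shrink
  as trials per subject grow. Consistency checks at 1,600 trials per
  subject confirm the estimator converges toward the truth; the shortfall
  at the task's usual scale is an information limit of the design, and
  subject-level learning-rate estimates from cohorts of this size should be
  interpreted accordingly.
* **Greedy selection is a heuristic.** The stepwise path evaluates at most
  the 14-member family and can stop at a local optimum of the expansion
  lattice; iBIC values carry Monte-Carlo error (reported as a standard
  error), so differences within a few standard errors should not be read as
  decisions.

## A small worked run

```{r, eval = FALSE}
spec <- model_spec("single", "single", bias = TRUE, pavlovian = TRUE)
cohort <- simulate_cohort(default_prior(spec), spec,
                          n_subjects = 12, n_per_cue = 25, n_runs = 2,
                          seed = 42)
fit <- em_fit(cohort$trials, spec, seed = 1)
ibic(fit, cohort$trials, n_mc = 1000, seed = 2)
behavior_summary(cohort$trials)$accuracy |> head()
```
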