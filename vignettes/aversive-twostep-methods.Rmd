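---
title: "Modeling model-free and model-based aversive learning for self and other"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling model-free and model-based aversive learning for self and other}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aversivetwostep)
```

## The task and the scientific question

`aversivetwostep` implements a simulation and analysis pipeline for a
two-stage ("two-step") decision task in which choices lead, through a fixed
probabilistic transition structure, to outcomes that are painful electric
shocks — delivered either to the decision maker ("self" blocks) or to
another person ("other" blocks). The question the pipeline addresses is
whether harm-avoidance learning relies more on *model-free* control
(caching action values from experienced outcomes) or *model-based* control
(planning through a known transition model), and whether that balance
shifts when the person at risk is someone else.

The task structure is the standard two-step design: two first-stage
stimuli (`A`, `B`) lead to one of two second-stage states (`S2`, `S3`);
`A` commonly (70%) leads to `S2` and `B` to `S3`, with the mapping
inverted on rare (30%) transitions. Each second-stage state offers two
actions whose shock probabilities drift across trials, so participants
must keep learning. The default experiment is four blocks of 68 trials,
alternating recipient, 136 trials each for self and other (272 in total;
a 36-subject cohort makes 9,792 choices). Outcomes are coded 1 = no pain,
0 = pain, so "reward" semantics coincide with harm avoidance and a
positive prediction error is unexpected pain relief.

The two systems leave distinct fingerprints on first-stage choice
repetition ("stay") behavior. A model-free learner repeats choices that
ended without pain and abandons choices that ended in pain, regardless of
the transition: a main effect of previous outcome. A model-based learner
evaluates first-stage options through the transition model, so after a
*rare* transition the credit goes to the *other* first-stage option: an
outcome × transition interaction. Both signatures are measured by the
stay/switch logistic regression in this package, and both are generated
by the agent family.

## The hybrid learner

The agent family (`model_registry()`) is a hybrid of a SARSA-style
model-free learner and a prospective model-based planner.

Second-stage values are learned by a delta rule with valence-dependent
learning rates,

$$Q_2(s, c) \leftarrow Q_2(s, c) + \alpha^{*} \,\big(r - Q_2(s, c)\big),
\qquad
\alpha^{*} = \begin{cases}
\alpha_{\text{NoPain}} & r = 1\\
\alpha_{\text{Pain}} & r = 0,
\end{cases}$$

and first-stage model-free values are updated from the visited
second-stage value plus an eligibility-weighted share of the outcome
prediction error,

$$Q_{MF}(c_1) \leftarrow Q_{MF}(c_1)
 + \alpha^{*}\big(Q_2^{old}(s_2, c_2) - Q_{MF}(c_1)\big)
 + \alpha^{*}\lambda\big(r - Q_2^{old}(s_2, c_2)\big).$$

With $\lambda = 1$ (fixed in the reduced models) this collapses to a
direct outcome update. The model-based values are computed prospectively
from the true transition matrix,
$Q_{MB}(a) = \sum_s P(s \mid a)\, \max_{c} Q_2(s, c)$ — agents are
pre-trained on the transition structure, so transitions are not learned.

First-stage choice follows a softmax over the ω-weighted mixture with a
perseverance bonus for repeating the previous first-stage choice:

$$P(a) \propto \exp\!\big(\beta\,[\,\omega_r Q_{MB}(a) + (1-\omega_r) Q_{MF}(a)\,]
 + \rho_r\,\mathbb{1}[a = a_{prev}]\big),$$

where $\omega_r \in (0,1)$ is the model-based weight and both $\omega$
and $\rho$ may be split by recipient $r$. Second-stage choice is a
softmax over $Q_2(s_2, \cdot)$ with no perseverance term. The registry
holds the full seven-parameter model (`daw7`: valence-split α,
stage-split β, free λ, shared ρ and ω), the five-parameter reduction
(`win5`), the recipient-split-ω six-parameter model
(`win6_omega_split`), and the variant splitting both ρ and ω
(`split7_rho_omega`).

Design choices worth stating explicitly:

* Q-values initialize at 0.5, the midpoint of the outcome scale, so pain
  and no-pain are symmetric surprises on early trials.
* The same valence-dependent $\alpha^{*}$ drives both stage updates; which
  learning rate governs the stage-1 bootstrap in valence-split models is
  genuinely underdetermined, and the choice is isolated in one update
  function.
* Perseverance applies at stage 1 only and references the previous
  trial's first-stage choice; it resets at block boundaries because
  blocks change recipient and stimuli. Values persist across blocks by
  default (`reset_values = FALSE`), since the outcome probabilities drift
  continuously across the session.
* Stimulus identity, not screen position, defines a choice; "stay" means
  repeating the same stimulus.

The likelihood of observed choices is the sum of log choice
probabilities of both stages, computed by exactly the probability and
update rules the simulator uses. A compiled (Rcpp) mirror of the R
reference path is the default engine for fitting; the test suite asserts
the two agree to better than 1e-12 on full-length sessions.

## The task environment

Shock probabilities for the four second-stage options drift as
independent Gaussian random walks with per-trial step s.d. 0.2
(`drift_scale`), reflected at the bounds [0, 1]. The noise law is a
modeling choice — the drift is described only by its rate and bounds —
and reflection (rather than truncation) is used because it preserves
the marginal spread near the bounds. Initial probabilities are drawn
uniformly from [0.25, 0.75] so that early trials are informative; the
walk's law and independence across options are configurable. The
"10% of accumulated shocks delivered afterwards" incentive rule is
metadata: shock totals are computed, delivery is not simulated.

## Hierarchical MAP fitting

Parameters are fitted per subject by maximum a posteriori estimation
under a Gaussian group prior in a transformed space chosen so the prior
is sensible: logit for unit-interval parameters (α, ω), log for positive
ones (β, λ), identity for ρ. The group prior starts weakly informative
(mean 0, variance 6.25 in transformed space) and is re-estimated by
expectation–maximization: the E-step computes each subject's MAP (BFGS,
jittered restarts, warm-started from the previous iteration's optimum
after the first pass) together with a Laplace approximation of the
posterior variance from the finite-difference Hessian (projected to the
nearest positive-definite matrix when needed); the M-step sets
$\mu = \overline{\theta}$ and
$\sigma^2 = \overline{\theta^2 + v} - \mu^2$ (floored at $10^{-6}$),
where $v$ is the Laplace variance. The variance inflation by $v$ keeps
the prior honest about per-subject uncertainty; one consequence is that
for a cohort of identical subjects the group variance collapses toward
the floor only geometrically across iterations rather than in one step.

Model evidence per subject is computed by Monte-Carlo integration of the
likelihood over the fitted group prior, and the group score is the
integrated BIC,
$$\mathrm{BIC}_{int} = -2 \sum_s \log \hat p(y_s) + 2k \log N_{choices},$$
with a penalty counting the two group-level quantities (mean, variance)
estimated per free parameter, and $N_{choices}$ counting both choices of
every trial. The penalty convention is configurable in principle (it is
one line) because the original convention is not fully specified by its
sources.

Exceedance probabilities — the posterior probability that a model is the
most frequent in the population under a Dirichlet random-effects model —
are computed by the standard variational scheme (the spm_BMS algorithm)
from the per-subject log evidences. A caution documented by this
package's own validation: the variational Dirichlet posterior is
systematically *sharper* than the exact posterior when the evidences
separate models clearly (differences up to ~0.2 in exceedance on
informative problems, verified against deterministic simplex
quadrature); it is exact in the symmetric and dominance limits and
preserves the ranking. `exceedance_probabilities(..., method =
"sampling")` provides an unbiased importance-sampling estimate of the
exact posterior for when calibrated probabilities matter.

Fitting never allows negative β by default; a diagnostic flag
(`allow_negative_beta`) refits with β on the identity scale, mirroring
the published check that no participant earned a negative weight (which
would indicate harm-seeking or a broken fit).

## Behavioral statistics

The model-agnostic path mirrors the study's primary analysis: per-subject
logistic regression of stay (1) vs switch (0) on effect-coded previous
outcome (+1 no pain / −1 pain), previous transition (+1 common / −1
rare), recipient (+1 self / −1 other) and their interactions, the first
trial of each block excluded. Effect coding is chosen so that the
model-free signature (staying after no pain) is a positive outcome
coefficient and "more model-free for other" is a negative outcome ×
recipient interaction. With the task's 70/30 transition frequencies the
outcome and outcome × transition regressors are correlated by design
(~0.4); on a fully balanced design the columns are orthogonal, which is
what the QC correlation check exploits. The optional trial-number
interactions use the z-scored within-experiment trial index.

Subjects are excluded when they switch on fewer than 5% of analyzable
trials or when the outcome and transition regressors correlate above 0.8
in absolute value on switch trials — both conditions make the regression
unidentifiable. Group inference uses per-subject coefficients with
two-tailed one-sample (or paired) t-tests, Cohen's d (= t/√n for the
one-sample case), 95% confidence intervals, and a default-prior
Jeffreys–Zellner–Siow Bayes factor for nonsignificant results, computed
by numerical integration with Cauchy scale 0.707 (the JASP default,
exposed as an argument). BF01 > 3 is read as substantial evidence for
the null.

## The synthetic cohort generator

`cohort_spec()` defines the generative study conditions: 36 subjects,
four blocks of 68 trials, counterbalanced block order (odd-numbered
subjects start with self), and subject parameters drawn from truncated
normals around group means. The recipient-split model-based weights
default to ω_self = 0.55 and ω_other = 0.45 — the reported group
estimates — while the remaining means (α = 0.35, β = 4, ρ = 0.2) and all
spreads (0.15 on the ω scale, 0.1 on α, 1 on β, 0.2 on ρ) are *assumed*
values chosen to produce realistic choice stochasticity and individual
variation; the subject-level fitted values they would correspond to are
not available. Every analysis that depends on the assumed values tests a
direction or threshold, never an equality. Subject-level ω_self and
ω_other are drawn independently; the generator does not impose the
positive within-subject correlation real data would likely show, which
makes recipient contrasts on synthetic cohorts noisier than the
within-subject design could be in reality.

What passing the synthetic-cohort suites shows — and what it does not:
the pipeline detects model-free and model-based signatures with high
power at study scale, recovers the direction of a generated ω split, and
neither pure strategy is better at avoiding shocks (the incentive
equivalence that makes the self/other comparison interpretable). It does
not certify the specific fitted values of the real dataset, which
require the deposited data; `load_trials(..., dialect = "osf")` maps a
deposited table onto the native schema through a declared, editable
column map.

## Numerical choices and problem sizes

* MAP optimization: BFGS with numerical gradients on the compiled
  likelihood, 5 jittered restarts by default (2 inside EM), ties within
  1e-6 broken by lower NLL then smaller parameter norm.
* EM: default tolerance 1e-3 on the maximum change in prior mean and
  variance; the summed penalized log posterior is tracked and is
  non-decreasing across iterations up to optimizer tolerance.
* BICint: at least 100 Monte-Carlo prior draws (default 1000–2000);
  doubling the draws moves BICint by under 2 units at the problem sizes
  used here.
* Exceedance: variational iterations to 1e-8; Monte-Carlo exceedance
  from 1e5 Dirichlet draws (4e4 importance samples for the exact
  method).
* Validation suites run 20-replicate batteries at the study's 36 × 272
  scale with reduced optimizer settings (EM capped at 6 iterations, 2
  restarts), and smaller cohorts for purely module-level properties;
  these sizes are the package's chosen compromise between Monte-Carlo
  resolution and a test suite that completes in minutes.
* All degenerate inputs fail loudly (empty trial tables, boundary
  parameter values, non-stochastic transition rows, undefined stay-table
  cells are flagged rather than imputed); the one deliberate absorption
  is `posthoc_switch_proportions()`, which returns a flat null
  comparison (t = 0, maximal BF01) when both recipients show identical
  behavior, because that is the meaningful answer there.

## Known limitations

* Reaction times are carried through the schema (`rt1`) but never
  modeled or generated.
* The transition model is known, not learned; there is no devaluation or
  replanning probe.
* Exceedance probabilities from the default variational method are
  overconfident away from the symmetric/dominant regimes (see above).
* The mixed-effects (random-slope) robustness path and any fMRI-side
  analyses are out of scope; group inference is per-subject fits plus
  t-tests.
* The OSF column map ships as a best-guess placeholder and should be
  aligned once against the actual deposit before loading real data.
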