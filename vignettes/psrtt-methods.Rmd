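---
title: "Models and methods for probabilistic serial reaction time tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for probabilistic serial reaction time tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrtt)
```

## The task and its generative structure

The package models a probabilistic serial reaction time task in which a
subject responds to a stream of four stimuli.  Sequences are organised in
two hierarchical levels.  At the lower level, each 50-trial block draws
its stimuli from one 4×4 transition matrix $T_{ij} = p(s^t = j \mid
s^{t-1} = i)$.  At the upper level, eight matrices — four 0th-order
(identical rows: the next stimulus is independent of the previous one),
two 1st-order (predominant successors trace a 4-cycle over all stimuli)
and two alternating (predominant successors pair the stimuli into two
2-cycles) — are each scheduled three times in pseudo-random order with no
matrix immediately repeating.  Every row of every matrix puts probability
`p_high` (default 0.7) on one predominant successor and spreads the rest
uniformly.

The published figure showing the matrices is not machine-readable beyond
the 0.7 predominant probability, so `default_matrices()` parameterises
the battery by `p_high` with the remaining mass uniform.  The two
4-cycles (1→2→3→4→1 and 1→3→2→4→1) and the two pairings ({1↔2, 3↔4} and
{1↔4, 2↔3}) are this package's defaults, chosen so that 1st-order
predominant runs visit all four stimuli and alternating dynamics have
period 2; both layouts are constructor arguments and can be overridden.

Two further conventions matter downstream.  The stimulus chain is
continuous across block boundaries — the last stimulus of a block
conditions the first draw of the next — because subjects receive no
boundary signal; and the very first stimulus of a session is drawn
uniformly.  Stimulus timing (200 ms display, 1200 ms interstimulus
interval) is recorded as design metadata only; it plays no computational
role.

## The forgetful observer model

The perceptual component tracks a 4×4 array $U$ of effective transition
counts, the parameters of four per-predecessor Dirichlet distributions.
After observing the transition $(s^{t-1}, s^t)$ every cell decays towards
an asymptotic prior $\gamma$ at forgetting rate $\lambda$ while the
observed cell gains one count:

$$U_{ij}^{t+1} = (1-\lambda)(U_{ij}^t - \gamma) + \gamma +
  \delta\big((s^{t-1}, s^t), (i,j)\big), \qquad U_{ij}(0) = \gamma .$$

$\lambda \in [0,1]$ is dimensionless per-trial decay: $\lambda = 0$ is
perfect counting, $\lambda = 1$ a complete reset each trial.  With
$\gamma > 0$ beliefs converge to uniform absent evidence, so transition
probabilities are re-learnt continually — the behavioural signature this
model exists to capture.  With $\gamma = 0$ the counts shrink but their
within-row ratios are preserved: uncertainty grows while relative beliefs
stay stable.  $\gamma$ is fixed at 1 by default (an extra free parameter
per subject is not warranted by BIC, while the comparison of the
$\gamma = 0$ and $\gamma = 1$ variants is itself informative).

The response component is linear in the model's belief about the realised
transition and in a post-error indicator:

$$\log \mathrm{RT}^t = \beta_0 + \beta_1 \bar U^t_{s^{t-1}s^t}
  + \beta_2\, \chi(e^{t-1}) + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2),$$

with RT in milliseconds (so $\beta_0 \approx 6.7$ corresponds to a
~800 ms baseline), $\beta_1$ in log-RT units per unit belief (negative:
expected transitions are answered faster) and $\beta_2$ the post-error
slowing in log-RT units.  $\bar U$ is the posterior-mean, i.e.
row-normalised, belief; the `count` variant uses the raw unnormalised
count instead, removing the built-in competition between successors, and
exists to quantify how much that competition matters.

Degenerate-input conventions: an all-zero count row (reachable only with
$\gamma = 0$ before the first observation from that predecessor) yields
the uniform predictive 0.25, the symmetric limit of the Dirichlet mean.
The session's first trial has no predecessor: it is excluded from every
likelihood, and in simulation its log RT is drawn at the uniform belief
0.25, a choice that affects no fit.  Invalid trials (misses and
anticipations, both recorded as incorrect) update beliefs — the stimulus
is observed regardless of the response — but contribute no likelihood
term; the post-error regressor uses the recorded correctness of the
preceding trial whatever its validity.

## Fitting

`fit_fom()` uses nested profile likelihood.  For fixed $\lambda$ the
filter is deterministic, so $\beta_0$–$\beta_2$ solve by ordinary least
squares of observed log RT on (1, belief, post-error), and $\sigma$
profiles out at its maximum-likelihood value $\sqrt{\mathrm{RSS}/n}$,
making the profile exact.  The outer search evaluates $\lambda$ on a
21-point grid plus restart points {0.05, 0.25, 0.45, 0.65, 0.85} and
refines the best bracket with `stats::optimize` (golden
section/parabolic, tolerance 1e-7).  The profile can in principle be
multimodal, hence the grid.  $\sigma$ is a profiled nuisance: the
declared free-parameter count is 4 ($\lambda$, $\beta_0$–$\beta_2$).
BIC uses $n$ = the number of likelihood trials (valid RT and a
predecessor) per subject; cohort BIC values are sums over subjects.
Fits require at least 10 likelihood trials and error out on constant
RTs (degenerate variance).

## The hierarchical Gaussian filter comparator

The comparator is a structurally faithful three-level hierarchical
Gaussian filter: 16 independent binary random-walk nodes, one per
transition cell, whose propensity is the logistic transform of a level-2
state, all coupled to one shared level-3 volatility node.  On each trial
the four cells whose source matches the previous stimulus receive a
binary observation (1 for the realised successor) and update by the
standard variational precision-weighted scheme; all cells propagate
predictive variance through the shared volatility, which is itself
updated from the informed cells' volatility prediction errors.  Because
the walks are not normalised by row, the four propensities of a row need
not sum to 1 — there is no built-in competition between successors,
which is precisely the structural contrast with the forgetful observer.
The level-2/3 coupling constant is fixed at 1; a non-positive level-3
precision or variance raises a filter-instability error naming the
trial.

Its response model is linear in a post-error indicator, the level-1 and
level-2 precision-weighted prediction errors of the realised transition,
and the current volatility estimate, with response variance
$e^{\zeta}$.  The 10 subject-specific parameters are $\mu_3(0)$,
$\sigma_3(0)$, the bounded metavolatility $\vartheta \in (0,
\vartheta_{\max}]$ ($\vartheta_{\max}$ defaults to 0.5 and is exposed in
the constructor, since only the existence of the bound, not its value,
is prescribed), the tonic step $\omega$, five response coefficients and
$\zeta$.  The relaxed $\zeta$ prior $N(-3, 100)$ is the default used in
model comparison; the restrictive mode ($N(-3, 0.01)$) is retained
behind a flag purely to demonstrate how strongly a response-variance
prior can distort likelihood-based comparison.

Fitting is stepwise: `optimal_perceptual_priors()` first fits the
perceptual component to the stimulus sequence alone (scoring the
normalised one-step prediction of each realised transition — the
normalisation is for scoring only) and returns the optimum as prior
means; then the joint fit maximises the penalised likelihood over the
four perceptual parameters by Nelder-Mead (restarted from the prior
means, up to 400 iterations) with the response coefficients profiled by
least squares under their flat priors and $\zeta$ by a 1-D bounded
search under its prior.  The reported log likelihood is unpenalised.

One empirical caveat, documented because it shapes a test: the sequence
score is nearly flat in $\vartheta$ — the metavolatility is weakly
identified from stimuli alone, consistent with the poor metavolatility
recovery this class of model is known for — and the tonic step $\omega$
absorbs the volatility of the stream instead (switching streams yield
larger $\omega$ priors than static ones).  The sequence fit therefore
carries weak hand-specified regularisers to keep the simplex off the
resulting plateaus, and the package's property test asserts the
volatility contrast on $\omega$, where it is identified.

## Speeding curves and permutation tests

A *run* is a maximal streak of consecutive within-block trials whose
realised transition is the active matrix's predominant one; the entering
transition from a rare stimulus counts as position 1 (a convention
exposed in the run table, since the original counting is not
prescribed).  Runs are labelled by the block half containing their start;
"half" splits the 50-trial block symmetrically at trial 25.  Log RTs are
z-scored per subject with mean and SD computed only on run trials inside
0th-order blocks that carry an observed RT, then applied to the whole
session.  Model predictions are standardised with the *data's* basis
mean and SD rather than their own: predictions are conditional means
without residual noise, so self-standardisation would inflate their
curves by the noise share of the data SD and distort the model-data
comparison the curves exist for.

`halves_permutation_test()` compares the mean one-step speeding
$z^{t+1}-z^t$ at a given run position between halves, building the null
by shuffling half labels among each subject's runs (10,000 iterations by
default) and using the add-one two-sided estimator $p = (\#\{|{\rm
null}| \ge |{\rm obs}|\} + 1)/(n_{\rm iter} + 1)$ — conservative but
never exactly zero.  `mismatch_magnitude_test()` compares two models'
deviations from the data: per subject (and half) it computes each
source's mean speeding difference, takes $|A - \mathrm{data}| - |B -
\mathrm{data}|$, and permutes the model labels within subjects (a sign
flip per subject).  Runs shorter than the tested position simply do not
contribute to it; a half with no contributing runs flags the position as
not testable rather than erroring.

## The synthetic-data generator

`simulate_subject()` runs the forgetful observer filter over a generated
stimulus stream and draws each trial's log RT from the response model
plus Gaussian noise of SD `sigma` (default 0.2 — roughly a 20% RT
coefficient of variation, typical for speeded key presses).  Response
errors are injected i.i.d. at `p_error` (default 0.05) and feed the
post-error regressor of the next trial; invalid trials (misses or
anticipations) occur i.i.d. at `p_invalid` (default 0.02), are recorded
as incorrect and carry no RT.  These defaults are the package's study
conditions and are arguments, not constants.

What the generator deliberately does not emulate: errors arise from a
coin flip, not from the subject's own uncertainty, so error-belief
correlations in real data are absent; RT noise is homoscedastic
Gaussian on the log scale with no autocorrelation, lapses or fatigue
drifts; there is no learning of the error process itself, no chunking of
stimulus n-grams, and no multiple forgetting timescales.  Passing tests
therefore certify the estimation and analysis machinery under the
model's own assumptions — they do not certify that real behaviour
satisfies those assumptions.

## Group contrasts

`compare_groups()` implements two-stage summary statistics: each
subject's point estimate of a parameter is the response in a linear
model on group indicators plus z-scored covariates (body weight,
alertness); each drug group is contrasted against placebo and p-values
are Bonferroni-multiplied by the number of drug contrasts (3 in the
standard design).  Covariates are z-scored because their raw scales are
arbitrary here and standardisation improves conditioning; rank-deficient
designs error out naming the collinear columns rather than silently
dropping terms.

## Problem sizes and numerical choices

The test suite exercises the analyses at the scales they are designed
for: parameter recovery over 30 synthetic subjects of 1200 trials with
$\lambda \sim U(0.05, 0.6)$ (correlation ≥ 0.9, MAE ≤ 0.05 required);
cohort-level recovery of the placebo point estimates over 20 subjects
(each mean within 2 Monte-Carlo standard errors of its generative
value); confusion analysis with 10 datasets of 600 trials per generating
model (zero misclassifications expected, matching sub-1% confusion at
full scale); permutation-test null calibration over 500 replicates
(rejection rate in [0.03, 0.07] at $\alpha = 0.05$); and 10,000-trial
sequences for transition-frequency checks (±3 binomial SEs).  Tolerances
follow the quantity: exact algebraic identities at 1e-12, likelihood
oracles at 1e-9, optimiser dominance at 1e-6.

## Limitations

The hierarchical Gaussian filter here is a structurally faithful
comparator, not a re-implementation of any released toolbox: the update
equations are the standard binary-outcome variational scheme applied per
transition cell with a shared volatility node, and the exact regressor
set of the original response model is not reproduced.  Conclusions that
depend on bit-exact HGF behaviour are out of scope; the package's claims
about the comparator are structural (propensities in (0,1), unnormalised
rows, volatility freeze limit, confusion separability).  Likewise the
per-matrix-type fits reset beliefs at block starts by construction, so
they are not comparable likelihood-wise to continuous-session fits
except through the nesting check the tests perform.
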