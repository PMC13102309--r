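---
title: "Measuring metacognitive efficiency in reversal learning with metarl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metacognitive efficiency in reversal learning with metarl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarl)
```

## The problem

Metacognitive *sensitivity* asks how well confidence reports discriminate
correct from incorrect decisions; metacognitive *efficiency* normalizes that
sensitivity by first-order task performance, since a high performer can look
"sensitive" simply by always reporting high confidence. Classical efficiency
measures for perceptual decisions (meta-d′ and the M-ratio) assume static
task difficulty. In reinforcement-learning tasks difficulty is intrinsically
dynamic — the agent is ignorant at the start of every unsignalled reversal —
so those measures do not transfer.

`metarl` implements a model-based alternative. Two copies of the same
reinforcement-learning model are fitted to one subject-condition:

* the **Forward model**, fitted to the subject's *choices* by maximum
  likelihood; and
* the **Backward model**, fitted to the subject's *confidence ratings* by
  least squares, treating the ratings as affinely rescaled choice
  probabilities of a notional decision-maker.

Both fitted models are then run autonomously on fresh realizations of the
task, and their mean fraction of better-option choices (`model_performance()`)
gives the Forward and Backward performances. Their quotient,

$$\mathrm{MetaRL.Ratio} = \overline{\mathrm{Perf}}^{B} /
  \overline{\mathrm{Perf}}^{F},$$

is the efficiency measure: Backward performance captures how much
choice-relevant information the confidence reports carry (sensitivity), and
dividing by Forward performance removes the first-order component. For a
*first-order* agent — one whose confidence is a deterministic function of the
same quantities that drive its choices — the ratio is 1 by construction;
values below 1 indicate confidence carrying less information than the
choices, values above 1 are possible when confidence carries extra
information (an error-monitoring analogue).

## The task

The environment is a two-armed bandit with unsignalled reversals
(`task_config()`, `run_episode()`): rewards are Gaussian with means 40
(worse option) and 60 (better option); the identity of the better option
flips every 18–22 trials (block lengths uniform, the final block truncated so
a session is exactly 400 trials); the reward scale is 8 in the low-variance
condition and 16 in the high-variance condition. The condition value is used
as the Gaussian *standard deviation* throughout — descriptions of such
designs sometimes label 8/16 "variances", but a single consistent reading is
required and the scale reading keeps the two conditions' discriminability
(d′ of 2.5 vs 1.25 per trial) in a psychologically sensible range. The first
block's better option is assigned uniformly at random; trials are 1-based.

## Choice models

The core learner is two-parameter Q-learning: after choosing option $a_t$
and receiving reward $r_t$,

$$Q_t(a_t) = Q_{t-1}(a_t) + \alpha\,(r_t - Q_{t-1}(a_t)),$$

with softmax choice
$P_t(a)\propto \exp(\beta\, Q_{t-1}(a)/100)$. Two conventions deserve
comment:

* **Predictive timing.** The probability of the choice at trial $t$ uses the
  values updated through trial $t-1$; the trial's own reward only enters
  afterwards. This is the standard causal convention for likelihood
  evaluation.
* **Inverse-temperature units.** $\beta$ is expressed per 100 reward units
  (equivalently, the learner's decision values live on a reward scale
  normalized by the task's nominal range). With raw 40–60 rewards any
  $\beta \gtrsim 2$ would be indistinguishable from deterministic choice,
  making the conventional $\beta \in [0, 100]$ fitting range, fitted values
  in the tens, and per-session likelihoods of order 100 nats mutually
  inconsistent. With the per-100 convention all three cohere, and the
  documented $[0,100]$ range spans fully stochastic to near-deterministic
  behaviour.
* **Initial values.** $Q_0 = 50$ for both options, the midpoint of the two
  reward means (configurable via `fit_settings(q0 = )`); the neutral start
  means the first trial is always a coin flip.

The refined four-parameter variant (`model = "mf4"`) splits the learning
rate by the sign of the prediction error ($\alpha^+$ for $\delta \ge 0$,
$\alpha^-$ for $\delta < 0$; the measure-zero tie is assigned to $\alpha^+$
so replays are reproducible) and updates the *unchosen* option with the same
prediction error scaled by a counterfactual rate $\alpha^u \in [-1, 1]$,
typically negative because the options are anticorrelated. With
$\alpha^+ = \alpha^- = \alpha$ and $\alpha^u = 0$ it reproduces the simple
model exactly (this nesting is tested bit-for-bit).

### The model-based (HSMM) learner

Because subjects are told reversals happen every 18–22 trials, a learner can
instead infer the latent state ("which option is better now") with a hidden
semi-Markov model (`hsmm_filter()`): two latent states that alternate
strictly, an explicit duration distribution — a negative binomial $NB(n, p)$
truncated to $1..D$ with $D = 70$ by default — and Gaussian emissions with
mean 60 when the chosen action matches the state and 40 otherwise, scale
equal to the condition's reward scale. The forward recursion marginalizes
the elapsed time $h$ of the ongoing segment under a uniform prior
$P(h\,|\,d) = 1/d$, and the policy chooses option $i$ with the *predictive*
posterior probability that state $i$ is active given history through
$t - 1$ (the trial's own reward never informs its own choice). Numerical
choices: all forward quantities are kept in the log domain with
log-sum-exp, the recursion is seeded with a virtual segment boundary at
$t = 0$ and a uniform prior over the first state (so the posterior at
$t = 1$ is exactly (0.5, 0.5)), and the recursion is validated against
exhaustive enumeration over duration-segmented state sequences on small
instances (relative error < 1e-8).

Duration parameters are fitted by grid search — $p$ over 17 equal steps on
$[0.01, 0.99]$ and $n \in \{1, 7, \ldots, 97\}$ by default
(`hsmm_default_grid()`, configurable) — with any continuous parameters
optimized at each grid point. The truncated distribution's mean,
`t_bar_rev`, is reported as the model's expected reversal time. The mixture
model (`model = "mixture"`) combines model-free and model-based
probabilities, $P = \gamma P_{MF} + (1-\gamma) P_{MB}$, with weight
$\gamma \in [0, 1]$.

## Confidence models and fitting

Model confidence is the probability assigned to the *chosen* option mapped
onto the rating scale with fitted reporting bounds,
$\mathrm{Conf}_t = (H - L)\,P_t(a_t) + L$ with
$1 \le L < H \le 5$. The bounds absorb individual differences in scale use
(confidence bias). $L < H$ is enforced by reparameterization — $L$ is fitted
directly and $H = L + (5 - L)\,\sigma(v)$ with a logit-scaled gap fraction —
rather than by rejection, which avoids boundary pathologies in the bounded
optimizer.

* `fit_forward()` is two-stage, mirroring the two separate estimation
  problems: choice parameters by maximum likelihood of the actions, then
  $(L, H)$ by least squares against the ratings with the choice parameters
  held fixed.
* `fit_backward()` is joint: choice parameters *and* $(L, H)$ (plus the leak
  weight $\lambda$ when `leaky = TRUE`) minimize the summed squared distance
  between model confidence and the empirical ratings. The model is always
  replayed on the subject's observed actions and rewards.

The leaky confidence variant predicts
$\lambda\,\mathrm{Conf}_t + (1-\lambda)\,\mathrm{Conf}_{t-1}$; when fitting,
$\mathrm{Conf}_{t-1}$ is the *reported* confidence on the previous trial
(the autocorrelation mechanism being modeled), while autonomous simulation
chains on the model's own previous output. The first trial, which has no
predecessor, uses the current confidence unmixed.

Every optimization uses multi-restart bounded local search (L-BFGS-B, with a
Nelder–Mead fallback per restart): initializations are drawn uniformly
within the parameter bounds from per-restart child seeds, so results are
reproducible and the best objective is non-increasing as restarts are added.
The default is 120 restarts — the count at which estimates stabilize for
this problem — with 20 used in the package's own cohort-level checks to keep
them fast; both counts are `fit_settings()` arguments. Choice probabilities
are floored at 1e-12 inside logarithms so likelihoods stay finite, and
performance estimates average 100 autonomous simulations by default to
absorb softmax stochasticity. Whether the Backward grid fit should inherit
the Forward duration parameters was genuinely open; it re-optimizes them,
since the two directions are separate estimation problems and are expected
to disagree about reversal expectations.

## Summary measures

`metacog_report()` assembles, per subject-condition: empirical performance;
Forward/Backward simulated performance and their ratio; the quadratic
scoring rule $\mathrm{QSR} = 1 - \frac1N \sum_t
\left(\frac{\mathrm{Conf}_t - 1}{4} - I_t\right)^2$ (confidence normalized
to the unit interval, scored against trial correctness $I_t$); the
scaled-QSR; confidence bias (mean rating); lag-1 confidence
autocorrelation; and the chance-level exclusion filter.

Two of these need caveats:

* **Scaled-QSR.** The scaled variant maximizes the QSR over an affine
  rescaling $(H - L)\,\mathrm{Conf} + L$ of the empirical ratings with
  $L, H \in [1, 5]$, $L < H$. Taken literally, the rescaling acts on
  ratings that already live on $[1, 5]$, so the identity transform
  ($H - L = 1$, $L = 0$) is *not* inside the feasible box; the package
  optimizes the literal objective over the stated box (the objective is a
  concave quadratic, solved with multi-start bounded optimization and
  validated against a dense grid in the tests) and therefore does not
  guarantee $\mathrm{scaledQSR} \ge \mathrm{QSR}$. Users comparing the two
  should be aware of this parameterization quirk rather than have it
  silently "fixed".
* **Exclusion.** A subject-condition is excluded when the chi-square
  goodness-of-fit of its correct/incorrect counts against 50/50 does not
  exceed 3.841 (1 df, p = .05) *or* when performance is at or below 0.5:
  the statistic is two-sided but only above-chance performers are retained.

## The synthetic cohorts: what they emulate and what they do not

The generators in this package are first-class study material, not test
fixtures: their defaults are the study conditions.

* `first_order_sweep_specs()` builds the two 30-agent populations used to
  show efficiency is independent of choice parameters: learning rates
  {.2, .5, .9} crossed with 10 equidistant inverse temperatures spanning
  [5, 90] (endpoints included, spacing 85/9), and inverse temperatures
  {5, 15, 40} crossed with 10 equidistant learning rates on [.05, 1].
  These agents report their own scaled choice probability as confidence
  (full-scale bounds 1 and 5), making them exactly first-order.
* `run_recovery()` draws agents uniformly within the fitting bounds
  ($\alpha \in [0,1]$, $\beta \in [0,100]$, bounds drawn on [1, 5] and
  ordered) and checks that Backward fits recover them.
* `hmeta_confidences()` builds perfectly sensitive agents: confidence 5 on
  correct trials and 1 on incorrect ones, corrupted by Gaussian noise of a
  chosen standard deviation, truncated to [1, 5] and quantized to a 0.01
  grid (continuous-slider granularity; both choices are configurable, as no
  finer convention is established). `run_noise_ladder()` uses choice
  parameters $\alpha \sim U(0.5, 1)$, $\beta \sim U(5, 40)$, the range
  typical of fitted human subjects in this task family.
* `run_difficulty_invariance()` runs one agent population
  ($\alpha \sim U(0.2, 1)$, $\beta \sim U(5, 40)$) at reward scales 8
  and 16.

What passing these checks shows: the estimator pipeline is internally
consistent — first-order agents score efficiency 1 regardless of their
choice parameters or of task difficulty, injected confidence noise lowers
Backward but not Forward performance, and parameters are recoverable when
the generative model is true. What it does not show: the generators produce
none of the idiosyncrasies of real raters — no autocorrelated confidence
noise beyond the leak mechanism, no lapses, no discretized or end-anchored
slider use, no session effects — so agreement on synthetic cohorts does not
by itself certify the measure on human data.

Problem sizes used by the package's own checks (chosen to keep them
routinely runnable while leaving Monte-Carlo error well below the effects
tested): 30-agent cohorts, 400-trial sessions, 20 restarts per fit, 100
simulations per performance estimate; the HSMM enumeration check runs all
instances with up to 8 trials and maximum duration 4.

## Known limitations

* Backward β is weakly identified when ratings are near-constant (degenerate
  scale use); fits return bounded values, but interpretation of individual
  parameters should be guarded in that regime.
* Forward maximum likelihood at 400 trials has a mild α–β ridge: parameter
  pairs trading learning rate against temperature fit almost equally well
  but can differ in simulated performance by a few percent, which is the
  dominant source of per-agent scatter in the efficiency ratio (cohort
  means are unaffected).
* The HSMM assumes strict state alternation and uniform elapsed-time priors;
  it is a model of *this* reversal structure, not of arbitrary
  non-stationarity.
* All fitting is per subject-condition; no hierarchical pooling is provided.
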