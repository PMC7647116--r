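---
title: "Models and methods: noisy-Newton inference for the puck-sliding task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: noisy-Newton inference for the puck-sliding task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisynewton)
```

## The task physics

A puck of mass $m$ is propelled by a button press of duration $t$ applying
a constant force $F$, so the release velocity is $v_0 = F t / m$, and then
decelerates under dry friction $\mu g$. The press-time that slides the puck
exactly $\Delta x$ metres is

$$T = \frac{m}{F}\sqrt{2 \mu g \,\Delta x},$$

linear in mass and square-root in distance. `simulate_slide()` integrates
the motion with per-frame difference equations ($v \leftarrow v - \mu g\,dt$,
then $x \leftarrow x + v\,dt$), terminating when the velocity crosses zero
with the final partial frame resolved analytically (the residual distance
$v^2 / 2\mu g$), so the displacement never overshoots and converges to
$v_0^2/2\mu g$ with error of order $dt$. Collisions are one-dimensional,
perfectly elastic and frictionless: `elastic_collision()` is the exact
closed-form solution of the two conservation equations.

The environment constants are not identifiable from behaviour — only mass
*ratios* and the square-root distance scaling are — so
`env_params()` defaults to conventional values ($\mu = 0.2$,
$g = 9.81\,\mathrm{m/s^2}$, $F = 10\,\mathrm{N}$, $dt = 1/60\,\mathrm{s}$),
all overridable. Recovered masses are therefore "effective" masses in units
fixed by these constants; the proportionality constants of the two
behavioural hypotheses are absorbed into the fitted mass (Newtonian class)
or slope (linear class). The display mapping (1080 px $\leftrightarrow$
11.5 m, i.e. $\approx 93.9$ px/m) is kept only to express simulation-space
quantities in screen pixels.

## The generative model of behaviour

On each trial a subject perceives the true distance $x$ through a
log-normal percept with constant log-scale SD $\sigma_x$
(Weber–Fechner scaling: the percept SD grows proportionally with $x$) whose
*mode* is anchored at $x$, i.e. log-location $\log x + \sigma_x^2$. The
same mode-anchoring convention is used for the velocity percepts of the
observation model; the data give no reason to anchor the distance percept
differently.

The intended press-time is $t^{int} = T(x^{per}; m_{belief})$ under the
Newtonian class or $c\,x^{per}$ under the linear heuristic. Motor output is
log-normal with log-scale SD $\sigma_t$ around a location chosen by the
subject's cost function: for a log-normal response the 0-1, absolute and
quadratic losses are minimised by its mode $e^{\mu-\sigma^2}$, median
$e^{\mu}$ and mean $e^{\mu+\sigma^2/2}$, so pinning the optimal statistic
at $t^{int}$ gives $\mu = \log t^{int} + s$ with
$s = +\sigma_t^2,\ 0,\ -\sigma_t^2/2$ respectively (`cost_shift()`).

### The synthetic cohort

`make_cohort()` emulates the study conditions: 16 subjects split evenly
between the "light-to-heavy" (1.5/2.0 kg feedback pucks, 2.5 kg unknown
puck) and "heavy-to-light" (2.0/2.5 kg, 1.5 kg) conditions; $\sigma_x =
0.05$ (log-units, numerically equal to a 5% Weber fraction); per-subject
$\sigma_t$ uniform on $[0.15, 0.33]$, the range individual press-time
variabilities span; four phases of 50 / 200 / 100 / 24+100 trials, pucks
alternating in blocks of four during feedback; distances uniform on
$[1, 5]$ m.

Values the design leaves open were chosen once, a priori:

* **Prior-phase mass belief** — drawn per subject from a gamma with mean
  2 kg, SD 0.6 kg, held constant within the phase (within-phase behaviour
  is consistent; between-subject spread is substantial).
* **Feedback-phase learning** — subjects observe the slid distance (with
  perceptual noise), invert their own model to an implied mass
  $F t / \sqrt{2\mu g\, d_{obs}}$ (or implied slope $t / d_{obs}$), and
  update a running precision-weighted log-belief
  (`running_belief_update()`, pluggable via the `learning_rule` argument).
  The initial belief carries a pseudo-count of 2 observations, so beliefs
  stabilise within a handful of trials — with two pucks, on the six-trial
  scale the learning-curve change-point analysis targets. The implied mass
  is exact up to perceptual noise because the subject's own press-time
  produced the observed slide.
* **Phase-3 belief** — the geometric mean of the two converged feedback
  beliefs (press-times without feedback mirror the combined behaviour of
  both previous pucks).
* **Phase-4 belief** — moves 70% of the way (log scale) from the phase-3
  belief towards the unknown puck's true mass: transfer from watching
  collisions is substantial but imperfect.
* **Collision movies** — the known puck slides in behind the unknown puck
  at $U(1.5, 2.5)$ m/s and catches it ($U(0.6, 1.2)$ m/s, same direction).
  These ranges guarantee all four pre/post velocities are strictly
  positive, which the log-normal velocity percepts require (a mode at a
  non-positive velocity is undefined); both ranges are configurable.

What the generator deliberately does **not** emulate: reaction times,
fatigue, memory decay between phases, trial-order effects beyond the
learning rule, and 2-D collision geometry. Passing recovery tests on this
cohort therefore shows that the inference machinery is correct and
well-calibrated *for data that follow the model*; it cannot show that
human data do.

## The interaction model

The joint density over one subject's trials is

$$p(d, l) = p(x)\,p(\sigma_x)\,p(x^{per}\mid x,\sigma_x)\,p(m)\,
p(\sigma_t)\,p(t^{pre}\mid x^{per}, m, \sigma_t, \theta),$$

with gamma priors keeping masses and variabilities positive. Defaults are
weakly informative: mass mean 2 kg, SD 2 kg; $\sigma_t$ mean 0.25, SD 0.25;
slope mean 0.5 s/m, SD 0.5. The $\sigma_x$ prior is gamma(2, 40) — mean
0.05, SD 0.035, centred on the canonical 5% Weber fraction for visual
distance — and this choice matters more than the others: in the press-time
marginal, $\sigma_x$ enters the variance only as $\sigma_x^2/4$ (Newtonian
class) against $\sigma_t^2 \approx 0.04$, so the likelihood barely
constrains it and its posterior is prior-dominated. That the fitted
perceptual variability "varies only marginally" across subjects is thus
expected behaviour, and downstream analyses pin it to a single pooled value
(`fix_nuisance()`).

### Sampling

Because the log-percept is Gaussian and enters the log press-time
linearly, two exact computations are available: the per-trial percept's
full conditional is Gaussian, and the percept-marginalised likelihood is
log-normal with inflated variance (`press_time_marginal_loglik()`).
`fit_interaction()` exploits both in a collapsed Metropolis-within-Gibbs
scheme: adaptive random-walk updates of $\log m_k$, $\log\sigma_t$,
$\log\sigma_x$ against the *marginal* posterior, followed by an exact
Gibbs redraw of all percept latents. The sampled joint distribution is
identical to the naive uncollapsed scheme, but the parameters are freed
from their coupling with 200 latents — in practice split-chain
$\widehat{R}$ drops from $\sim 3.6$ to $\sim 1.01$ at equal cost.
Convergence is flagged (not silently ignored) when $\widehat{R} > 1.01$ or
the effective sample size falls below 400 for any parameter.

**MAP extraction.** The reported MAP is the retained draw with the highest
percept-marginalised log posterior. The naive alternative — the draw with
the highest *joint* density including the latents — is degenerate here:
the joint density grows without bound as $\sigma_x \to 0$ (each percept
term concentrates), so the highest-joint draw systematically selects the
smallest $\sigma_x$ visited. The marginal is exact, bounded and
reproducible.

**Residuals.** `residual_analysis()` predicts each trial's press-time as
the cost-optimal intended press-time at the MAP parameters evaluated at
the true distance (the model's systematic "aim point") and correlates the
residuals with distance (Spearman). A matched model class leaves no
distance trend; a linear fit to square-root data produces a strong
negative trend. One structural consequence is worth knowing: on data
generated *by the model itself* under a quadratic cost, the absolute-loss
fit's residuals have median exactly zero at every distance (its fitted
location is the median of the data distribution), so its $|\rho|$ is
mechanically the smallest of the three cost fits even though its mass
estimates are biased low by $e^{-\sigma_t^2/2}$; cost functions are
reliably distinguished by the accuracy of the recovered masses, not by
residual flatness alone.

## The observation model

For each watched collision the observed data are the true pre- and
post-collision velocities and the known puck's mass; the latents are the
perceived pre-collision velocities and the two mass beliefs. Percepts are
log-normal with $\sigma_{vel} = 0.2$ and mode at the actual velocity. The
perceived post-collision velocities are anchored at the elastic-collision
prediction computed from the perceived pre-velocities and the masses; the
observed post-collision velocities enter as their measured values, which
collapses the post-collision percepts onto the observations and makes the
unknown mass identifiable (as $\sigma_{vel} \to 0$ with point priors the
posterior collapses onto the algebraic solution of the conservation
equations). Mass priors are gamma; `as_gamma_prior()` moment-matches
interaction-posterior samples so phase-2 beliefs can seed phase-4
inference per subject. Sampling is element-wise adaptive random-walk
Metropolis on the log-percepts plus random-walk updates of the log-masses.

The observation posterior is necessarily wider than the interaction
posteriors that seed it: every collision routes the mass evidence through
four uncertain velocity percepts, whereas every sliding trial constrains
the mass directly through the press-time.

## Model comparison

**Product-space Bayes factors.** A latent index selects the active model
class each iteration; conditional on the index, the active class's
parameters are updated against the percept-marginalised likelihood while
the inactive class's parameters are drawn from pseudo-priors
(log-normal moment matches of short pilot single-model runs — the standard
device for keeping the index mobile). With equal prior model
probabilities the Bayes factor equals the posterior odds of the index. The
marginalisation here is exact, not an approximation, and is what makes the
index's Gibbs step cheap; the interaction model's own fits keep the
explicit latents. When the evidence is so one-sided that the index never
switches, $K$ is reported at the $(\text{count} + 0.5)$ bound and flagged.
The conventional evidence band at $K = 3.2$ separates "worth mentioning"
from substantial support.

**Distribution checks.** `ks_two_sample()` wraps the classical two-sample
Kolmogorov–Smirnov test; `kl_press_time_divergence()` estimates
$KL(\text{observed}\,\|\,\text{predictive})$ on a shared 50-bin histogram
with add-one smoothing — a deliberately simple, always-finite estimator,
documented because no canonical choice exists.

**Change-point model.** `change_point_fit()` is a two-level Bayesian model:
error levels $\mu_1$ (trials $1..\tau$) and $\mu_2$ (after), common noise
SD, uniform prior on $\tau$, zero-centred normal priors (SD 10 m) on the
levels, half-Cauchy (scale 1 m) on the SD. Given $\tau$ and the SD the
model is conjugate, and the SD is integrated on a 60-point log grid, so
the $\tau$ posterior is exact up to quadrature and fully deterministic —
no MCMC. A near-uniform posterior (entropy above 90% of the maximum) is
flagged as diffuse, which is the expected outcome for a constant series.

## Numerical choices and degenerate inputs

* All positive parameters are sampled on the log scale with Jacobians;
  out-of-support latent values score $-\infty$ rather than raising.
* Proposal scales adapt towards 44% acceptance during warmup
  ($2/\sqrt{it}$ gain) and freeze afterwards, preserving detailed balance
  of the retained draws.
* All randomness flows from explicit integer seeds through deterministic
  substreams (`derive_seed`); refitting with the same seed reproduces
  results bit-for-bit, and RNG state is restored around every seeded call.
* Zero noise is handled exactly: `perceive_distance(x, 0)` returns `x`,
  `emit_press_time(t, 0, ...)` returns `t`.
* A perfect-prediction residual series reports $\rho = 0$ with a
  degeneracy flag; a zero-trial product-space input returns the prior
  odds.

## Problem sizes

The test suite and the acceptance script run the full study scale where it
matters — 16 subjects $\times$ 200 feedback trials for mass recovery, 24
collisions (12 per known puck) for the observation model, 10 seeded
replicates for model-selection recovery — with deliberately short chains
(2 chains, a few hundred warmup and retained draws) whose convergence
flags are expected and tolerated there; production analyses should use the
longer defaults of `interaction_spec()` and `observation_spec()`.

## Known limitations

* $\sigma_x$ is not meaningfully identified by press-times; treat its
  posterior as a prior-dominated nuisance, fixed downstream.
* Masses are identified only relative to the assumed environment
  constants; comparisons across environments require rescaling.
* The observation model assumes strictly positive velocities throughout;
  collision configurations that reverse a puck's direction would need a
  signed-percept extension.
* The feedback-phase learning rule is a deliberately simple running
  Bayesian update; it reproduces the few-trial adjustment scale but is not
  a model of trial-by-trial human learning dynamics.
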