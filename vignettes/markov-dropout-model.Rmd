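---
title: "A three-state Markov model for incomplete binary outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov model for incomplete binary outcomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovmiss)
```

## The model

`markovmiss` analyzes a dichotomous outcome observed at scheduled visits
in a randomized trial where patients drop out. Instead of imputing the
missing outcomes, it models the joint outcome-and-dropout process as a
continuous-time Markov chain over three states: nonresponse (1), response
(2) and an absorbing study-discontinuation state (3). Transitions 1⇄2
capture response and relapse; 1→3 and 2→3 capture state-dependent
dropout. The four intensities γ₁₂, γ₁₃, γ₂₁, γ₂₃ per arm — in units of
inverse time, per week throughout this package's examples — are the
parameters of interest; every reported estimand is a deterministic
function of them.

Three assumptions do the work:

* **Markov property.** A patient's future path depends only on the
  current state — not on how long they have been in it, nor on earlier
  states. Plausible when carry-over effects of past response are small;
  questionable for conditions with strong history dependence.
* **Time-homogeneous rates.** Intensities are constant over follow-up.
  For long trials a piecewise-constant extension would be natural; it is
  deliberately out of scope here.
* **Exchangeability within arm** in the base model; relaxed by
  patient-level random effects and covariates (below).

Because the state space is exhaustive, the generator `build_generator()`
has zero row sums, and the transition probability matrix solves the
Kolmogorov forward equation, Π(Δt) = exp(Δt·G). For this particular
structure the eigen-decomposition is analytic: with exit rates
λ₁ = γ₁₂+γ₁₃, λ₂ = γ₂₁+γ₂₃ and discriminant
h = √((λ₁−λ₂)² + 4γ₁₂γ₂₁), the transient 2×2 block decays as a mixture
of exp(−(λ₁+λ₂−h)Δt/2) and exp(−(λ₁+λ₂+h)Δt/2)
(`transition_probs()`), and the dropout column is the row complement.

## Likelihood for panel-observed visits

Visits give panel data: the path between observations is unobserved. Each
pair of consecutive non-missing states (including the implicit state-1
baseline at time 0) is one multinomial draw whose cell probabilities are
the corresponding row of Π(Δt) (`transitions_from_record()`,
`log_likelihood()`). Two consequences worth spelling out:

* a patient observed in the *same* state twice is still informative —
  staying put has a probability too;
* a skipped visit flanked by observations contributes nothing itself; it
  only lengthens the Δt between its neighbours. No imputation and no
  extra assumption is needed, and the likelihood of `(1@0, NA@1, 1@2)`
  is identical to that of `(1@0, 1@2)`.

A patient whose trailing visits are all missing without an observed
dropout is treated as administratively censored at the last observed
visit. The harsher preprocessing rule used in the motivating trial —
recode a missed visit and everything after it as dropout — is available
as an explicit, optional transform (`recode_missing_as_dropout()`), never
an inference-layer default.

## Fitting

`fit_mle()` maximizes the transition likelihood over the free log rates
(L-BFGS-B, several jittered starts, box (−10, 5) matching the prior
support below) and reports Wald intervals from the numerical Hessian. A
transition type with no information ends up at the box bound and is
flagged non-identifiable rather than silently reported. Random-effects
models are excluded from the MLE route: they would require integrating
the likelihood over patient effects, and the Bayesian route handles that
naturally.

`fit_bayes()` uses a handwritten gradient-free sampler:
componentwise adaptive random-walk Metropolis on the
unconstrained parameters, adaptation (toward 44% acceptance, Robbins-
Monro on the log step size) during burn-in only, so the retained chain is
a valid fixed-kernel Markov chain. Priors are minimally informative and
configurable (`prior_spec()`): ln γ ~ Uniform(−10, 5) — the bounds only
exclude absurd rates and in practice do not move estimates — τ ~
Uniform(0, 1), covariate coefficients Normal(0, 10²); the coefficient
prior is a package choice, documented because no reference value exists.
Reference protocol: 2 chains, 20 000 burn-in, 20 000 retained draws;
convergence via the between/within-chain potential scale reduction factor
(`psrf()`), with PSRF > 1.1 attached as a warning — never an exception,
since the user needs the samples to diagnose the problem. Interval
summaries are type-7 empirical 2.5/50/97.5 percentiles.

Model structure is declared, not coded (`model_spec()`): within-arm
equalities such as γ₁₃ = γ₂₃ (the MCAR restriction), rates shared across
arms (for example a common responder-dropout rate), random effects on any
subset of transitions with a common or per-transition τ, and covariates
with optional coefficient tying (b₁₃ = b₂₃, or coefficients common across
arms). Tied parameters are one free parameter, so constrained draws are
bitwise identical by construction. Random effects are sampled by data
augmentation — one log-offset per patient per affected transition —
updated in vectorized blocks; this is valid because the likelihood
factorizes over patients given the arm-level parameters, and it is what
keeps the default chain lengths affordable. Per-patient random-effect
vectors across transition types are independent; nothing in the
hierarchical form suggests otherwise, and a correlated version would add
parameters the data cannot inform.

Two likelihood engines sit behind the samplers: for models without
patient-specific terms the data collapse to (arm, from, to, Δt) counts
and the likelihood is a short weighted sum; with random effects or
covariates the per-patient probabilities are evaluated vectorized from
the closed form. Every stochastic operation takes an explicit seed and
records it in the result.

## Derived estimands

All estimands exist in two summaries, and the distinction matters: the
*posterior* summary transforms each draw and takes medians (the right
thing for inference), while the *plug-in* summary transforms point rates
(the thing that reproduces a table computed from printed medians — a
median of transforms is not the transform of medians). Published
posterior-median contrasts are therefore matched exactly by plug-in only
where the transform chain is deterministic; elsewhere the plug-in
approximation lands within a couple of units in the second decimal.

* `relative_effect()` — δ = l(π₍XY₎ⁿᵘᵐ) − l(π₍XY₎ᵈᵉⁿ) under a logit,
  log, or identity link; exponentiated scales returned as OR/RR. Draws
  with degenerate probabilities under the link are skipped and counted;
  more than half skipped is an error.
* `rate_ratio()` — per-draw or plug-in ratios of intensities, the scale
  on which multi-study pooling would happen.
* `expected_time_in_state()` — ∫₀ᵀ π₁ₓ(t) dt, analytic because each
  occupancy is a sum of exponentials. The three values sum to T exactly;
  adaptive quadrature of the matrix-exponential path
  (`expected_time_in_state_quad()`) is kept as an independent check and
  as the fallback for degenerate rates. The horizon is always an explicit
  argument.
* `prob_dropout_without_response()` — probability of dropping out by Δt
  *without ever having responded*, which is the probability that the
  first jump out of state 1 goes to 3 and happens before Δt:
  (γ₁₃/λ₁)(1−e^(−λ₁Δt)).
* `dropout_split()` / `prob_dropout_after_response()` — π₁₃ split by the
  state from which dropout occurred, computed by duplicating the
  absorbing state into two copies and exponentiating the expanded 4×4
  generator. The two split parts sum to π₁₃ exactly. Note the subtlety:
  "dropout from nonresponse" (the split component) is *larger* than
  "dropout without ever responding", because a patient can respond,
  relapse, and then drop out from state 1; the two notions are
  deliberately separate functions, and both are validated against exact
  path simulation.
* `cca_odds_ratio()` / `locf_odds_ratio()` — the comparator analyses,
  with Woolf log-scale intervals and a 0.5 continuity correction on zero
  cells (the interval method is a package choice; none is prescribed for
  these comparators).

## The four-state missingness extension

Treating response and dropout as mutually exclusive wastes the question
everyone actually asks: what would the dropouts' outcomes have been?
The extension replaces state 3 with unobserved nonresponse (4) and
unobserved response (5); dropouts keep moving between 4 and 5 but never
return — dropout stays absorbing as a block. The estimand becomes
π₁₂ + π₁₅, response whether observed or not.

The eight four-state rates are not identifiable from observed data, so
the workflow is two-stage by type design: fit the three-state model, then
expand the fitted rates under a named scenario (`expand_scenario()`):

* **MCAR** — dropout independent of everything: γ₁₄ = γ₂₅ = common
  dropout rate (requires a fit with γ₁₃ = γ₂₃; requesting it otherwise
  is an error instructing a refit), γ₁₅ = γ₂₄ = 0, hidden dynamics
  mirror the observed ones (γ₄₅ = γ₁₂, γ₅₄ = γ₂₁). Response and dropout
  become independent processes, and π₁₂+π₁₅ collapses to the two-state
  formula (γ₁₂/(γ₁₂+γ₂₁))(1−e^(−(γ₁₂+γ₂₁)Δt)) — an identity the tests
  verify to 1e-9.
* **MAR** — dropout depends on the observed state only:
  γ₁₄ = γ₁₅ = f·γ₁₃, γ₂₄ = γ₂₅ = f·γ₂₃ with f = 0.5 by default.
* **MNAR** — dropout depends on the unobserved destination:
  γ₁₄ = f₁γ₁₃, γ₁₅ = (1−f₁)γ₁₃, γ₂₄ = f₂γ₂₃, γ₂₅ = (1−f₂)γ₂₃, hidden
  dynamics scaled by m₄₅, m₅₄. Defaults f₁ = f₂ = 0.9, m₄₅ = 0.1,
  m₅₄ = 2 reproduce the illustrative analysis in which 90% of dropouts
  land in unobserved nonresponse and tend to stay there. (The source
  scenario list states the γ₂₅ constraint with a typo — γ₁₅ appears
  twice; the second occurrence is read as γ₂₅, the only reading
  consistent with the first.)
* **LOCF-like** — dropouts freeze in their last observed state:
  γ₁₅ = γ₂₄ = γ₄₅ = γ₅₄ = 0.
* **All dropout failure** — the literal published constraint is
  γ₁₄ = γ₂₄ = 0, which under the state-4 = unobserved-*nonresponse*
  convention routes every dropout into unobserved *response* —
  contradicting the scenario's name. Rather than guess the intent, both
  readings are provided behind a flag: `literal = TRUE` (default)
  applies the constraint as written; `literal = FALSE` routes all mass
  to unobserved nonresponse (γ₁₅ = γ₂₅ = 0, γ₄₅ = 0). Neither silently
  substitutes for the other.

Every expansion conserves dropout mass (γ₁₄+γ₁₅ = γ₁₃, γ₂₄+γ₂₅ = γ₂₃),
so the probability of having dropped out is preserved whenever the hidden
dynamics do not matter for it. Four-state probabilities come from the
matrix exponential — no closed form is attempted at this dimension — and
are validated against exact path simulation for every scenario.

## The simulator, and what passing tests do not show

`simulate_study()` is first-class code, not a fixture: exact event-driven
simulation of the continuous-time chain (exponential holding times,
competing-risk destination draws), observed only at the visit schedule.
It emulates the motivating design — two arms, visits at weeks 1, 2, 4, 6,
8, everyone starting in nonresponse, arm sizes 115/113 where the original
scale is wanted — plus log-normal random effects, a standard-normal
covariate (no reference distribution exists; standard normal is the
neutral choice) and an independent missed-visit process, kept strictly
distinct from dropout.

Because the simulator *is* the generative model, parameter-recovery tests
demonstrate internal consistency, not robustness: they cannot reveal how
the model behaves under non-Markov dynamics, time-varying rates,
non-lognormal heterogeneity, or missingness mechanisms outside the
scenario family. That is exactly the class of question the four-state
scenarios are meant to probe as sensitivity analyses, not settle.

Reproducibility: each patient draws from an own substream whose seed is
drawn once from the master stream, so record i is reproducible under
reordering. (Deriving substream seeds as consecutive integers is not
innocuous: the first draws of consecutively-seeded Mersenne-Twister
streams are correlated enough to bias occupancy proportions visibly at
n = 2·10⁴; drawing the substream seeds from the master stream removes
the artifact.)

`monte_carlo_path_probability()` exposes the same engine, vectorized over
10⁵-path batches, as the oracle for every closed-form claim: predicates
over path summaries (final state, states ever visited, state from which
dropout occurred) are compared to analytic values within three binomial
standard errors.

## Numerical choices

* **Closed form vs expm.** The analytic π₁₂ expression divides by γ₂₁
  and all closed forms divide by h; both singularities are removable.
  When γ₂₁ < 1e-12 or h < 1e-10 the computation routes silently through
  the matrix exponential (`Matrix::expm`, scaling-and-squaring), which
  is always defined. The power-series definition of the exponential is
  documented but never used for computation — truncated series are
  numerically poor for large Δt·rates. Closed form and expm agree to
  1e-10 over randomized rates in [0, 2] per week and Δt up to 20 weeks.
* **Round-off policy.** Probabilities are clipped to [0, 1] and rows
  renormalized only when the violation is below 1e-10; anything larger
  raises an internal-consistency error — float noise is tolerated, bugs
  are not.
* **Units.** Rates and visit times share whatever unit the data use
  (weeks in all examples); nothing is rescaled internally.
* **PSRF.** Classic between/within form, floored at 1: values below 1
  are sampling noise, and the floor makes the identical-chains edge case
  return exactly 1.
* **Ties and degenerate inputs.** Zero rates, empty arms, patients with
  a single visit, datasets with no transitions (posterior = prior) are
  all defined behavior with tests.
* **Config format.** The CLI reads YAML configs and writes JSON fit
  artifacts — human-diffable, no binary dependencies.

## Problem sizes in the test suite

The suite exercises the closed-form/expm agreement at 1000 random rate
sets × three horizons; recovery at 5000 patients (MLE, ±10%) and at
500/arm (trial scale; Bayesian medians within 3 posterior SDs at 2
chains × 2000/2000); heterogeneity recovery (τ = 0.6) at 500/arm;
Monte-Carlo validation at 10⁵ paths. These sizes were chosen so the whole
suite runs in a few minutes while leaving each check clearly powered —
with one instructive exception: at 500 patients/arm the smallest rate in
the reference configuration (γ₂₃ = 0.009 per week) generates only about
eleven 2→3 events, so its MLE has a log-scale standard error near 0.34
and *no* estimator can reliably hit a ±15% band at that scale. The
corresponding fixed-tolerance assertion is retained at face value and
documented as failing for that statistical reason; the well-calibrated
3-posterior-SD check on the same data passes.

## Limitations

* Time-homogeneous rates; no piecewise-constant extension.
* MLE route excludes random effects.
* One absorbing reason for dropout; trials recording dropout causes would
  need more absorbing states, which also ends the closed-form regime.
* Four-state rates are assumption-driven, never estimated: the scenarios
  are sensitivity analyses, and measures of fit cannot choose among them.
* Meta-analytic pooling across studies is out of scope; the rate-ratio
  scale output is the intended interface to it.
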