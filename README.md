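# markovmiss

Continuous-time Markov models for longitudinal binary outcomes with
informative dropout.

## The problem

Trials that record a dichotomous outcome (responder / non-responder) at a
handful of scheduled visits almost always lose patients along the way; in
psychiatry, dropout rates of 30–50% are routine, and dropout is usually
*informative* — patients who are not getting better leave more often. The
common fixes (complete-case analysis, last observation carried forward,
mixed models for repeated measures) each hard-wire an assumption about the
missing outcomes.

`markovmiss` takes a different route: it models the *process* that
generates both the outcome and the dropout. Each patient moves through
three states —

* state **1**: nonresponse (everyone starts here),
* state **2**: response, with relapse back to 1 allowed,
* state **3**: study discontinuation, absorbing —

as a continuous-time Markov chain with four transition intensities
γ₁₂, γ₁₃, γ₂₁, γ₂₃ (per week) per treatment arm. The generator

```
        ( −(γ12+γ13)    γ12        γ13  )
    G = (    γ21     −(γ21+γ23)    γ23  )
        (     0           0         0   )
```

gives the transition probability matrix Π(Δt) = exp(Δt·G), for which the
three-state structure admits closed forms: with λ₁ = γ₁₂+γ₁₃,
λ₂ = γ₂₁+γ₂₃ and h = √((λ₁−λ₂)² + 4γ₁₂γ₂₁), every π_XY(Δt) is a mixture
of exp(−(λ₁+λ₂∓h)Δt/2) terms. Each pair of consecutive observed states is
one multinomial draw over the three destinations, so panel-observed visit
data (including skipped visits, which simply lengthen Δt) yield a
likelihood for the rates. Fitting is by maximum likelihood or by adaptive
Metropolis MCMC with uniform(−10, 5) priors on the log rates, optional
patient-level random effects (log-normal, SD τ ~ uniform(0, 1)) and
covariates.

From the fitted rates the package derives the quantities clinicians ask
for: time-dependent odds ratios for response and dropout, transition-rate
ratios, expected time spent in each state, and the probabilities of
dropping out with or without ever having responded. A four-state extension
with *unobserved* nonresponse/response states (4 and 5) encodes MCAR, MAR,
MNAR, LOCF-like and all-dropout-failure scenarios for sensitivity analysis
of what happened to the dropouts; its estimand is the probability of
observed-or-unobserved response, π₁₂ + π₁₅. An exact event-driven
trajectory simulator doubles as synthetic-data generator and Monte-Carlo
oracle.

## Worked example

Using the published median rates of a two-arm schizophrenia trial
(amisulpride: γ₁₂ = 0.189, γ₁₃ = 0.052, γ₂₁ = 0.076, γ₂₃ = 0.024;
risperidone: 0.136, 0.047, 0.056, 0.009 per week):

```r
library(markovmiss)
ami <- transition_rates3(0.189, 0.052, 0.076, 0.024)
ris <- transition_rates3(0.136, 0.047, 0.056, 0.009)

transition_probs(ami, dt = 8)
#> Transition probabilities over dt = 8
#>          1        2        3
#> 1 0.254986 0.471315 0.273699
#> 2 0.189523 0.606602 0.203875
#> 3 0.000000 0.000000 1.000000
```

A patient starting amisulpride has a 47.1% chance of being an (observed)
responder at week 8 and a 27.4% chance of having left the study. Over the
8 weeks they spend on average 3.97 weeks in nonresponse, 2.80 in response
and 1.23 after discontinuation (`expected_time_in_state(ami, 8, state)`).

```r
arms <- list(amisulpride = ami, risperidone = ris)
relative_effect(arms, from = 1, to = 2, dt = 8, link = "logit",
                arms = c("risperidone", "amisulpride"), summary = "plugin")
#> OR at dt = 8: 0.9288
relative_effect(arms, from = 1, to = 3, dt = 8, link = "logit",
                arms = c("risperidone", "amisulpride"), summary = "plugin")
#> OR at dt = 8: 0.8064
```

Response hardly differs between the drugs (OR 0.93), while risperidone
patients drop out less (OR 0.81). Under an illustrative
missing-not-at-random scenario in which 90% of dropouts land in unobserved
nonresponse and tend to stay there:

```r
scenario_odds_ratio(arms, scenario_spec("MNAR"), dt = 8,
                    arms = c("risperidone", "amisulpride"),
                    summary = "plugin")
#> OR at dt = 8: 0.9118
```

Simulating a trial at the original size and refitting recovers the rates:

```r
ds  <- simulate_study(sim_config(arms, n_per_arm = c(115, 113), seed = 42))
fit <- fit_bayes(ds, chains = 2, burnin = 2000, iter = 2000, seed = 1)
fit$summary[1:2, ]
#>              parameter   type estimate lower upper psrf
#> 1 lgamma12.amisulpride lgamma    -1.70 -1.96 -1.46 1.00
#> 2 lgamma12.risperidone lgamma    -2.15 -2.44 -1.89 1.00
```

(`log(0.189) = -1.67`, `log(0.136) = -1.99`; both true values sit inside
the 95% credible intervals, and PSRF ≈ 1 indicates the two chains mixed.)

A command-line front end for shell pipelines lives at
`inst/cli/markovmiss.R` (subcommands `simulate`, `fit`, `effects`,
`predict-missing`, `occupancy`; YAML configs, JSON fit artifacts).

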