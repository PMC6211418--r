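---
title: "An agent-based model of sports participation and income inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of sports participation and income inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sportabm` simulates adult sports participation in a gridded city of
10 m cells. Individuals are agents characterised by age, sex, income
level, a home cell, and an *initial tendency* $T_0$ — a dimensionless
propensity drawn at creation from a Gamma distribution with mean 1.
Sports facilities (fitness centres and sports-club facilities) are
agents too: they sit on designated locations, carry a dichotomous price
level (cheap/expensive), and adapt annually to demand.

Participation happens in three categories: **fitness** (at a fitness
centre), **club** (e.g. football or tennis, at a club facility) and
**self-organized** (e.g. running; no facility needed). Whether and when
an individual starts a category is governed by the *tendency to start
sports*,

$$
T_c \;=\; T_0 \cdot E \cdot s_{\text{age}} \cdot s_{\text{sex}} \cdot
 s_{\text{income}} \cdot s_{\text{safety}} \cdot s_{\text{cohesion}}
 \cdot s_{\text{social}} \cdot
 \underbrace{s_{\text{price}} \cdot e^{-\beta d / 10}}_{\text{facility
 categories only}},
$$

where $E \ge 1$ is a health-education boost (1 unless targeted),
$s_{\text{safety}}, s_{\text{cohesion}} \in [0,1]$ are the home
neighbourhood's perceived safety and social cohesion,
$s_{\text{social}} = 1 + p$ with $p$ the share of participating
residents within 50 m, $s_{\text{price}}$ is 1 (cheap) or 0.85
(expensive) for the selected facility, and $e^{-\beta d/10}$ is the
accessibility of that facility at Euclidean distance $d$ metres
($\beta$ per 10 m, i.e. per cell). Individuals rank all open facilities
of a kind by the *preference score* $s_{\text{price}} \cdot
e^{-\beta d/10}$ and join the best one (ties to the lowest facility
id). Self-organized sport ignores price and accessibility.

The waiting time from becoming eligible to starting a category is
exponential with rate $\lambda_c = T_c \cdot F$ per year, $F$ being the
mean frequency of sports in the city. Each simulated month (the model's
time step) individuals age by 1/12 year, some die or migrate away — each
replaced by a new non-participating resident of the same neighbourhood,
keeping the population constant — and start events fire. At the end of
every year, participants quit each category with the category's annual
probability (0.28 fitness, 0.12 club, 0.27 self-organized), survivors
change frequency (monthly→weekly with 0.21, weekly→monthly with 0.09),
and the facility stock turns over: per kind, the open facility with the
fewest members closes (its location becomes vacant; members immediately
re-select the best remaining facility) and a new facility opens at a
vacant location of the neighbourhood with the highest demand.

### Monthly hazards instead of explicit clocks

The specification of the start mechanism has two parts: exponential
clocks ceiled to whole months, *and* a refresh of pending clocks
against current tendencies at every step (so that price changes, new
facilities and changing neighbours take effect immediately). Because
the exponential is memoryless, these two together are exactly
equivalent to firing a start each month with probability
$1 - e^{-\lambda_c/12}$ computed from the current tendency: for a
constant rate, the month of the first start is Geometric with that
success probability, which is precisely the distribution of the ceiled
exponential clock. The engine therefore draws a single uniform per
agent, category and month; `schedule_start()` exposes the literal clock
draw, and the test suite checks both routes against each other.

Quitting and restarting need no extra state either: a quitter simply
becomes a non-participant again, and the same monthly hazard governs
the restart — the stated rule that restarts behave like first starts,
with no refractory period.

## Shipped parameter values

| Parameter | Value | Origin |
|---|---|---|
| mean frequency $F$ | 153.5 / yr | published calibrated value |
| age scores (young 18–35 / middle 35–55 / old 55–85) | 1 / 0.157 / 0.148 | published calibrated values |
| sex scores (male / female) | 1 / 0.659 | published calibrated values |
| income scores (high / middle / low) | 1 / 0.471 / 0.428 | published calibrated values |
| price score (cheap / expensive) | 1 / 0.85 | published estimate |
| distance decay $\beta$ (fitness / club) | 0.029 / 0.027 per 10 m | published calibrated values |
| annual quit probabilities (fitness / club / self) | 0.28 / 0.12 / 0.27 | published national rates |
| frequency flip probabilities (up / down) | 0.21 / 0.09 | published rates |
| multi-sport frequency adjustment | 0.5 | published assumption |
| initial tendency | Gamma, mean 1, variance 0.5 | published best fit |
| weekly share at start | 0.5 | package assumption |
| death schedule | $2.6\times10^{-5} e^{0.0946\,\text{age}}$ /yr | package assumption (Gompertz-like) |
| out-migration | 0.05 /yr | package assumption |

Age-group boundaries are half-open — 35 belongs to the middle group and
55 to the old group. The Gamma parameterisation reads "(1.0, 0.5)" as
mean and variance (shape 2, scale 0.5): the mean is separately stated
to be one, and the calibration profiles are described as assumptions on
the *variation* of the initial tendency. Both the distance-decay unit
(per 10 m; a per-metre reading would annihilate every non-colocated
facility, $e^{-29}$ at 1 km) and the boundary convention are exposed as
configuration, not hard-coded.

## The synthetic city

The original city's registry and GIS inputs are not public, so
`generate_city()` builds a stand-in that matches the *published
aggregates*: 88 contiguous neighbourhoods on a 600×600-cell grid
(36 km²), 173,567 adults aged 18–85 (mean 46, 49% female, income split
41/40/19% low/middle/high), 305 fitness and 98 club designated
locations, 30 fitness centres and 158 club facilities open, with
37%/40% priced expensive. Neighbourhoods are Voronoi cells of random
seed points (contiguous by construction); residents are allocated to
neighbourhoods in proportion to area; neighbourhood demographic mixes
are Dirichlet-perturbed copies of the city aggregate (concentration
$1/\text{sorting\_strength}$), then recentred by iterative proportional
fitting so the population-weighted aggregates are exact. Safety and
cohesion are Beta-distributed per neighbourhood on $[0,1]$ with mean
0.65 — the intervention arithmetic ("raise to 0.75", "raise to the city
mean") fixes the scale of these scores, and 0.65 leaves realistic
headroom below the intervention targets.

Two deliberate deviations from the published description:

* The published counts are internally inconsistent for clubs: 158 open
  club facilities cannot sit one-per-location on 98 designated
  locations. The generator creates `max(locations, open)` locations per
  kind, so clubs get 158 (all initially occupied). A consequence worth
  knowing: club openings can only reuse locations freed by closures, so
  the availability intervention mostly adds fitness centres.
* A `population_scale` option shrinks population, facility counts *and
  grid area* proportionally (keeping all 88 neighbourhoods), so that
  spatial density — and with it the social-influence neighbour counts
  and facility distances — stays comparable at desk scale. All
  rate-type parameters are per-capita and unaffected.

What the generator does *not* emulate: the real city's geography,
spatial autocorrelation of income beyond the one-knob Dirichlet
sorting, the true per-neighbourhood age/sex/income joint distributions
(only the marginals and their between-neighbourhood dispersion), and
empirical facility siting. Tests passing on the synthetic city
demonstrate internal consistency of the mechanism, not fidelity to the
real city.

## Reconstructions of unavailable detail

Three pieces of the original supplementary material are not restated in
the main text; each is reconstructed and flagged:

* **Preference score** — the product price × accessibility; this is the
  natural combination of the two published facility factors.
* **Facility demand** — a neighbourhood's demand for a kind is the
  summed facility-independent tendency of residents not yet in that
  category, divided by (1 + open facilities of the kind in the
  neighbourhood): demand grows with unserved propensity and falls with
  local supply. A simpler participant-count alternative can be swapped
  in.
* **Multi-sport frequency adjustment** — the direction of the
  probability-0.5 change is unstated; we implement compensation
  (starting an additional sport may drop an existing weekly habit to
  monthly; quitting one of several may upgrade a remaining monthly
  habit). Participation metrics are frequency-blind, so this choice
  does not affect the headline outcomes.

The social-influence functional form (the published text only says the
tendency *increases with* the neighbour share) is the bounded
multiplier $1 + p \in [1, 2]$; whether "participating neighbours"
counts any category or the category being scored is a config switch
(`si_mode`), defaulting to any-category.

## Randomness, determinism and scenario contrasts

All randomness flows through named streams (population, demography,
starts, quits, frequency, facilities, interventions), each seeded from
the scenario seed by a fixed splitting rule. Demography, starts and
quits draw one uniform per agent per occasion regardless of
eligibility, so the stream consumption is state-independent: an
intervention leaves the demographic history of its counterfactual
bit-identical, and scenario contrasts are paired by common random
numbers. Identical configs and seeds reproduce runs exactly.

Ensembles summarise uncertainty the published way: with 80 runs the 95%
range discards the two highest and two lowest outcomes (3rd smallest to
3rd largest); for other ensemble sizes `ceiling(0.025 n)` per tail is
discarded, and below 5 runs the interval is omitted with a warning.

## Numerical and procedural choices

* Waiting times are ceiled to whole months (the monthly hazard above).
* Annual events run in a fixed order: quits → frequency flips →
  facility turnover (fitness before club) → intervention bookkeeping.
* Quits are applied before frequency flips when both hit the same
  individual in the same year; the source is silent on the order.
* Facility-choice ties break to the lowest facility id; demand ties to
  the lowest neighbourhood id; the availability ranking breaks ties to
  the lowest neighbourhood id.
* Annual reporting is implicit in the monthly metric log; equilibrium
  quantities average the last five simulated years of monthly values,
  and a stationarity diagnostic (absolute slope of annual overall
  participation over the last ten years, flagged above 0.2 points/yr)
  accompanies every equilibrium estimate.
* Neighbourhoods that lose all residents to a filter yield `NA`
  metrics, never silent zeros.

## Calibration

`grid_search()` implements the published procedure: the eight free
parameters (two age scores, the female score, two income scores, two
distance decays, the mean frequency) are searched on a user grid
against equilibrium participation targets with an equally weighted
sum-of-squares loss, reference categories pinned at 1, with optional
coarse-to-fine refinement. `calibrate_baseline()` is the fast scale
calibration used by the reproduction harness: on a synthetic city the
published *scale* parameters cannot transfer (the spatial and social
structure differs), so the mean frequency — and optionally the two
income scores — are re-tuned by monotone secant search on the log scale
(participation odds are roughly linear in the rate scale, so the first
jump lands near the root; a running bracket safeguards every step).
Evaluations are single-seed equilibrium runs; verification always uses
independent seeds.

Problem sizes: the reproduction harness runs 20,000 agents with a
30-year burn-in and a 5-year measurement window, verifying on 10
independent seeds; the intervention-ordering checks use 4,000 agents
and 20-run ensembles. These sizes give Monte-Carlo standard errors of a
few tenths of a percentage point on participation levels, small against
the 1–4 point effects being measured, while keeping a full test cycle
on a single CPU pleasant. Full-scale experiments (173,567 agents,
50-year burn-in, 80-run ensembles) use exactly the same code paths via
the default config.

## Known limitations

Starting, quitting and frequency changes are mutually independent
processes; quitting ignores the tendency. Price is dichotomous. Social
influence stops at a 50-m radius — no friendship networks. No childhood
sports history; entrants never participate at entry. Intervention
effects are immediate by assumption. The synthetic city is a documented
stand-in: absolute calibrated scale parameters on it are not
comparable to the published ones, and conclusions about the real city
require the real inputs.
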