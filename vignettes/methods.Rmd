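---
title: "Methods: habitat-driven landings projections, inverse demand, and consumer welfare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat-driven landings projections, inverse demand, and consumer welfare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishclim)
```

This vignette documents the models implemented in `fishclim`, the
assumptions behind them, the defaults and why they were chosen, and the
places where the design was genuinely open and a choice had to be made.

## 1. The problem

Warming oceans shift where fish can live. Given per-species projections of
*thermally available habitat* (summed probability of occurrence over a
coastal grid) under two emissions scenarios (RCP 4.5 and RCP 8.5) and five
general circulation models, the pipeline asks two questions:

1. **Screening:** if landings change in direct proportion to thermal
   habitat, which fisheries gain or lose, and by how much in discounted
   ex-vessel revenue over 2021–2100?
2. **Welfare:** for the 16 highest-value tractable fisheries, organised
   into four substitution groups, what do those harvest changes do to
   seafood consumers once prices and budget reallocation respond?

Producer surplus, fleet dynamics and management response are deliberately
out of scope: harvests are exogenous trajectories, motivated by management
regimes that constrain catch to biologically determined levels.

## 2. Screening

### Habitat to annual multipliers

Habitat totals arrive in five 14–20-year bins (baseline 2007–2020, then
T1–T4 covering 2021–2100). Per GCM, the fractional change versus baseline
is $\Delta h = (H(\mathrm{bin}) - H(B_0))/H(B_0)$; the *ensemble* value is
the arithmetic mean of the per-GCM fractional changes (mean of ratios, not
ratio of means — the average is taken after the percent-change step; the
two differ only at second order in the GCM spread).

The published analysis defines only bin values but plots annual series.
`annualize()` anchors each bin's value at its midpoint (2013.5, 2030.5,
2050.5, 2070.5, 2090.5), interpolates linearly between anchors, and holds
the last value flat from 2090.5 to 2100. Midpoint anchoring respects bin
means for linear trends; the flat tail avoids extrapolating beyond the last
bin. Stepwise repetition of bin means was the alternative; the
interpolation choice is recorded in every run manifest.

A zero baseline bin is an error by construction (the percent change is
undefined); degenerate records of that kind are expected to be excluded
upstream, as was done for snow crab in the source analysis.

### Valuation

Landings scale proportionally: $x_t = \bar{x}\, m_t$ with
$m_t = 1 + \Delta h(t)$, at constant ex-vessel prices. Values are
discounted at a real $r = 0.03$ to end-2020 (the first projection year 2021
carries exponent 1), so a constant dollar over 2021–2100 is worth
$\sum_{k=1}^{80} 1.03^{-k} = 30.2008$ — the convention that reproduces the
published percentage columns exactly. Percentage impacts are
$\Delta PV / (\bar{x} \times 30.2008)$.

### Monte Carlo intervals

The published intervals name exactly two variance sources: interannual
variation in 2007–2016 landings, and GCM spread. The scheme here is the
simplest one using exactly those: each draw (i) bootstraps the ten annual
baseline values with replacement and (ii) picks one GCM uniformly; the
interval is the 2.5th/97.5th percentile of
$(\bar{x}_{\mathrm{draw}} m - \bar{x})/\bar{x}$ across 10,000 draws
(configurable). Landings and habitat are resampled independently — whether
the original simulation coupled them is unstated, and independence is the
natural default. The point estimate is the ensemble-mean percent change, to
which the Monte Carlo mean converges as interannual variance vanishes.

### Record matching

`match_records()` mirrors the published curation order: automated
name-equality match, manual synonym match, exclusion of multi-species
aggregate records, then a *de minimis* exclusion (mean annual revenue
strictly below \$100,000, in 2018 dollars) applied only to records not
otherwise matched, with the remainder classified as lacking a projection.
A record appearing in both the synonym map and the multi-species set is an
error (ambiguous curation), not a silent choice.

## 3. The inverse almost ideal demand system

Ex-vessel quantities are set by biology and management; prices adjust. The
natural model is therefore an *inverse* demand system: shares respond to
quantities. The IAIDS derives from the translog distance function

$$\ln D(q, u) = a(q) - u\, b(q), \qquad
a(q) = \alpha_0 + \sum_i \alpha_i \ln q_i + \tfrac12 \sum_{i,j}
\gamma_{ij} \ln q_i \ln q_j, \qquad
b(q) = \beta_0 \prod_i q_i^{\beta_i}.$$

Differentiating $\ln D$ and evaluating on the frontier $D = 1$ (where
$u\,b(q) = a(q)$) gives the share equations

$$w_i = \alpha_i + \sum_j \gamma_{ij} \ln q_j - \beta_i \ln Q,$$

with $\ln Q = a(q)$. Note the **negative** sign on $\beta_i$: it is forced
by utility-theoretic consistency. With $\ln D = a - u\,b$ and
$b(q) = \beta_0\prod q^{\beta_i}$, the restriction set
($\sum\alpha_i = 1$, $\sum\beta_i = 0$, $\Gamma$ symmetric with zero row
sums) delivers linear homogeneity $D(\lambda q, u) = \lambda D(q, u)$, the
flexibility formula below, and shares that sum to one identically — all
three are verified by tests. Writing the share equation with $+\beta_i$
would flip one of the other two. $\alpha_0$ and $\beta_0$ are not
identified by the share equations; they are fixed at 0 and 1 and act as
welfare normalisations.

### Estimation

For estimation $\ln Q$ is replaced by the Stone index
$\sum_j w_j \ln q_j$ (LA-IAIDS), the standard estimable form when the
translog index's parameters are unknown. Estimation details:

* The $n$-th share equation is dropped — adding-up makes the system
  covariance singular — and its parameters are recovered from the
  restrictions afterwards. A test verifies the estimates are invariant (to
  $10^{-6}$) to *which* equation is dropped.
* Homogeneity is imposed by differencing log quantities against the
  dropped good; symmetry by sharing $\gamma_{ij}$ across equations. The
  free vector is $(\alpha_{1..n-1}, \beta_{1..n-1},
  \mathrm{vech}(\Gamma_{n-1}))$: 12 parameters for $n = 4$, with the other
  12 identified by the restrictions.
* Iterated feasible GLS (seemingly unrelated regressions) runs to the
  maximum-likelihood fixed point: tolerance $10^{-8}$ on the relative
  parameter change, at most 100 iterations, with an informative error and
  iteration trace on non-convergence. A perfect fit (noise-free data) is
  detected by a vanishing residual scale and returns a zero covariance; a
  genuinely singular residual covariance with non-trivial residuals is an
  error advising more data.
* Quantities enter centred at the panel's per-species geometric mean. The
  IAIDS is not invariant to quantity units, so a units convention is
  required; centring makes the base period the numeraire bundle and is
  applied identically in generation, estimation and forecasting.

Flexibilities (the inverse-demand analogue of price elasticities,
$\partial \ln p_i/\partial \ln q_j$) at mean shares $\bar w$ are

$$f_{ij} = -\delta_{ij} + (\gamma_{ij} - \beta_i \bar w_j)/\bar w_i,$$

verified against finite differences of the implied inverse demand
$p_i = w_i E / q_i$. The published tables are labelled "price
elasticities" while an inverse system natively yields flexibilities; both
are computed and reported side by side, with the elasticities taken as the
entries of $F^{-1}$. Intervals use the delta method: numerical gradients
of the statistic in free-parameter space against the FGLS covariance, with
$\pm 1.96$ standard errors as inner 95th percentiles.

### Two-stage budget allocation

Sixteen goods make a single system intractable; demand is modelled as
first allocating total expenditure across the four fishery groups, then
across species within each group. The stage-1 quantity index for a group
is the Stone index over member species with *frozen* base-period weights —
the estimated stage-2 share intercepts — avoiding simultaneity between
forecast shares and the index. Stage 2 is estimated first; its intercepts
then define the stage-1 indices.

## 4. Forecasting and welfare

Total expenditures grow with real income:
$E_t = E_{\mathrm{anchor}} (GDP_t/GDP_{\mathrm{anchor}})^{0.11}$, with the
GDP path linear between the packaged decadal values and the income
elasticity 0.11 taken from the seafood-demand literature. The path is
anchored at 2020 (for the packaged data, the printed 2020 expenditure;
for synthetic runs, the panel's own baseline annual expenditure) — the
anchoring that reproduces every packaged decadal expenditure row. Growth
is reported against the 2007–2016 average separately.

Forecast shares evaluated at the projected quantity multipliers allocate
$E_t$ to groups and species (`solve_shares()` keeps the Stone index
consistent with the forecast shares themselves, so expenditure is
conserved at both stages to machine precision); dividing by forecast
harvests yields implied prices. A predicted non-positive share — possible
far out of sample — is an error naming the year and good, not a silent
truncation.

Welfare per group uses the group's stage-2 distance function with utility
benchmarked at baseline harvests ($u_0 = a(q_{base})/b(q_{base})$, so
$D(q_{base}, u_0) = 1$), monetised with the group's forecast stage-1
expenditure:

$$W_t = E_t\,(1 - 1/D(q_t, u_0)).$$

This money-metric form is the largest gap-filling decision in the package:
the source defers the exact monetisation to unavailable supplementary
material. The form chosen is exact for proportional bundle changes
($q_t = \lambda q_{base}$ gives $W_t = E_t(1 - 1/\lambda)$ exactly), has
the right sign ($\mathrm{sign}(W_t) = \mathrm{sign}(u(q_t) - u_0)$), zero
point, and is bounded above by $E_t$; losses exceed symmetric gains. An
equivalent-style variant $W_t = E_t(D - 1)$ is exposed behind
`monetization = "ev"`. A bisection money-metric oracle (find the
proportional scaling returning the bundle to benchmark utility) confirms
the implementation to $10^{-6} E_t$. Cross-group interactions enter only
through the stage-1 expenditure allocation; the total is the sum of group
welfare by construction.

## 5. The synthetic data generator

The generator is the package's study-condition definition, not a tuning
knob. Defaults:

* **Layout:** 16 species in 4 groups matching the published group
  assignment; monthly panel over 120 months (2007–2016); baseline annual
  landings (MM lb) equal to the published baseline harvests; group and
  species share intercepts equal to the observed baseline revenue shares
  (total \$3,079.6 MM per year).
* **Quantities:** log-quantity = species mean + 12-month sinusoid
  (amplitude 0.15) + AR(1) noise ($\rho = 0.5$, sd 0.1) — enough
  within-year variation to identify a monthly demand system without exotic
  structure, and positive by construction.
* **Shares:** from the true two-stage share equations (Stone-consistent),
  plus additive $N(0, 0.01)$ noise on the first $n-1$ shares with the last
  the residual, so adding-up holds by construction; draws producing a
  non-positive share are redrawn. At `share_noise_sd = 0` the panel is an
  exact realisation of the true system, enabling the exact-recovery tests
  ($<10^{-6}$, observed at machine precision).
* **True parameters:** $\gamma = c\,(\mathrm{diag}(\alpha) -
  \alpha\alpha')$ with $c = 0.35$ (stage 1) and $0.30$–$0.38$ (stage 2) —
  symmetric, zero row sums, and every good's true own flexibility near
  $-(1-c)$ regardless of its share, i.e. uniformly well-behaved
  downward-sloping inverse demands; small zero-sum $\beta$.
* **Habitat:** per-bin trends equal to the published ensemble-mean harvest
  changes per RCP (interpolating T1 and T3), baseline level 100 shared
  exactly across GCMs, log-normal GCM noise (sd 0.05) on future bins.
* **Expenditure:** constant \$3,079.6/12 MM per month.

What the generator does **not** emulate: real species-specific
seasonality, serially correlated share noise, measurement error in
landings, GCM spatial fields, or any supply response. Passing tests
demonstrate the pipeline's correctness and statistical behaviour under the
assumed data-generating process, not the accuracy of the published
estimates on real data.

One behaviour worth knowing: the smallest-share species (Florida stone
crab, share ≈ 0.03) carries share noise of a third of its level at the
default settings, so its estimated own-price terms are imprecise; at some
seeds the point estimate can cross zero, with a delta-method interval wide
enough to flag it. That mirrors the real-data situation, where one
fishery's own-price interval also crossed zero.

## 6. Problem sizes and reproducibility

The test suite and the reproduction script run the full pipeline at the
study scale the package targets: 120-month panels, 16 species, 5 GCMs, 80
projection years, and 10,000 Monte Carlo draws by default (tests use
fewer draws where only determinism or degeneracy is being checked; the
delta-method width test uses a 480-month panel). A complete
screening-plus-welfare run takes on the order of seconds.

Every random draw descends from a single integer seed through
stage-partitioned substreams (panel, habitat, Monte Carlo), so adding
draws to one stage does not perturb another; run outputs regenerate
byte-identically from the manifest, and the generator restores the
caller's RNG state.

## 7. Known limitations

* The Stone index uses observed (noisy) shares, so share noise induces a
  small errors-in-regressors bias; it is negligible at the default noise
  level (the recovery tests bound it) but would grow with noisier shares.
* The money-metric monetisation is exact only for proportional bundle
  changes; for non-proportional changes it is a first-order money metric
  (the bisection oracle bounds the agreement used in tests).
* Baseline prices default to the estimation window (2007–2016); the
  published baseline-price table uses a longer 1996–2016 window that the
  package does not attempt to reconstruct.
* The annualization of binned habitat changes is a modelling choice; bin
  definitions only constrain the trajectory at midpoints.
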