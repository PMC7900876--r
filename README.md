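# fishclim

Economic assessment of climate-driven shifts in thermally available habitat
for US commercial fisheries: habitat-proportional landings projections with
present-value screening, a two-stage **inverse almost ideal demand system
(IAIDS)** estimated under utility-theoretic restrictions, expenditure and
price forecasting, and distance-function consumer-welfare measurement. The
package is aimed at fisheries and resource economists who want a tested,
fully reproducible implementation of this pipeline; a seeded synthetic-data
generator emulates the monthly landings panel and the 5-GCM habitat
projection ensemble so every stage runs without proprietary data.

## What it computes

**Screening.** For each species-region, the fractional change in thermal
habitat per 20-year bin and GCM, Δh = (H(bin) − H(B0))/H(B0), is ensemble
averaged across GCMs (mean of ratios), anchored at bin midpoints, and
interpolated to annual multipliers m_t = 1 + Δh(t). Landings scale
proportionally, `landings_t = baseline × m_t`, and changes are valued at a
3% real discount rate against the annuity value of the 2007–2016 baseline
(annuity factor Σ<sub>k=1..80</sub> 1.03<sup>−k</sup> = 30.2008).
Confidence intervals come from a Monte Carlo that bootstraps the baseline
years and samples GCMs uniformly.

**Demand.** Expenditure shares follow the LA-IAIDS share equations

&nbsp;&nbsp;w<sub>i</sub> = α<sub>i</sub> + Σ<sub>j</sub> γ<sub>ij</sub> ln q<sub>j</sub> − β<sub>i</sub> ln Q,

with the Stone index ln Q = Σ w<sub>j</sub> ln q<sub>j</sub>, estimated by
iterated SUR/FGLS with adding-up, homogeneity and symmetry imposed exactly
(12 free parameters per 4-good system). Uncompensated flexibilities
f<sub>ij</sub> = −δ<sub>ij</sub> + (γ<sub>ij</sub> − β<sub>i</sub>w̄<sub>j</sub>)/w̄<sub>i</sub>
are reported with delta-method intervals, alongside the elasticities
(entries of F<sup>−1</sup>).

**Forecast and welfare.** Total expenditures grow with GDP through an
income elasticity of 0.11, E_t = E<sub>anchor</sub>(GDP_t/GDP<sub>anchor</sub>)<sup>0.11</sup>;
the two-stage budget allocation turns them into species expenditures and
implied ex-vessel prices. Welfare uses the translog distance function
ln D(q, u) = a(q) − u·b(q) benchmarked at baseline harvests, monetised as
W_t = E_t (1 − 1/D), with net present values per fishery group.

## Worked example

```r
library(fishclim)

cfg <- run_config(synthetic = synthetic_config(seed = 42), n_draws = 5000)
run_screening(cfg)
#> Screening analysis: 16 species, RCP4.5 & RCP8.5
#>       rcp             region baseline_mean delta_pv pct_change
#> 1  RCP4.5         East Coast          1038   1036.3     3.3043
#> ...
#> 7  RCP4.5              Total          3080   1090.7     1.1728
#> ...
#> 14 RCP8.5              Total          3080    645.2     0.6937

run_welfare(cfg)
#> Two-stage IAIDS welfare analysis
#> Own-price elasticities (stage 1):
#>             group elasticity elas_lower elas_upper
#> 1 High-value fish      -1.92      -2.34      -1.50
#> 2    Lobster/crab      -1.35      -1.51      -1.19
#> 3  Low-value fish      -1.79      -2.21      -1.37
#> 4  Shrimp/mollusk      -1.42      -1.56      -1.28
#> Welfare NPV (MM 2018 US$):
#>       rcp           group     npv
#> ...
#> 7  RCP8.5    Lobster/crab -1372.4
#> 9  RCP8.5  Shrimp/mollusk  1496.6
#> 10 RCP8.5           total  -229.6
```

The screening table reads like the published regional screening: baseline
mean annual revenue (MM 2018 US$), the change in discounted 2021–2100
revenue versus holding landings at baseline, and that change as a share of
the baseline's annuity value. In this synthetic world (whose habitat trends
mirror the published ensemble-mean harvest changes) the Gulf gains under
both scenarios while the Pacific regions lose, and the lobster/crab group
bears the largest welfare loss under RCP 8.5 while shrimp/mollusk gains —
the qualitative pattern of the source analysis. All own-price elasticities
are negative, as inverse-demand theory requires.

The expenditure forecast on the packaged GDP path:

```r
ep <- forecast_expenditures(packaged_gdp_path())
#> E(2050) = 3301.5   E(2100) = 3587.9   growth vs 2007-2016 = 16.5 %
```

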