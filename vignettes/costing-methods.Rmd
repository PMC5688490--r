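---
title: "Methods: ingredients-based MNCH costing and translog factor shares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ingredients-based MNCH costing and translog factor shares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costkit)
```

# The costing model

costkit estimates the financial cost of delivering a package of maternal,
newborn and child health interventions. The model is deliberately simple and
transparent — an ingredients-based (quantities × prices) build-up, annual
time steps, constant USD:

1. **Services.** For every (intervention, population group, year):
   `services = population × need_fraction × coverage_fraction`. The need
   fraction is the share of the target population requiring the intervention
   in that year and may exceed 1 where a person can present more than one
   case per year (diarrhoea, malaria). Coverage is *effective* coverage —
   the fraction of those in need actually served — and is bounded by 1.
   Service counts are kept as reals; rounding is a formatting concern.

2. **Unit cost per case**, per delivery channel, mixed by channel fractions:
   - *Drugs and supplies*: Σ unit price × units per case × fraction of
     clients receiving the item.
   - *Labor*: Σ minutes per visit × visits × the cadre's cost per minute.
     Cost per minute divides annual remuneration (wages + benefits) by
     *productive* minutes — working days × minutes per day × utilization —
     so a cadre that spends half its paid time delivering services costs
     twice as much per delivered minute. This is the convention under which
     low utilization raises unit costs, which is what a planner needs to see.
   - *Other-direct and indirect overheads*: outpatient visits and inpatient
     days per case are priced at the country's "hotel" cost per visit/day
     (all costs except drugs and laboratory), then multiplied by the
     other-direct-cost and indirect-cost factor shares. Health-centre shares
     apply to outpatient visits and hospital shares to inpatient days, in
     all cases. The personnel and consumables portions of the hotel cost are
     deliberately *not* added: those inputs are already ingredient-costed,
     and adding them again would double count. The engine consumes only the
     ODC and indirect shares — a property the test suite asserts directly.

3. **Intervention and total cost.** Each unit-cost component is scaled by
   the service count and summed over population groups; the scenario total
   adds above-facility program costs in six categories (program management,
   research, monitoring & evaluation, communication/media/outreach,
   above-facility training, infrastructure & equipment), each either a fixed
   annual amount or a markup fraction on the facility-level total. Markups
   apply to the full facility-level cost including drugs — the specification
   of "over and above the facility-level costs" admits no exclusion.

Facility-level costs are therefore exactly linear in every price, wage,
hotel cost, population count, need and coverage fraction, and the `total`
column is the exact sum of the five components; both properties are tested
as invariants (conservation to 1e-9 relative, doubling of all prices
doubling every facility component exactly).

In exports, other-direct costs are labelled "other recurrent costs" and
indirect costs "capital costs", matching the reporting vocabulary of MNCH
costing tools; the CSV carries a header note with this mapping.

# The translog factor-share estimator

The hotel cost of a visit or bed-day bundles four factors: personnel,
consumables (excluding drugs and laboratory costs), other direct costs
(nonconsumables and facility training) and indirect costs (capital, support
personnel, maintenance/utilities, supervision/management). To split out the
ODC and indirect portions, a four-factor translog cost function is estimated
on facility-level data, separately for hospitals (applied to inpatient days)
and health centres (applied to outpatient visits):

$$\ln\frac{C}{p_4} = \beta_0 + \sum_{i=1}^{3}\beta_i \ln\tilde p_i
  + \tfrac12 \sum_{i,j}\gamma_{ij}\ln\tilde p_i \ln\tilde p_j
  + \delta_y \ln y, \qquad \tilde p_i = p_i/p_4$$

Dividing cost and prices by the indirect-cost price $p_4$ (the numeraire)
imposes linear homogeneity in prices; symmetry $\gamma_{ij}=\gamma_{ji}$
holds by construction of the design (diagonal regressors
$\tfrac12\ln^2\tilde p_i$, off-diagonal products once). A single
$\ln y$ output term makes the default specification homothetic;
price–output interactions are available via
`price_output_interaction = TRUE` but off by default, because share
estimates at the mean are insensitive to them in the well-conditioned
designs this estimator is meant for.

By Shephard's lemma the cost share of factor $i$ is
$s_i = \beta_i + \sum_j \gamma_{ij}\ln\tilde p_j$, evaluated at the sample
mean of the log normalized prices — the standard evaluation point when none
is dictated by the application — and $s_4 = 1-\sum_i s_i$, so the four
shares sum to one exactly by construction. Because each share is a linear
combination of coefficients, delta-method standard errors are exact linear
forms in the coefficient covariance. That covariance is the
heteroskedasticity-robust Huber/White sandwich with HC1 small-sample
scaling, $\frac{n}{n-k}(X'X)^{-1}X'\mathrm{diag}(e^2)X(X'X)^{-1}$ — the
common default of that estimator family. The implementation is the explicit
formula (it operates on a bare design matrix and residual vector); the test
suite cross-checks it against both a brute-force meat summation and
`sandwich::vcovHC(type = "HC1")`.

Two genuinely open design points, and how they are resolved here:

- *Cost function vs. share system.* "Estimating a factor-shares equation
  using a translog cost function" can mean differentiating a fitted cost
  function or estimating the share equations directly. The default is the
  fitted-cost-function route (`fit_translog` + `derive_shares`); a direct
  share-system estimator (`fit_share_system`, per-equation OLS of observed
  expenditure shares on log normalized prices, numeraire equation dropped
  and recovered by adding-up) is provided for sensitivity analysis. It
  needs per-factor expenditure columns, which the facility CSV contract
  treats as optional. Neither route claims to replicate the published
  estimates, whose underlying dataset is not public.
- *The published health-centre shares sum to 96.9%* as printed, presumably
  from rounding. They are shipped verbatim (`default_factor_shares`,
  `shares_report`); `renormalize = TRUE` rescales a row to exactly 100%.
  Renormalization is not the default because the engine consumes only the
  ODC and indirect entries, whose printed values are the published claim.

Degenerate inputs are rejected rather than patched: non-positive prices,
fewer records than regressors + 5, and rank-deficient designs (e.g. all
facilities sharing one price vector) raise typed errors. Estimation
requires no iteration — the fit is ordinary least squares via QR — so there
are no initialisation or convergence knobs.

# The synthetic-data generators

Two generators make every module testable without external databases, which
for this class of tool are distributed inside country-planning software and
are not openly downloadable.

**Toy-country scenario** (`generate_country_fixture`): three population
groups (pregnancies, births, children under five, 0.4–1.8 M persons with
1–3%/yr growth), ten interventions with one or two delivery channels, 1–4
drug/supply lines each (unit prices 0.05–5 USD), provider time for up to two
of three cadres (salaries 3 000–24 000 USD/yr, 230 working days, 480
min/day, utilization 0.5–0.9), 0.5–4 outpatient visits and occasional
inpatient days per case, hotel costs of 1–5 USD per visit and 5–20 USD per
bed-day, the packaged default factor shares, and a nonzero program-cost
specification mixing fixed amounts and markups. Coverage ramps linearly
from a 20–50% start to a 60–95% endpoint across the year range — the
standard scale-up shape in strategic planning. These magnitudes are chosen
to be realistic for a low-/middle-income setting, but the generator makes
no claim of epidemiological realism: need fractions are arbitrary, there is
no seasonality, no supply constraint, no price inflation. Passing tests
demonstrate the arithmetic and its invariants, not country-level validity.

**Facility cost records** (`simulate_facility_costs`): log factor prices
i.i.d. uniform on [−0.5, 0.5] (a ±65% price spread around 1, keeping the
translog design well conditioned), output lognormal around 5 000
services/yr, and log total cost from a translog whose first-order
coefficients equal the configured true shares. Since the mean log
normalized price is 0, the implied shares at the evaluation point are
exactly the configured ones. The second-order block defaults to small but
nonzero entries (±0.01–0.02) so the shares genuinely vary with prices and
the cost-function and share-system estimators are distinguishable; its
columns sum to zero, keeping simulated shares safely inside (0, 1). Noise
is multiplicative lognormal (σ = 0.05 by default) because cost data are
positive and right-skewed. Per-factor expenditures are the implied shares
times total cost, so records satisfy the adding-up identity by
construction. Default true shares echo the packaged default table (the
health-centre row renormalized to sum to 1, as a data-generating process
requires).

Identical seeds give byte-identical files: every CSV is written with a
fixed shortest-round-trip number format, so `load(write(x))` reproduces
`x` field-for-field and bit-exactly.

# Problem sizes and numerical choices

The test suite runs at sizes chosen to make the statistical checks sharp
yet quick: parameter recovery at n = 1 000 facilities (each share lands
within ±0.02 of truth; typical error ≈ 0.005), a 200-replicate Monte-Carlo
at n = 500 (mean absolute share bias < 0.01; 95% delta-method intervals
cover the truth in ≥ 90% of replicates), and 50 random small scenarios
(≤ 5 interventions) for brute-force oracle equivalence at 1e-9 relative
tolerance. The noise-free limit is checked exactly: adjusted R² = 1 within
1e-9 and coefficients recovered to 1e-8.

Other numerical conventions: fractions are stored as [0, 1] proportions
(readers accept a percent dialect flag); years are annual steps with no
interpolation unless the `interpolate_years` helper is invoked explicitly;
currency is constant USD with no discounting (cost streams are compared
undiscounted, as is usual when the planning horizon is short and effects
are reported per life saved); channel mix fractions are constant per
intervention, must sum to 1 within 1e-9, and "percent of clients receiving"
is capped at 1, with repetition expressed through units per case. Negative
inputs are rejected, never clamped. League-table ties break
lexicographically by intervention id, and dominated entries (positive
incremental cost, non-positive incremental lives saved) are flagged and
listed last rather than dropped — silently losing rows is worse than an
awkward ranking.

# Limitations

- The packaged factor shares were estimated on voluntary-medical-male-
  circumcision facility data, not MNCH services; portability rests on the
  assumption that labor utilization patterns are comparable. Users with
  country facility-cost data can re-estimate via `fit_translog`.
- Lives saved are an external input; the package computes no mortality or
  morbidity impact, no DALYs, and applies no discounting of effects.
- No bottleneck/constraint modelling, supply-chain markups, or
  health-system strengthening costs; program costs are a six-category
  amount-or-markup abstraction.
- Country fixed effects, case-mix and scale/scope economies are outside the
  default translog specification.
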