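---
title: "Modelling birth-risk distributions from contraceptive prevalence and method-mix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling birth-risk distributions from contraceptive prevalence and method-mix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birthrisk)
```

## The problem

Births carry very different under-five mortality risk depending on their
demographic circumstances: the mother's age at birth (under 18 or 35 and
older), the birth order (first births and births of order five or more), and
the time elapsed since the next-oldest sibling (intervals under 18 months are
the riskiest). Family-planning programs shift not only the *number* of births
but their *distribution* across these categories, and the size and direction
of that shift depends on which contraceptive methods drive the change:
permanent methods (tubal ligation, vasectomy) limit completed fertility but do
nothing for spacing, while short-acting methods are often used to space.

`birthrisk` implements an ecologic analysis of this relationship. The unit of
analysis is a national survey. From individual birth histories it computes,
per survey, the percent of recent births in each risk category, the modern
contraceptive prevalence rate (mCPR, percent of women 15–49 in union using a
modern method), and the method-mix (the percent of modern users on permanent
methods and on long-acting reversibles, IUD/implant). It then models each
category's percent as log-linear in those covariates, with a country random
intercept, and uses the fitted models to project the birth-risk distribution
under method-specific mCPR scale-up scenarios.

## Risk classification

Three dimensions partition births (all intervals half-open `[lo, hi)`):

* **spacing** (births of order ≥ 2 only): `<18mo`, `18-23mo`, `24-35mo`,
  `36+mo`;
* **mothers_age** (completed years at birth): `<18`, `18-34`, `35+`;
* **parity**: `first`, `2-4`, `5+`.

The half-open convention is what makes each dimension's categories disjoint
and exhaustive: an interval of exactly 24 months is "24–35 months", and a
mother of completed age 35 is "35+". Spacing percentages are computed among
births of order ≥ 2 (a first birth has no preceding interval), so the spacing
row sums to 100 like the other two. Classification windows cover the
`window_months` (default 36) months up to and including the survey month,
with dates in DHS century-month code (months since January 1900), which keeps
all calendar arithmetic in integers.

The package reads two delimited text tables, `women.csv` (one row per woman:
age, union status, current method among ten enumerated codes, optional
sampling weight defaulting to 1) and `births.csv` (one dated birth per row).
Records violating the schema invariants — an interval on a first birth, a
non-increasing birth date within a woman — are rejected with the field named.

The period total fertility rate is computed over the same window:
`TFR = 5 × Σ ASFR_g` over the seven 5-year age groups 15–19 … 45–49, with
each group's age-specific fertility rate taken as window births to mothers of
that (completed) age group divided by woman-years of exposure. Exposure is
reconstructed from age at survey in completed years — a woman aged `a`
contributes one year at each of `a`, `a-1`, `a-2` for a 3-year window —
which is exact for cohorts whose birthdays align with the survey month and
accurate to a few percent otherwise (the approximation concentrates at the
15–19 and 45–49 boundaries).

## The models

For each category, with `p` the category percent in a survey from country
*i*, three nested specifications are fit independently:

* **m1**: `log p = β0 + β1·mCPR` by ordinary least squares;
* **m2**: `log p = β0 + β1·mCPR + β2·%permanent + β3·%LARC` by OLS;
* **m3**: the m2 mean structure plus a country random intercept
  `b_i ~ N(0, τ²)` and residual `ε ~ N(0, σ²)`.

The response is the natural log of the *percent* (0–100 scale) rather than
the proportion; the two differ only in the intercept and the downstream
renormalization makes the choice invisible. Covariates are stored per
percentage point; `report_per10()` provides the conventional
per-10-point display (estimates and standard errors ×10, t and p unchanged).

A category with zero observed births in a survey would make the log response
infinite. The default `zero_rule = "continuity"` substitutes half a birth,
i.e. percent `100 × 0.5 / n_births_window`, before logging; `"drop"` and
`"error"` are available. Surveys with no window births at all are dropped for
that dimension. The continuity rule perturbs nothing when cells are nonzero,
and keeps rare small-survey zeros from dominating the fit.

### REML estimation

The m3 model is estimated by restricted maximum likelihood. Writing
`λ = τ²/σ²`, the marginal covariance is `σ²(I + λZZ')` with `ZZ'`
block-diagonal by country, so each block inverts in closed form
(`(I + λJ)⁻¹ = I − λ/(1 + n_i λ) J`). For fixed `λ` the coefficients are
generalized least squares and `σ²` has a closed-form REML estimate, leaving a
one-dimensional criterion in `λ`. That criterion is scanned on a 50-point
log-spaced grid over `λ ∈ [10⁻⁸, 10³]`, refined with a bounded scalar search
(tolerance 10⁻⁹ on `log λ`), and compared against the boundary `λ = 0`; when
the boundary is at least as good the fit collapses *exactly* to OLS rather
than to within optimizer tolerance. The procedure is deterministic and needs
no starting values or seeds. REML (rather than ML) is used because with ~4
fixed effects on ~200 surveys the ML variance components would be noticeably
biased downward; this is also what makes the empirical-Bayes step standard.

Country effects are recovered as empirical-Bayes best linear unbiased
predictors: for country *i* with `n_i` surveys and mean fixed-effect residual
`r̄_i`,

`b̂_i = n_i τ̂² / (n_i τ̂² + σ̂²) · r̄_i`,

so a country with four surveys and `τ̂² = σ̂²` keeps 80% of its mean
residual, and countries with little data are shrunk towards the global line.

### Inference conventions

Wald t tests are reported with `df = n − p` for the OLS variants. For m3 the
reference distribution is not settled in the mixed-model literature; the
package uses `df = n − p − (m_eff − 1)`, floored at 1, where `m_eff` is the
number of countries when `τ̂² > 0` and 1 at the boundary (no effective
country-level parameters remain there). This containment-style convention is
conservative relative to `n − p`; with ~200 surveys and ~70 countries the
two differ little in practice, and simulation (see the test suite) puts the
95% interval's coverage for the mCPR slope at its nominal level. Models 1–2
deliberately make no adjustment for repeated surveys within a country — they
are the "average across surveys" comparators that m3 improves on.

## Prediction and scenarios

`predict_distribution()` evaluates every category's fitted model at given
covariates, adds the country's BLUP (or a fallback: zero, or the average
effect of the country's region from a `country_id → region` table),
exponentiates, and rescales within each dimension so the predicted
percentages cover 100% of births. Because of that renormalization, adding any
constant to all of a dimension's intercepts — or an identical random effect
to every category — cancels; only *relative* category effects matter.

`apply_scenario()` implements a method-specific scale-up: an increase of Δ
percentage points of mCPR (default 10, interpreted as points, not relative
percent) allocated wholly to one method class. Scenario A targets permanent
methods, B long-acting reversibles, C short-term modern methods. The update
works in user-shares of all women: with baseline mCPR `m` and permanent share
`s` of users, permanent users are `m·s/100` points of mCPR; the Δ is added to
the target class's user-share and the mix re-expressed over the new base
`m + Δ`. Existing users do not switch methods, so total modern use is
conserved by construction. A baseline of 33% becomes 43% under any scenario —
only the mix differs.

## The synthetic-data generators

No public individual-level data ships with the package, so both levels of the
pipeline are exercised by seeded generators whose truth is known.

**Survey panels** (`generate_panel()`): per survey, mCPR uniform on
[5, 75]%, a Dirichlet(2, 2, 6) composition for the
(permanent, LARC, short-term) mix — short-term dominant, as in most
low- and middle-income settings — and the category percent emitted exactly
from the log-linear law `exp(β0 + β1·mCPR + β2·%perm + β3·%LARC + b_i + ε)`
with `b_i ~ N(0, τ² = 0.04)` shared within country and
`ε ~ N(0, σ² = 0.01)`. The default coefficient table
(`default_truth_betas()`) uses per-10-point mCPR slopes typical of
multi-survey compilations (−0.14 for parity 5+, −0.06 for mothers 35+, +0.09
for first births, +0.07 for 36+-month spacing, near-zero for births to
mothers under 18), with intercepts calibrated so the implied distribution at
mCPR 29%, 20% permanent, 20% LARC matches a typical all-survey average.
Method-mix slopes are chosen so that permanent methods associate with
relatively more short-spaced and high-parity births — strongly enough that a
permanent-method scale-up gives the smallest reduction in parity-5+ births
among the three scenarios, but not so strongly as to reverse the mCPR effect.
An optional flag renormalizes the emitted percentages per dimension, which
matches what observed tables look like but breaks the exact per-category
data law; it is off by default so estimators can be checked against the
generating coefficients.

**Birth histories** (`generate_birth_histories()`): women's ages uniform on
15–49, union probability 0.7, modern use 0.35 among in-union women (so the
implied mCPR is 35%), and a method distribution implying 15% permanent / 20%
LARC. Fertility is a monthly Bernoulli process with hazard `ASFR_g/12` in the
woman's current age group (default schedule summing to a TFR of 4.1), which
gives the implied ASFRs and TFR exact closed forms. The simplification to
note: there is no postpartum infecundity or minimum interval, so simulated
intervals can be unrealistically short and the spacing distribution is
geometric-like rather than humped at 24–36 months. A `fixed_interval_months`
mode forces every interval to a constant for degenerate-category tests. All
randomness flows from a single seed, with deterministic per-survey
sub-streams, so equal seeds give byte-identical CSVs.

Passing tests on these generators demonstrates that the estimators recover
the parameters of the model they assume, at realistic scale (207 surveys, 71
countries, 200 replicates for the recovery study; 500–5,000 women per survey
for the history pipeline — sizes chosen to pin Monte-Carlo error well below
the tolerances tested). They do not demonstrate robustness to what real
survey data adds: sampling design and weights, displacement and heaping of
reported birth dates, covariate measurement error, or joint risk categories
(e.g. short-spaced births to adolescent mothers), none of which the ecologic
design addresses.

## Numerical and design notes

* Interval bounds half-open everywhere; boundary months 18/24/36 and
  boundary ages 17/18/34/35 are covered explicitly in the tests.
* The mCPR denominator is women 15–49 *in union*; surveys differing in this
  convention should be harmonised upstream.
* Weights: a `sample_weight` column is honoured in aggregation (default 1);
  the regressions are unweighted because the unit of analysis is the survey.
* The REML criterion is unimodal in `log λ` in every panel we have examined,
  but the grid-then-refine scheme does not rely on that.
* Predictions are point predictions; no interval is attached to the
  renormalized distribution (the delta-method variance of a renormalized
  composition is not implemented).
* The scenario update assumes no method switching among existing users;
  other allocations (proportional reallocation, say) would need only a
  different `apply_scenario()`.
* Mortality consequences of the redistributed births are out of scope: the
  package stops at the predicted distribution.

## A worked example

```{r example, eval = FALSE}
sim <- generate_panel(panel_params(n_countries = 40, surveys_per_country = 4,
                                   seed = 808))
fits <- fit_all_categories(sim$aggregates, variants = "m3")
summary(fits$fits$m3$parity$`5+`)

base <- data.frame(country_id = "C001", mcpr_pct = 33,
                   pct_permanent = 10, pct_larc = 15)
run_scenarios(fits, base)
```

The same pipeline is available from the shell through
`birthrisk_cli(c("pipeline", "--config", "demo.cfg"))`; see
`inst/extdata/demo.cfg` for the configuration keys.
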