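---
title: "Resilience indicator traits and their genetic parameters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resilience indicator traits and their genetic parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `resilayer`, the
assumptions behind them, the synthetic-data generator that stands in for
proprietary breeding data, and the numerical and design choices made
where several options were defensible.

## From egg collections to traits

Raw data are egg *collections*: a unit (an individually housed purebred
hen, or a collective cage of 6–8 crossbred paternal half-sibs), a date,
and an egg count covering the days since the previous collection (1–4
days).  Trait construction proceeds in four steps.

**Daily spreading.**  Each collection is divided evenly over the days of
the half-open interval (previous date, collection date].  The half-open
convention conserves totals and counts no day twice; the first record of
a unit spreads back to the housing start when that is known, otherwise
it covers its own date only.  For individually recorded hens a
collection implying three or more eggs on one day is biologically
impossible and the record is discarded *before* spreading; two-egg days
are retained, because consecutive collections taken at different times
of day can legitimately attribute two eggs to one date.  Cage records
are never filtered this way — a cage of six can obviously exceed three
eggs a day.

**Weekly production.**  Daily values are summed over the seven days of
each age week (`week = floor(age_days / 7) + 1` from the hatch date).  A
completeness fraction (default 1.0, i.e. all seven days covered) guards
against partially observed boundary weeks entering the deviation series;
it is configurable because a laxer 0.5 recovers a few extra weeks at the
cost of noisier sums.  Cage totals are divided by the average number of
hens alive in the cage that week, giving eggs per hen per week.

**Batch deviations.**  The "undisturbed" expectation of a hen is the
average of her batch (contemporary group): total eggs laid in the
batch-week divided by hens alive, cages contributing hen-weighted.
Hens are counted as alive at week start (death occurs at the start of
the recorded death week); the alternative mid-week convention is
available but changes little.  Deviations are the unit's weekly per-hen
value minus this average; hen-weighted deviations therefore sum to zero
within a complete batch-week, which the test suite asserts.

**Indicators.**  Per unit, over the recording range (weeks 25–83):

* `EP` — the summed weekly values; missing weeks contribute zero, so
  death truncates the sum, and the survival-class fixed effect in the
  models absorbs the consequences.
* `LNVAR` — natural log of the n−1 sample variance of the deviations.
* `SKEW` — the moment skewness `m3 / s^3` (third central moment over the
  cube of the n−1 SD), computed through the `e1071` skewness function
  (its default type-3 estimator).
* `AUTO-R` — the lag-one autocorrelation in the `acf` convention
  (overall mean, denominator over all T terms); only consecutive-week
  pairs enter the numerator, so a gap in the series breaks pairs rather
  than correlating values two weeks apart.

All three indicators require at least `min_weeks = 10` deviations
(configurable; the data do not dictate a value, and 10 keeps the
estimators out of their worst small-sample regime while losing few
units) and are undefined for zero-variance series.  Outliers beyond the
population mean ± 4 SD are set to missing per indicator — a unit losing
its LNVAR keeps its SKEW, AUTO-R and EP.  The filter is single-pass:
mean and SD come from the pre-filter values and are not recomputed, so
re-running the filter on its own output can, by design, remove a little
more (the moments shift once extremes are gone); the single pass matches
the stated one-shot rule.

## The mixed models

Purebred records follow an animal model,

    y = mu + HatchLoc + SurvClass + a + e,

with `a ~ N(0, A sigma2_ap)` over the pedigree and a single residual
variance.  Crossbred cage means follow a sire model,

    y = mu + HatchLoc + SurvClass + MaternalLine + s + e,

with `var(s) = sigma2_ac / 4` and a separate residual variance per cage
size (the cage-mean residual variance shrinks with cage size, and the
two sizes present in a line differ enough to matter).  `SurvClass` bins
lifespan into 4-week classes spanning 24–112 weeks of age (22 classes),
capturing survival effects without assuming linearity.  For cages, which
contain several death times, the class is taken from the cage's average
lifespan — an interpretation, flagged as such, since a cage-level
lifespan is not otherwise defined.

The purebred–crossbred analysis treats the two contexts as two traits:
animal effect on purebred records, sire effect on cage records, jointly
normal with covariance `A x G0` where
`G0 = [[sigma2_ap, r_pc sigma_ap sigma_sc], [., sigma2_sc]]` and
`sigma2_sc = sigma2_ac / 4`.  No residual covariance is fitted (a hen is
present in only one environment).  Trait-pair analyses within a
population estimate both the genetic and the residual covariance, the
latter because both traits are measured on the same units; crossbred
trait pairs are fitted one cage size at a time.

Crossbred cages enter the pedigree through their sire only — dam lines
are not individually pedigreed — and records are weighted equally
regardless of within-cage mortality; mortality acts through the
denominator of the weekly cage values and through `SurvClass`.

## REML machinery

The restricted likelihood is evaluated through the mixed-model-equations
identity `-2l = (n-p) log 2pi + log|R| + log|G| + log|C| + y'Py`, with
`C` the full MME coefficient matrix held as a weighted sum of fixed
sparse components (residual-stratum cross-products and padded
`G`-inverse blocks), so each evaluation reduces to refreshing one sparse
Cholesky factorisation whose symbolic analysis is reused.  `A^-1` comes
from Henderson's rules with inbreeding (Meuwissen–Luo recursion for F);
pedigrees are pruned to recorded individuals and their ancestors, and
recordless single-offspring base parents are absorbed into the
offspring's Mendelian-sampling term — both operations leave the
likelihood unchanged and shrink the equations several-fold.

Optimisation is quasi-Newton/Nelder–Mead on an unconstrained scale: log
variances (floored at `1e-10` of the phenotypic variance), correlations
through `atanh` clipped to ±0.999, and for the rank-1 genetic structure
a single-factor Cholesky `G0 = lambda lambda'` fitted through the
reduced system `W = [X, lambda1 Z1 + lambda2 Z2]`, `w ~ N(0, A)` — the
exact formulation for a singular `G0`, used for the `r = 1` constraint.
Convergence requires the optimizer to settle with a small numerical
gradient; non-convergence flags the result rather than raising.
Standard errors come from the observed information (numerical Hessian of
the restricted likelihood on the natural scale) at the optimum, and
derived quantities (heritabilities, correlations) get delta-method SEs
from it; both are documented as asymptotic approximations.  The sparse
path is verified against a dense multivariate-normal likelihood oracle
to 1e-6 at arbitrary parameter values, and against closed-form ANOVA
estimators on balanced designs.

## Heritability scales

Purebred: `h2 = sigma2_a / (sigma2_a + sigma2_e)`.  Crossbred cage
means: the cage record is the average of `n` half-sibs, so
`sigma2_P* = sigma2_s + n sigma2_e` reconstructs the individual-scale
phenotypic variance and `h2 = 4 sigma2_s / sigma2_P*`.  For LNVAR the
cage value is the log-variance of the pooled deviations, *not* the mean
of the members' individual LNVARs, so the `n`-rescaling does not apply
and `h2 = 4 sigma2_s / (sigma2_s + sigma2_e)` is used instead.  At
`n = 1` the pooled formula collapses to the purebred one — a consistency
limit the tests assert.  One reference-table quirk: for the second line
the published residual-variance rows are labelled as cages of 6 and 7
while that line's cages held 7 and 8 hens; internal consistency of the
derived heritabilities shows the labels mean "smaller/larger cage", and
the package stores them that way (`cage_small`, `cage_large`).

## Significance testing

`LR = 2 (l_full - l_constrained)`, clamped at zero with a warning if
numerical noise puts the constrained fit marginally higher.  Tests of a
parameter on the boundary of its space — a variance against 0, a
correlation against 1 (via the rank-1 structure) — use the 50:50
mixture of chi-squared(0) and chi-squared(1); its 5% threshold is
2.706, and at `LR = 0` the mixture's point mass gives `p = 0.5`.  The
test of a correlation against 0 is interior and uses chi-squared(1).
Under a simulated true null the boundary test holds its nominal 5% size
within Monte-Carlo error (asserted over 500 replicates).

## The synthetic-data generator

Two fidelity levels, because they serve different purposes.

**Direct mode** draws records from the mixed models themselves:
breeding values recursed down the pedigree (offspring = parent average +
Mendelian sampling with variance `k sigma2`, `k` reflecting parental
inbreeding and unknown parents), fixed-effect level values drawn once
per level and recorded.  On this scale the REML targets are exact, so
parameter recovery can be tested quantitatively: the acceptance runs
recover the purebred LNVAR heritability (truth 0.096 from generating
components 0.065/0.609) and the purebred–crossbred EP correlation
(truth 0.31) at the design scales stated in the README.

**Longitudinal mode** generates the raw records the trait-construction
code expects: batch lay curves (rapid rise to a peak near 30 weeks, slow
decline; clamped to [0, 7] eggs/week — seven days at the biological
one-egg-per-day limit, with 2-egg days arising only as
collection-interval artifacts); hen-level mean deviation, log innovation
variance, and lag-one autocorrelation each carrying additive genetic
structure down the pedigree (the autocorrelation on a scaled-logit link
to keep it inside (−1, 1) — no generative model is dictated by the
science, any support-preserving link is acceptable); AR(1) weekly
deviations; perturbation events at a weekly batch rate with
exponentially distributed depths and individual lognormal recovery
rates; geometric mortality; weekly totals disaggregated into collection
records at random 1–4 day intervals with cumulative rounding so integer
egg counts conserve totals; and an optional fraction of corrupted
purebred records (≥ 3 eggs/day) to exercise the discard filter.

One modelling point worth making explicit: because the indicators are
computed from deviations *from the batch average*, a perturbation that
hits every hen in a batch equally is absorbed by the contemporary-group
mean and leaves the indicators untouched.  Events therefore strike a
susceptible subset of each batch (default probability 0.5 per unit,
exposure shared cage-wide), which is what produces the negative skew and
inflated variance of affected hens.  This mirrors the real caveat that a
batch-wide disturbance lowers the batch average itself and masks
individual deviations.

Longitudinal defaults (innovation-variance baseline `mu_v = -1`,
additive SDs 0.35 eggs/week for the mean level, 0.22 for the log
innovation variance, 0.30 on the autocorrelation link, perturbation
rate 0.03/week with mean depth 1.5 eggs and median recovery 0.5/week,
weekly mortality 0.1–0.2%) were chosen once to give phenotypic means,
SDs and removal fractions in the range reported for commercial layer
lines, and are not tuned further.  The mapping from these process
parameters to indicator-trait heritabilities is nonlinear and is only
checked qualitatively (e.g. between-sire variance of family-mean LNVAR
increases monotonically in the additive SD of the log innovation
variance).  Passing tests on this generator therefore demonstrate that
the pipeline measures what the process puts in — not that real data
follow this process; in particular the generator does not attempt real
lay-curve shapes, country/farm structure, beak-trimming effects, or
social interactions within cages.

## Problem sizes

The test suite and acceptance runs use desk-scale designs chosen to make
Monte-Carlo error small relative to the assertions: 100 sires × 30
offspring (20–60 replicates) for heritability recovery, 200 sires with
30 purebred offspring and 10 cages of 6 (20–45 replicates) for the
purebred–crossbred correlation, 500 replicates of a 15 × 6 balanced
design for the size of the boundary test, and 200-animal random
pedigrees for the relationship-matrix identities.  At these scales a
single correlation estimate still has an SD near 0.16 (genetic sampling
over the finite number of sires compounded by the weakly informed sire
variance), which is why the correlation is asserted on the replicate
mean.

## Known limitations

* SEs are asymptotic (observed information + delta method); for
  variance ratios near boundaries they are rough, as the test suite's
  25%-band sanity check acknowledges.
* The batch average is computed within the unit's own population and
  batch; whether real contemporary groups pool across farms is
  data-dependent and not modelled.
* Weeks recorded after a perturbation-driven production stop but before
  death are included in the deviation series — the records give no way
  to distinguish a stopped layer from a poor one.
* No genomic relationships, genetic groups, permanent-environment or
  social-interaction effects; selection and non-random mating are not
  simulated.
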