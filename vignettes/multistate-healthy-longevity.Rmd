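---
title: "Multi-state frailty dynamics and healthy life expectancy over the life course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state frailty dynamics and healthy life expectancy over the life course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailmslt)
```

## The scientific problem

Healthy longevity in ageing cohorts is usefully summarised not by how long
people live but by how many of their remaining years are spent in good
health. `frailmslt` implements a complete pipeline for this question in
the deficit-accumulation framework: health at each survey wave is scored
by the Rockwood frailty index (FI) over 38 self-reported deficits, coded
into a three-state process — robust (FI $\le 0.10$), frail (FI $> 0.10$),
dead — and modelled as a continuous-time Markov chain whose transition
intensities depend on age, gender, and socioeconomic status (SES) measured
over the life course. A multi-state life table then converts fitted
intensities into total, robust, and frailty life expectancy (LE) for any
covariate profile.

The package targets the data situation of large longitudinal ageing
surveys such as the CLHLS: staggered enrolment, follow-up waves roughly
two to three years apart, living states observed only at waves
(interval censoring), and deaths dated exactly from death certificates.
Because such microdata are access-restricted, the package ships a
calibrated cohort simulator so that every stage — state construction, SES
coding, likelihood, life table, bootstrap — is testable end to end
against known ground truth.

## States and the frailty index

The FI is the mean of the observed deficits, each scored in $[0,1]$.
Deficits with missing values are excluded from numerator and denominator;
if strictly more than 30% of the 38 items are missing (12 or more), the FI
is *incomplete* and the record is excluded, mirroring the usual
missing-FI exclusion rule. The boundary is sharp: 11 of 38 missing
(28.9%) still computes, 12 (31.6%) does not. Death dominates coding, and
no FI is ever computed at a death record.

## SES indices and life-course trajectories

Childhood SES is built from four binary indicators (urban birth, freedom
from childhood hunger, non-agricultural father's occupation, adequate
childhood medical care) and adult SES from six (urban residence, any
schooling, non-agricultural occupation, pension, financial sufficiency,
adequate medical care at 60). Missing indicator cells are multiply
imputed by chained equations, each index using only its own indicators as
predictors; each missing cell is replaced by the mean of `m` imputed
draws (default 100), rounded to the nearest whole number and mapped to
0/1. The chained engine uses logistic conditionals with stochastic
(Bernoulli) draws and a 10-sweep burn-in per imputation — a standard
chained-equations construction; the conditional-model family is a design
choice of this package.

Summed scores are binned into low/medium/high. For the childhood score
(0–4), four equal-width integer bins are $\{0\},\{1\},\{2\},\{3,4\}$; a
three-way split requires merging the top bins, and the package's default
is $\{0\}\to$ low, $\{1\}\to$ medium, $\{2,3,4\}\to$ high, which
reproduces the published prevalence pattern (about 68/21/12%). The adult
score (0–6) uses range terciles $\{0,1\},\{2,3\},\{4,5,6\}$. Both maps
are configurable, and validity requires monotone surjections onto
{low, medium, high}; the equal-width phrasing in the source literature is
ambiguous about the merge, so the default is documented rather than
claimed canonical. The nine life-course trajectories are coded
$3\,\mathrm{child} + \mathrm{adult} + 1$, so low–low $=1$ through
high–high $=9$, supporting the mobility (upward: codes 2, 3, 6; downward:
4, 7, 8) and accumulation-score summaries.

## The three-state model and its likelihood

Each allowed transition $r\to s \in \{1\!\to\!2, 1\!\to\!3, 2\!\to\!1,
2\!\to\!3\}$ has a log-linear intensity

$$q_{rs}(a, x) = \exp\{\beta_0 + \beta_a (a - 65) + \beta_g\,
\mathrm{male} + \textstyle\sum_k \beta_k x_k\},$$

with SES entering as dummies for either the childhood category (2
dummies) or the trajectory (8 dummies); female and the lowest SES level
are the reference. Death is absorbing, so the generator's exponential
reduces to the closed-form exponential of the 2×2 living block, whose
eigenvalues are always real; the package evaluates it in a vectorised,
overflow-safe spectral form (both eigenvalues are non-positive).

The panel likelihood is the standard one for interval-censored multistate
data: a living state observed at the next wave contributes the interval
transition probability; an exactly dated death contributes
$\sum_{r\in\{1,2\}} P_{s r}(t_1, t_d)\, q_{r3}(t_d^-)$, summing out the
unobserved pre-death state. Age is a continuous time-varying covariate;
the package holds intensities piecewise-constant on a 0.1-year age
lattice *within* each observation interval, so the likelihood, the
simulator, the annual transition matrices, and the life-table integration
all share a single age discretisation. (Freezing the covariate at the
interval's left endpoint — the other common convention — is available via
`age_update = "interval"`; the shared-lattice default was chosen because
it makes the estimator exactly consistent with the generating process and
removes the intercept bias the left-endpoint treatment induces over
multi-year waves.) The exact-death intensity is evaluated at the left
endpoint of the final lattice substep.

Estimation is bounded quasi-Newton (L-BFGS-B) with an analytic score:
because every coefficient enters the substep matrices only through its
transition's rate, the full gradient is accumulated in one
forward–backward pass over the lattice at a cost independent of the
number of parameters. The optimisation is internally preconditioned by
standardising the age and dummy covariates (the intercept/age-slope
collinearity otherwise cripples quasi-Newton steps); estimates and the
covariance — the inverse observed information, from finite differences of
the analytic gradient — are mapped back to the natural parametrisation.
Intercepts are bounded at ±20 on the log scale and other coefficients at
±5; a fit touching a bound is flagged rather than trusted. Because
published results are reported per gender, fits are gender-stratified by
default, with a pooled gender-main-effect fit available (and used for
parameter-recovery checks, where the gender coefficient itself must be
recovered).

## Life tables, annual probabilities, and uncertainty

Annual transition probabilities are products of ten 0.1-year substep
exponentials. State occupancy propagates $\pi(x+h) = \pi(x)\,
e^{Q(x)h}$ from the index age to an assumed maximum age of 130 on the
same grid; LE integrates occupancy with the left-endpoint rectangle
("step") rule, the convention of the published workflow, with a trapezoid
option behind a flag. Robust LE + frailty LE = total LE holds exactly by
construction. The step rule's error is first order in $h$ (about 0.05
years at $h=0.1$ in the analytic single-state benchmark), which the test
suite verifies together with its decay under grid halving.

Published tables do not state whether LE conditions on starting robust or
is marginal over initial states; the package computes both — conditional
is the default, and `init = "marginal"` weights initial states by a
logistic-in-age frailty-prevalence model fitted to the analysis panel per
profile.

Uncertainty is a parametric bootstrap: `B` (default 500) parameter
vectors drawn from the multivariate normal at the MLE with the fitted
covariance, LE recomputed per draw, percentile 2.5/97.5 bounds reported.
This reading of "repeated estimates through random draws" is the package's
interpretation; nonparametric subject resampling would be the natural
alternative and can be layered on by refitting resampled panels.

## What the simulator emulates — and what it does not

`simulate_paths()` draws latent trajectories by exact competing-risks
sojourn sampling under the lattice-piecewise intensities (cumulative
hazard inversion), so simulated dynamics match the fitted model class
exactly. The default `cohort_config()` emulates the design of a
multi-wave ageing survey: seven enrolment waves, follow-up every 3 ± 0.5
years, truncated-normal entry ages (mean 87, SD 11, minimum 65), 41.2%
male, childhood SES prevalence 67.7/20.7/11.6%, entry states from a
logistic-in-age frailty prevalence so older entrants are more often
frail, and small item-level missingness (3% deficits, 2% SES). The
default `TruthParameters` were calibrated once against published
anchors — male low-SES annual robust→frailty probability rising from
roughly 23% at 65 towards ~50% by 95, recovery falling from ~20% to ~2%,
male/female total LE at 65 near 14.3/15.5 years with about a third of
male remaining life robust — and are fixed; SES effects are graded and
additive, with the childhood component 2.5 times the adult one on the
log-intensity scale.

Deficits are emitted conditionally independent given the latent state
(robust records draw 0–3 of 38 deficits, frail records at least 4), and
SES indicator patterns are mostly-Guttman within an index, which induces
the strong inter-item correlation that chained imputation exploits. Real
questionnaire data have richer dependence (domain structure in deficits,
cross-index SES correlation, proxy respondents, sampling weights, wave
non-response); passing tests therefore certify the pipeline's
correctness under its own model class, not distributional realism of any
particular survey. Per-subject seed substreams are drawn from a
master-seeded stream, so shrinking a cohort never reshuffles the
remaining subjects.

## Numerical choices and degenerate inputs

* 0.1-year lattice everywhere; entry ages rounded to the lattice.
* Closed-form 2×2 exponential with a guarded near-defective branch
  (discriminant × time < 1e-7 switches to the limit form) and rates
  clamped at 1e10 so extreme optimizer probes cannot overflow.
* `-Inf` intercepts are admitted and switch a transition off exactly,
  which the closed forms and the simulator handle natively (used by the
  analytic benchmark models).
* Zero-probability observations make the likelihood return `+Inf` (capped
  to a large finite value inside the optimizer); data with no observed
  exits drive intercepts to the bound and flag `boundary`.
* A non-positive-semidefinite covariance aborts the bootstrap with an
  instruction to refit rather than silently truncating.
* Printed-style rounding is half-up at two decimals (`round_half_up()`),
  matching published tables rather than banker's rounding.

## Problem sizes used by the tests

The suite exercises parameter recovery on 5,000 subjects with waves every
two years and entry ages 65–85 (every coefficient within two estimated
standard errors of truth), estimator-versus-microsimulation consistency
on 100,000 simulated paths (state-specific LE within 0.05 years, with
path years-in-state accumulated by the same left-endpoint rule so the
check isolates the stochastic dynamics from the quadrature error, which
the closed-form benchmarks bound separately), 200 random generators
against high-accuracy ODE integration (1e-8), and full-pipeline runs at a
few hundred subjects. These sizes are the package's chosen benchmark
conditions.

## Known limitations

* No hidden-Markov misclassification layer; state coding is taken at
  face value.
* No calendar-period inhomogeneity and no random-effects frailty terms;
  age is the only time scale.
* The discrete-time multinomial-logit route to annual transition
  probabilities, sometimes described alongside continuous-time
  modelling, is not implemented: annual matrices are derived from the
  continuous-time fit.
* Gender×SES interactions are available only through stratification.
* The childhood score binning is a documented default, not a canonical
  rule; alternative schemes plug in through `CategorizationScheme`
  arguments.
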