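---
title: "Models and methods: pharmacopeial monographs and generic competition"
author: "genentry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pharmacopeial monographs and generic competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genentry)
```

## The scientific problem

Pharmacopeial drug-product monographs are public quality standards for a
finished dosage form: identity, strength, purity, and the validated tests a
manufacturer can use instead of developing its own. If these standards lower
the cost of entry for generic manufacturers, they should be visible in market
outcomes: whether a drug ever faces a generic competitor, how quickly
successive generic manufacturers arrive, and how many ultimately enter. More
competitors mean lower prices, so a monograph effect on entry translates into
a counterfactual spending difference.

`genentry` implements this full analysis as a reusable pipeline:

1. **Ingestion** of drug approval records (the tilde-delimited Orange Book
   "products" dialect or plain CSV), a monograph directory and a drug-year
   sales panel, with strict schemas and an auditable rejects sidecar.
2. **Linkage** at the ingredient-route market level (product monographs match
   on ingredient and route; substance monographs, which describe only the
   active ingredient, match on ingredient alone) and a sequential
   eligibility cascade with a telescoping attrition ledger.
3. **Three estimands** of the monograph-competition association with
   cluster-robust variances over therapeutic classes.
4. **A counterfactual savings engine** mapping the fitted count-model rate
   ratio through a competition-to-price curve.
5. **Sensitivity analyses** re-running the main model under exposure-timing
   variants, interval and class-size restrictions, and route strata.
6. **A synthetic-cohort generator** with known ground truth, so that every
   stage, including the variance estimators, is testable without proprietary
   sales data.

## The three estimands

Let drug *i* belong to therapeutic class *c(i)*, with exposure
$X_i = 1$ if a drug-product monograph became official before the first
generic entrant (timing variants use the second or third entrant). Adjusted
models also include: a drug-substance monograph indicator, log10 of
pre-entry market size (sales in the calendar year before the first generic
approval, or before loss of exclusivity for never-genericized drugs), drug
age (years from originator approval to the study end), vintage (competition
rank of the approval date within class), and route group (oral, inhalation,
intravenous, topical, other).

**Any-generic model.** A marginal logistic model
$\mathrm{logit}\, P(N_i \ge 1) = \alpha + \beta X_i + \gamma' Z_i$
estimated by generalized estimating equations with an exchangeable working
correlation within class. The exposure effect is reported as an odds ratio.

**Count model (main analysis).** A marginal log-link count model
$\log E[N_i] = \alpha + \beta X_i + \gamma' Z_i$, also GEE with exchangeable
working correlation. The working mean-variance is Poisson; the sandwich
variance keeps inference valid under the substantial overdispersion real
entrant counts show. The exposure effect is an incidence rate ratio (IRR).

**Gap-time model.** Among markets with at least two generic entrants, a Cox
proportional-hazards model for the days between the second and third
entrants' approvals, administratively censored at the study end
(2018-04-03), with Efron tie handling and a cluster-robust (class) variance.
The second-to-third gap is the primary timing outcome because litigation and
the 180-day first-generic exclusivity distort the first two entries; the
first-to-second gap is a secondary analysis.

### Cluster-robust machinery

No GEE implementation is available in this environment's R stack, and the
sandwich estimator is in any case part of what must be validated, so both are
implemented in the package. `gee_fit()` iterates the estimating equations
$\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0$ with the exchangeable correlation
estimated by the usual moment estimator from Pearson residuals; the
exchangeable inverse is applied in closed form, so no per-cluster matrix is
inverted. `sandwich_covariance()` computes
$B^{-1} \left(\sum_c s_c s_c'\right) B^{-T}$ from per-cluster summed scores
and the bread matrix; the unit tests verify it against an independently coded
HC0 formula, and the GEE against a maximum-likelihood logistic fit with
heteroskedasticity-robust variance in the singleton-cluster case.

With ~30 classes the raw sandwich is anti-conservative, so the model layer
applies the standard small-cluster correction: CR1 scaling ($G/(G-1)$ on the
variance) and t critical values with $G-1$ degrees of freedom. Simulation at
the study scale shows 95% interval coverage near 0.92-0.95 with the
correction, versus at or below 0.90 without it.

Ties in the Cox model use Efron's method; Wald intervals are two-sided at
$\alpha = 0.05$. Markets with a missing market size are dropped from adjusted
fits only, and counted.

### Kaplan-Meier summaries

`km_summary()` reports the product-limit curve with log-log confidence
bands. The median is the *first time the survival curve is at or below 0.5*
(so uncensored times 1..100 give exactly 50, the empirical quantile), and
its confidence limits are the first crossings of the upper and lower bands.

## The counterfactual savings engine

For every exposed market and calendar year, with fitted rate ratio IRR and
competition-to-price curve $D(\cdot)$ (relative unit price at a given number
of generic manufacturers, $D(0) = 1$, nonincreasing):

* counterfactual entrant count: $N_P = N_A / \mathrm{IRR}$ — dividing out
  the multiplicative monograph effect; the typeset source formula is
  ambiguous about direction, and division is the only direction consistent
  with monographs *adding* manufacturers when IRR > 1;
* counterfactual price: $P_P = \dfrac{D(N_P)}{D(N_A)} \, P_A$, where
  $P_A$ = observed dollars / observed prescriptions that year;
* counterfactual sales: $P_P \times V_A$ with volume held fixed (volume
  response to price is deliberately out of scope);
* savings: counterfactual minus observed sales, summed per year. The
  "additional manufacturers" figure $\sum (N_A - N_P)$ is rounded only at
  the total; per-drug counts stay continuous and the curve is evaluated by
  linear interpolation between its integer knots with constant extrapolation
  past the last knot.

These conventions make savings provably nonnegative and monotone in the IRR
whenever the curve is nonincreasing, which the property tests assert. The
empirical competition-price curve is a user-supplied input; the file shipped
at `inst/extdata/price_curve_synthetic.csv` is a clearly labelled synthetic
illustration for tests and examples, not an estimate.

The counterfactual is applied to markets whose product monograph predates
the first generic (the main model's exposure definition); a configuration
switch widens it to any monograph for sensitivity.

## The synthetic-cohort generator

`simulate_cohort()` emits the three input tables the readers ingest, plus a
truth record. Its defaults are the study conditions the package is designed
around: 982 drugs in 30 classes; route mix 553 oral / 183 intravenous / 122
other / 93 topical / 31 inhalation per 982; product-monograph prevalence
40.3% and substance prevalence 74.9% with the corresponding route-specific
prevalences; 51% of product monographs official before the first generic;
unexposed mean of 1.7 entrants per drug (7.2 among exposed drugs in the
crude calibration); inter-entrant gaps with median about 180 days;
originator approvals uniform 1982-2015; panel years 1997-2016;
administrative censoring 2018-04-03. Default effect sizes are the adjusted
estimates the analysis targets: OR 0.64, IRR 1.53, second-to-third HR 0.99,
first-to-second HR 0.88.

Three design choices deserve explanation.

**Exact realization of exposure.** The monograph official date is placed by
first drawing a *bucket* relative to entrant indices (before the 1st,
between 1st and 2nd, ..., after the study window), then converting the
bucket to a date interval against the realized timeline. Monographs destined
to appear after the study window are still emitted with a post-window
official date — the directory is a snapshot taken later than the study —
so `compute_exposure()` on the emitted tables reproduces the generative
exposure indicator exactly at the before-first/second/third timings. Without
this, classification noise between generation and fitting attenuates every
recovered effect.

**A coherent multi-outcome chain.** The binary, count and gap-time truths
must coexist in one cohort even though the outcomes are deterministic
functions of one entrant timeline. The generator therefore builds the
timeline sequentially: the any-generic gate is Bernoulli with the logistic
truth; the first entrant lands uniformly in the post-1998 window; the second
entrant is a Bernoulli with a truncated-exponential gap (so it never spills
past the study end); the third entrant arrives after an exponential
proportional-hazards gap carrying the HR truth, censored only
administratively; and the number of later entrants is a negative-binomial
draw whose conditional mean is solved in closed form so that the
*unconditional* expected entrant count equals the log-linear count truth,
drug by drug (times a mean-one lognormal class frailty). Counts are
overdispersed, within-class correlated, and all three fitted models are
exactly correctly specified. Two small prices are paid: drugs whose target
mean falls below the any-generic probability (about 2% in the tails of the
covariate distribution) stop at one entrant, and the first-to-second gap is
truncated rather than fully exponential — so the secondary first-to-second
HR is reproduced only approximately, which is why it is reported but not
used as a recovery target.

**Clustering through two channels.** The count layer carries a shared
class frailty; the binary and gap layers see within-class correlation only
through class-correlated covariates (a class-level shift in market size). A
random intercept in a logistic or Cox layer would change the *marginal*
effect away from the conditional truth (non-collapsibility), defeating
recovery of the stated parameter; log-link means are collapsible over a
mean-one frailty, so the count layer can carry one.

Pre-entry revenue in the sales panel is deliberately noise-free, so the
market-size covariate recomputed by the pipeline equals the generative one;
post-entry prices decline along the competition curve with lognormal noise.

What the generator does *not* emulate: name-matching noise in linkage (keys
are clean by construction), corporate mergers among applicants, authorized
generics, partial-year sales in the approval year, or any real-world joint
distribution between monograph timing and unobserved entry barriers.
Passing recovery tests therefore demonstrates that the estimators and
pipeline are correct under the stated generating model — not that the
published real-data estimates are themselves unconfounded.

## Numerical and procedural choices

* Eligibility cascade: filters run in the flow-diagram order (pre-1982
  approvals; generics or loss of exclusivity before 1998; monograph official
  before the originator approval; under patent; unmatched to sales; no
  therapeutic class; OTC or discontinued), each market attributed to the
  first filter it fails; cut years are configuration keys.
* Entrants are distinct ANDA *applicants* (not application numbers), each
  timed at its first approval; the earliest NDA defines the market.
* Vintage uses competition ranking (ties share the lower rank, next rank
  skipped). Drug age is measured to the study end, a fixed reference shared
  by all drugs, since the estimands are time-fixed.
* Market size enters models as log10(dollars + 1).
* GEE convergence: damped Newton steps (capped at 4 on the linear-predictor
  scale), exchangeable correlation clamped to [0, 0.95], hard failure with
  diagnostics on separation or a singular working information matrix.
  Degenerate fits (constant exposure, empty strata) raise typed errors that
  the sensitivity layer converts to "not estimable" rows.
* Determinism: one seed drives a single RNG stream through the whole
  generator; the same seed reproduces the emitted tables byte for byte.

## Problem sizes

The package's recovery studies use 200 replicate cohorts of 982 drugs in 30
classes per estimand — enough that the Monte-Carlo standard error of the
mean log estimate (≈0.01 for the count model) is well below the 0.05
log-scale tolerance the acceptance checks use. The unit-test cohorts are
smaller (250-600 drugs) and chosen so every route stratum is populated;
at those sizes sparse strata can legitimately separate, which the fits
report as errors rather than estimates.

## Known limitations

* The GEE implementation supports the two canonical links used here and
  exchangeable/independence working correlations only.
* The cluster-robust inference is asymptotic in the number of classes; with
  few classes (< ~15) coverage degrades even with the CR1/t correction, as
  the small-cohort simulations show.
* Combination products are keyed by their full ingredient string; the
  directory linkage performs no fuzzy name matching by design.
* The savings engine treats the competition-price curve as exact and shared
  across drugs, and ignores rebates, net-price dynamics and volume
  responses.
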