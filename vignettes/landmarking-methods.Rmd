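---
title: "Dynamic prediction by landmarking: models, generator and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic prediction by landmarking: models, generator and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmarker)
```

## The prediction problem

For a chronic progressive condition such as cystic fibrosis, the clinically
useful question is rarely "what is survival from birth" but "given that this
patient is alive at age $L$ with their current health status, what is the
probability of surviving another $t$ years".  **Landmarking** answers it
directly: at each landmark age $L$ the data are restricted to individuals
still at risk (alive, untransplanted, under observation), covariates are
summarised using only information available by $L$, and residual survival is
modelled on the time-since-landmark scale with administrative censoring at a
horizon $L + w$.  This package implements that workflow end to end for
registry-style longitudinal data, with $L \in \{18, \dots, 50\}$ years and
$w = 10$ years by default.

The core model is a Cox proportional-hazards *supermodel* fitted to the
stacked landmark datasets: for a record of patient $i$ in the landmark-$L$
dataset with covariate vector $x_{i}(L)$,

$$
\lambda_i(t \mid L) \;=\; \lambda_{0,L}(t)\,
\exp\!\bigl(\beta^\top x_i(L)\bigr),
\qquad t \in (0, w],
$$

with a separate (stratified) baseline hazard $\lambda_{0,L}$ per landmark
age and coefficients $\beta$ shared across landmark ages.  Because a patient
contributes one record to every landmark dataset for which they are at risk,
rows are correlated within patient; all standard errors are cluster-robust
sandwich estimates with the patient as cluster.  Predicted survival is
$\hat S(t \mid L, x) = \exp\{-\hat H_{0,L}(t)\, e^{\hat\beta^\top (x - \bar
x)}\}$ with $\hat H_{0,L}$ the Breslow estimator and $\bar x$ the
stacked-data covariate means (the centering vector is stored and serialised
with every fit, so exported baselines are unambiguous).

### The six model variants

`variant_options()` / `fit_variant()` encode the model family that a
landmarking analysis typically compares:

1. separate Cox models per landmark age (no pooling);
2. the supermodel above — stratified baselines, common coefficients;
3. variant 2 with coefficients varying smoothly in $L$ through interactions
   with the scaled landmark age $u = (L - 18)/(50 - 18)$ (default degree 2:
   $u, u^2$; degree 0 recovers variant 2 exactly, which is tested);
4. variant 2 with coefficients varying in time-since-landmark through
   interactions with a deterministic time basis, default $f(t) = t/w$
   (natural cubic spline optional), evaluated at the event times *inside*
   the partial likelihood — the landmarking device for time-varying
   effects, not post-hoc stratification;
5. a common baseline with $\gamma_1 u + \gamma_2 u^2$ regression terms
   replacing the stratification;
6. variant 2 plus two-stage features: mixed-model fitted values and slopes
   at $L$ for FEV1%, FVC% and weight (by default alongside the
   last-observation-carried-forward values).

The scaling of $u$ to $[0,1]$ is a numerical choice (basis terms stay on
the unit scale); the restricted variant-4 form with only FEV1%
time-varying is provided because the strongest predictor is the natural
single candidate for a time-varying effect.

## Covariate summaries at the landmark

The default summary is last observation carried forward (LOCF): for each of
the 13 time-dependent variables, the value at the latest review at or
before $L$, with the staleness `lag_*` (years since that review) logged per
record.  No staleness limit is imposed — the emulated registry has
near-complete annual follow-up, so stale carries are rare — but the logged
lags let a user filter if their data are gappier.  A patient with no
pre-$L$ measurement of a required variable is excluded from that landmark
dataset and counted in its exclusion log; imputation is deliberately not
silently applied.  Boundary conventions: a review, diagnosis or registry
entry exactly at $L$ counts as available at $L$; a death exactly at $L$
makes the patient ineligible ("alive at $L$" is strict); a death exactly at
$L + w$ is an event with `time = w` (the censoring interval is half-open).
Calendar year enters as a continuous covariate (the value at age $L$);
since the engine centers every column at the stacked-data means, no
separate centering convention is needed for it.

### Two-stage landmarking

`fit_multivariate_mixed()` fits, per landmark age, a trivariate linear
mixed model to all pre-$L$ measurements of FEV1%, FVC% and weight:
outcome-specific fixed intercept and slope in $(\mathrm{age} - L)$,
patient-level random intercepts and slopes jointly Gaussian across the
three outcomes (unstructured $6 \times 6$ covariance) and outcome-specific
residual variances.  Outcomes are z-scored on the pre-$L$ data before
joint fitting — the $6\times6$ covariance is then well conditioned — and
back-transformed afterwards.  Estimation is maximum likelihood (not REML)
so that likelihoods are comparable across models fitted to the same
records; an expectation–conditional-maximisation iteration alternates a
generalised-least-squares fixed-effect update with EM updates of the
variance components, so the log-likelihood trace is non-decreasing (this is
asserted in the tests).  Near-singular covariance iterates are inverted
with a small diagonal inflation.  The empirical BLUPs give each patient's
fitted value at $L$ and slope per outcome; these become the `_fit` /
`_slope` columns of variant 6.  The fixed-effect structure is deliberately
minimal (intercept and slope only): it is exactly what the two-stage
features require, and covariate extensions would change the features'
meaning, not their mechanics.

## The Cox engine

`fit_cox()` maximises the stratified partial likelihood by Newton–Raphson
with step-halving.  Numerical choices:

* **Ties**: Breslow by default — the synthetic death times are continuous,
  so ties essentially never occur — with Efron available by flag.  With
  Efron ties the sandwich variance uses Breslow-form score residuals (exact
  when there are no ties); this approximation is documented rather than
  hidden.
* **Convergence**: score max-norm below $10^{-9} \times \max(1,\,$number of
  events$)$, or relative log-likelihood change below $10^{-13}$.
  Iteration is capped at 50.  With separated data (possible in tiny
  per-landmark fits at sparse old ages) the partial likelihood is monotone
  in a coefficient; the engine then stops at the likelihood plateau with a
  warning that a coefficient may be diverging, as `coxph` does, and uses an
  eigenvalue pseudo-inverse if the information matrix is numerically
  singular there.  Genuine non-convergence is an error carrying the
  iteration trace.
* **Centering**: all design columns are centered at their data means before
  fitting; baselines refer to the centered reference and the centering
  vector is serialised with the fit.
* **Rank**: the time-fixed part of the design is QR-checked and collinear
  terms are reported by name; a term with a time basis shares its base
  column with its main effect by construction and is excluded from that
  check.
* **Speed**: for Breslow ties the score and information are accumulated by
  cumulative-weight identities (no loop over event times), so a fit on a
  few hundred thousand stacked records with ~17 predictors takes seconds.

Time-since-landmark is the analysis timescale: every subject enters at
$t = 0$, so no left truncation is needed within a landmark dataset.  A
stratum with no events gets a flat baseline (with a warning), predicts
$S \equiv 1$, and is retained so that prediction for that stratum remains
defined.

Fits are serialised as JSON — term descriptors, centering vector,
coefficients, both covariances, and per-stratum baseline jumps — which is
exactly the information a published "full model specification" carries, and
round-trips through `read_cox_fit()` including the landmark- and time-basis
terms.

## The synthetic registry generator

There are no public registry data at the scale this methodology needs, so
the package ships a generator whose ground truth is known, making every
downstream stage testable.  `simulate_registry()` emulates:

* a calendar observation window (2005–2015 by default) with administrative
  censoring at its end; individuals enter at
  $\max(18, \text{diagnosis age}, \text{age at window start})$;
* roughly annual review visits (mean interval 1 year, jitter SD 0.1,
  minimum gap 0.25);
* birth years on 1960–1995 with a linearly increasing density
  (`birth_cohort_shape = 2`): an adult cystic-fibrosis cohort thins
  steeply with age through survivorship, so landmark ages in the 40s are
  data-sparse relative to the 20s — the feature that makes pooling across
  landmark ages valuable;
* continuous latent trajectories, linear in age with correlated random
  intercepts and slopes per patient (FEV1% declining ~1.5%/year with wide
  between-patient spread, FVC% similar, weight drifting slowly, height
  flat); emitted measurements add independent Gaussian error while the
  hazard acts on the latent value, so LOCF predictors are error-prone
  proxies, as in reality;
* binary infection/comorbidity states as per-visit Markov chains started
  at their stationary prevalences (a prevalent adult cohort is at steady
  state); zero-inflated annual IV-antibiotic days redrawn each visit;
* a death hazard that is piecewise-constant in age times
  $\exp\{\sum_j \theta_j (x_j - r_j)\}$ on the current latent values plus
  a calendar-time trend.  The reference values $r_j$ are an equivalent
  reparameterisation of the baseline: without them the baseline constant
  would have to offset a linear predictor of order $-0.03 \times 75$.
  The default baseline is low and nearly flat (~0.3%/year): most of the
  age gradient of mortality emerges from the declining trajectories acting
  through the coefficients, giving all-in death rates from ~1%/year in the
  mid-20s to ~4%/year at 50 and a 10-year landmark mortality around
  10–15%, in the range reported for adult cystic-fibrosis cohorts;
* transplant as a competing intercurrent event whose hazard rises as
  latent FEV1% falls; after transplant no further reviews are generated
  and death follows a constant post-transplant hazard — transplanted
  individuals therefore contribute exactly their death/censoring times, as
  the landmark eligibility rules require;
* near-zero loss to follow-up (configurable).

Event times are sampled *exactly* for this generative model by
piecewise-constant inversion: within each inter-visit interval the
covariate part of the hazard is held at the interval-start latent values
while the baseline piece switches at its age breakpoints.  The generator is
deterministic given the config seed and never touches the caller's RNG
stream.

**What the generator does not emulate** — and hence what passing tests do
not establish about real registries: cross-variable correlation of the
random effects (FEV1% and FVC% trajectories are independent given age),
informative visit timing (sicker patients are not seen more often),
measurement error correlated within visit, treatment effects, paediatric
dynamics, reference-equation (GLI) computation of percent-predicted values,
and pre-window survivorship (random effects are drawn independent of the
requirement to be alive at entry, so the oldest entrants are not selected
for good trajectories as real survivors would be).  Validation against this
generator establishes that the *machinery* is correct, not that any
particular coefficient describes real patients.

### The survival oracle

`oracle_survival()` returns the generative conditional survival
$S(L + t \mid L, x)$ by integrating the configured hazard along the
covariate path: continuous variables follow the *expected* conditional
latent trajectory given the current value (the best linear predictor of
the random slope given the random-effect realisation at $L$), while binary
chains, IV-day redraws and the competing transplant process are
marginalised by Monte Carlo with a fixed inner seed.  Each draw contributes
$\exp(-\int \lambda)$ — a Rao-Blackwellised estimator whose Monte-Carlo
error is far below that of an empirical survival proportion at the same
number of draws.  The integration grid reproduces the generator's
conventions (interval-start covariates, exact baseline breakpoints), so in
scenarios with time-constant covariates the oracle is exact.  Its one
approximation in dynamic scenarios is using the expected continuous path
rather than marginalising over the conditional slope distribution;
validation scenarios therefore either freeze the slopes or drive the hazard
through the binary states, where the oracle is exact.

### The time-constant validation scenario

`registry_config_constant()` freezes every source of within-patient
variation (slopes, measurement error, binary transitions, IV redraws) while
keeping between-patient spread, and switches off transplant and loss.
Under this scenario the stratified supermodel with LOCF covariates is
*exactly* correctly specified — the configured coefficients are the truth,
including the calendar coefficient, which is identified through the
calendar-year column because age and calendar time decouple across birth
cohorts within a landmark stratum.  This is the scenario behind the
parameter-recovery and prediction-oracle validation: coefficient estimates
are checked against the truth at 3 robust standard errors with pooled
95%-interval coverage over 20 replicate registries of 2,000 individuals,
and predicted survival curves are checked against the oracle at the
tolerance of a 100,000-draw empirical oracle on a 400,000-individual
single-cohort registry, for ten profiles spanning the deciles of predicted
risk.

## Evaluation

* **Discrimination** is a truncated Harrell concordance: outcomes are
  administratively censored at the evaluation horizon, a pair is evaluable
  iff the smaller censored time is an event (or the times are tied with
  exactly one event), ties in predicted risk count ½.  The pair counting
  is delegated to `survival::concordance` (identical conventions,
  C implementation); the package's tests pin the definition against an
  exhaustive pair-enumeration oracle.  Predicted risk at horizon $h$ is
  $1 - \hat S(h)$ from the fitted model.
* **Prediction error** is the IPCW Brier score: subjects dead by $h$ are
  weighted by $1/\hat G(T^-)$, survivors past $h$ by $1/\hat G(h^-)$,
  subjects censored before $h$ by 0, with $\hat G$ the Kaplan–Meier
  estimator of the censoring distribution on the evaluation records.  Left
  limits are used throughout so that records censored exactly at the
  horizon (the administrative-censoring norm here) remain evaluable.  In
  pooled evaluations $\hat G$ is estimated per landmark age, because the
  censoring structure depends on age and calendar time.
* **Percentage reduction** compares the model's Brier score with that of
  the per-landmark Kaplan–Meier survival probability applied to every
  record of that landmark — the natural covariate-free reference.
* **Overall metrics** pool all evaluation records across landmark ages
  into one pair/weight set (a per-landmark-averaged alternative would
  weight sparse old ages equally with dense young ones; pooling weights
  records, which matches how the stacked model is fitted).
* **Protocol**: an 80/20 split of the stacked records stratified by
  landmark age (each patient has at most one record per landmark age, so
  record sampling within stratum is patient sampling within stratum), and
  Monte-Carlo cross-validation on the training part — repeated 80/20 inner
  splits, default 50 repetitions, refitting per repetition — to avoid
  optimism when comparing variants.
* **Calibration** groups records into deciles of predicted survival at a
  horizon and compares mean predicted probability with the within-group
  Kaplan–Meier estimate and its Greenwood band; `simulate_outcomes()`
  redraws outcomes from a fitted model's own predictions, giving data that
  are calibrated by construction for verifying the machinery.

## Validation design and problem sizes

The test suite builds all of its data programmatically.  The sizes are the
package's own validation choices: hand fixtures of 3–8 subjects for the
brute-force partial-likelihood, concordance and IPCW oracles; registries of
a few hundred individuals for structural and identity checks (variant
nesting, serialisation round-trips); 2,000 × 20 replicates for coefficient
recovery; a 400,000-individual single cohort for the prediction oracle;
3,000 × 10 replicates for the qualitative supermodel-versus-per-landmark
comparison; and 1,100 individuals with complete adult histories for
two-stage BLUP recovery (truncated histories of two or three visits dilute
slope information and are not informative about the estimator itself).

Two empirical properties of the default generator are worth knowing when
reading results.  First, pooled discrimination of the correctly specified
supermodel sits near $C \approx 0.70$ at these settings (the value the
reproduction script computes).  This is the information ceiling of the
generative design rather than an estimation deficit — no predictor can beat
the true latent state at the landmark, and the configured effect sizes
bound how much that state separates patients; real registries show higher
C because real between-patient heterogeneity in prognosis is larger than
these defaults.
Second, per-landmark models at old landmark ages sit on 25–100 records and
can separate; the supermodel's pooling is exactly what repairs this, and
the package's qualitative comparison asserts that repair (higher overall C,
lower Brier, gains concentrated at old ages) as a majority direction over
replicate registries rather than per replicate, since per-landmark metrics
at sparse ages are noisy.

## Known limitations

* Efron ties combined with the robust variance uses Breslow-form score
  residuals (exact only without ties).
* The oracle's expected-conditional-path treatment of continuous
  trajectories is an approximation in scenarios with active random slopes.
* `simulate_outcomes()` supports time-fixed coefficient fits only (variant
  4 fits cannot be inverted by a single step function per record).
* Variant 1 at sparse landmark ages can plateau with diverging
  coefficients; the fit warns rather than fails, mirroring standard
  practice, and its huge variances make the affected terms visibly
  uninformative.
* No support for interval censoring, penalised estimation, competing-risk
  decompositions or post-transplant prediction; transplanted individuals
  contribute only their subsequent death/censoring times, so predictions
  refer to patients untransplanted at the landmark.
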