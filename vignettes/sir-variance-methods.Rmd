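---
title: "Variance estimation for log standardized incidence ratios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance estimation for log standardized incidence ratios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The profiling problem

Registries that follow patients across many treatment centers routinely ask
whether any center's outcome rate is out of line with its peers *after*
accounting for the patients it treats. The standard instrument is the
indirectly standardized incidence ratio: a risk-adjustment model is fitted to
patient-level data, each patient's predicted event probability is summed
within centers to give an expected count \(E_c\), and the center's observed
count \(O_c\) is compared through

\[\mathrm{SIR}_c = O_c / E_c, \qquad \text{reported as } \log \mathrm{SIR}_c .\]

The log scale symmetrizes excess and deficit and is where interval
construction behaves; funnel plots put SIR against \(E_c\) with control
limits that tighten as precision grows, avoiding spurious league-table
ranking.

Everything downstream of the point estimate — flagging a center, the width
of its funnel position, the false-positive burden of a surveillance program —
depends on \(\widehat{\mathrm{Var}}(\log \mathrm{SIR}_c)\). This package
implements and compares the three standard choices on a common risk model:
an analytic delta method, a nonparametric bootstrap with full model
refitting, and Bayesian MCMC.

## The risk-adjustment model

The outcome is binary at the patient level, so the model is a
random-intercept logistic regression

\[\operatorname{logit} P(y_i = 1) = \beta_0 + x_i^\top \beta + u_{c(i)},
\qquad u_c \sim N(0, \sigma_u^2),\]

with `status ~ gender + agegp + indigenous + lung + diabetes + cvd + late +
bmi30 + mmm + timegp + (1 | centre_id)` as the reference covariate set: two
binary demographics, a 7-level age band, five binary clinical flags, a
7-level remoteness scale and a 3-level treatment-era period. Fitting is
maximum likelihood via the Laplace approximation (`lme4::glmer`), adequate
for a single scalar random effect; adaptive quadrature is available through
`nAGQ`. A boundary fit (\(\hat\sigma_u = 0\)) is a legitimate converged
estimate, not a failure; genuine non-convergence is reported truthfully in
the `converged` flag and never returned silently.

Expected counts use each patient's predicted probability with the random
intercept set to zero (`conditional_null`): "what would be expected if this
case mix were treated at an average center", the conventional reading of
indirect standardization. Because the convention is not universal, predicted
probabilities conditional on the center's own estimated intercept and
probabilities marginalized over \(N(0, \hat\sigma_u^2)\) (by fixed-grid
quadrature over \(\pm 6\) SD, 121 nodes) are also exposed; the choice only
shifts all \(E_c\) by a common pattern and is documented rather than
consequential for the comparisons here.

A center with \(O_c = 0\) receives the standard continuity correction
\(O^* = 0.5\) (flagged in the output) so that \(\log \mathrm{SIR}\) and its
variance stay finite; exclusion is available instead.

## The three variance estimators

**Delta method.** First-order propagation with \(E\) treated as fixed:
\(\widehat{\mathrm{Var}}(\log \mathrm{SIR}) = \mathrm{Var}(O)/O^2\). Because
the likelihood is Bernoulli, the default takes
\(\mathrm{Var}(O) = \sum_i \hat p_i (1 - \hat p_i)\) over the center's
patients (*binomial* mode); the classical Poisson form
\(\mathrm{Var}(O) = O\), reducing to \(1/O\), is the alternative. Binomial
never exceeds Poisson since \(p(1-p) < p\). Intervals are Wald on the log
scale.

**Nonparametric bootstrap.** Patients are resampled with replacement within
each center (preserving every center's size, so its SIR exists in all
replicates), the *full* risk model is refitted, and all log SIRs are
recomputed; the estimate is the sample variance over replicates
(denominator \(B_\mathrm{ok} - 1\)) with a percentile interval. The
production default is \(B = 5000\); the scaled-down analyses here use
\(B\) between 150 and 500. A replicate fails only if the refit errors or
produces a non-finite log SIR — lme4 convergence *warnings* on a resample
are tolerated, since discarding boundary fits would bias the bootstrap
distribution; more than 10% failures aborts with advice. A cluster bootstrap
(resampling whole centers) is implemented but non-default, because a
replicate that omits a center cannot contribute to that center's variance.

**Bayesian MCMC.** The same hierarchical model is sampled with JAGS
(defaults 3 chains, 25,500 total iterations, 1500 warmup per chain,
weakly-informative priors: Normal(0, 2.5) on coefficients, Normal(0, 10) on
the intercept, Half-Normal(1) on \(\sigma_u\); all configurable since no
canonical choice exists). Two per-draw constructions of log SIR are
provided:

* `sir_draw = "expected"` (default): the observed \(O_c\) over the draw's
  expected count at \(u = 0\). The posterior spread then quantifies
  *risk-model* uncertainty around the plug-in SIR. This is the natural
  Bayesian analogue of the delta/bootstrap target and produces the markedly
  smaller variances one expects of a posterior summary that conditions on
  the observed count.
* `sir_draw = "posterior"`: the draw's own center-effect SIR,
  \(\sum_i \operatorname{logit}^{-1}(\eta_i + u_c) /
  \sum_i \operatorname{logit}^{-1}(\eta_i)\). This is the full posterior of
  the center's standardized ratio as a *parameter*; its credible interval is
  the one that can calibrate against a known simulation truth, and it is
  what the evaluation harness uses for coverage and false-positive rates.

The distinction matters: the "expected" construction ignores the binomial
noise in \(O_c\) entirely, so its credible interval is not a confidence
procedure for the true SIR and should not be scored for coverage. Reporting
both makes the comparison honest instead of accidental. Convergence is
monitored per center (split-chain Gelman–Rubin \(\hat R\) and effective
sample size via coda); any \(\hat R > 1.05\) flags the whole result
`unconverged` with a warning, never silently.

## Evaluation against synthetic truth

The registry the estimators were designed for is not publicly available, so
evaluation runs on a seeded synthetic registry whose generating process
matches the model: covariates sampled independently from configurable
frequencies (no joint distribution is published, so independence is the
default and a correlation hook is left open), center sizes uniform on a
configurable range, center effects \(u_c \sim N(0, \sigma_u^2)\), outcomes
Bernoulli from the linear predictor. The generator knows each center's true
standardized ratio

\[\mathrm{SIR}^{\mathrm{true}}_c = \frac{\sum_{i \in c}
\operatorname{logit}^{-1}(\eta_i + u_c)}{\sum_{i \in c}
\operatorname{logit}^{-1}(\eta_i)},\]

which equals 1 exactly when \(u_c = 0\). Bias, variance and MSE of each
method's point estimate (plug-in log SIR for delta and bootstrap, posterior
mean for MCMC) are accumulated over replicate-centers as errors
\(e = \widehat{\log \mathrm{SIR}} - \log \mathrm{SIR}^{\mathrm{true}}\),
with the population-variance convention (denominator \(R\)) so that
\(\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{variance}\) holds to machine
precision and is asserted on every run. Coverage is the fraction of 95%
intervals containing the truth (closed endpoints); the false-positive rate
is the flagged fraction of truly in-control centers (\(u_c = 0\)), with
either interval-based flagging (the 95% interval for log SIR excludes 0) or
funnel-based flagging at the center's own \(E\).

On real data the "truth" behind a bias statement is unobservable; the
synthetic truth here is this package's substitute, not a claim about any
registry's values.

The single random seed is split deterministically into sub-streams (center
structure, covariates, outcomes, missingness; and per pipeline stage), so
changing the bootstrap \(B\) or switching missingness on cannot perturb the
generated outcomes — a property the determinism tests check at the byte
level on all CSV outputs.

### Default generator settings

Where the source setting is known it is kept: study period 2012–2023 in
three eras, the 7-level age and remoteness scales, a 20-patient minimum
subgroup size per center in the exclusion cascade, \(B = 5000\) and
3 chains × 8500 iterations as production defaults. Quantities no public
source states were fixed once at values a registry statistician would call
realistic and are not revisited: intercept −1.6 (baseline event rate
≈ 17%), modest case-mix gradients (e.g. +0.40 log-odds for diabetes, up to
+0.80 for the oldest age band), Indigenous prevalence 20%, center sizes
100–600, \(\sigma_u = 0.3\) for heterogeneous scenarios. The generator does
not attempt to mimic real marginal distributions, covariate correlations, or
survival/censoring processes (censoring is only a status code for the filter
stage) — so passing tests demonstrate correctness of the estimators under
the assumed model, not fidelity to any particular registry.

## The exclusion cascade

Registry analyses reach their analysis cohort through an auditable chain of
exclusions; the package mirrors that as composable filters (study period,
minimum subgroup count per center, complete-case on chosen fields, censored
status), each returning in/out/dropped counts that chain into an attrition
report which refuses inconsistent chains. One wording in the source
narrative admits two readings: whether a center failing the subgroup
threshold loses only that subgroup or all its rows. The filter drops the
*whole center*, because per-center subgroup comparisons need adequate counts
on both sides; this is deliberately prominent in the documentation. Filters
are complete-case only — the source describes exclusions, not imputation.

## Numerical and design choices

* **Scenario sizes.** The statistical checks run at deliberately scaled-down
  sizes chosen for Monte-Carlo resolution, stated here as the package's own
  choices: parameter recovery uses 50 replicates of 40 centers × 500
  patients; the delta-method oracle resamples 100,000 outcomes per center at
  centers with \(E \ge 30\); bootstrap–delta agreement uses 10 centers of
  800–1200 patients with \(B = 500\); coverage calibration uses 20
  replicates of 10 centers (≥ 200 replicate-centers) with \(B = 150\) and
  3 × 1800 MCMC iterations; false-positive calibration uses 600 null
  replicate-centers.
* **Delta oracle evaluation point.** The resampling oracle holds \(\hat p\)
  and \(E\) fixed, so its draws center at \(E[O] = E\); the formula is
  compared at that same point (\(O := E\)). Comparing at an observed
  \(O \ne E\) would confound the check with the \(1/O^2\) plug-in, which is
  a property of the data, not of the approximation.
* **Bootstrap–delta agreement is a null-scenario statement.** With genuine
  center effects the two estimators target different quantities: the delta
  formula evaluates \(\mathrm{Var}(O)\) under the risk model at \(u = 0\),
  while the within-center bootstrap tracks each center's *own* empirical
  rate. They coincide asymptotically for in-control centers, so the
  agreement check generates under \(\sigma_u = 0\). Even there a residual
  gap of order −10% persists because patients are resampled jointly with
  their covariates, correlating \(O\) and \(E\) across replicates — visible,
  documented, and well within the 25% agreement band.
* **Row-order invariance.** Refitting on a permuted table reproduces
  estimates to about \(10^{-7}\), not machine precision: floating-point
  summation order moves the Laplace-deviance optimum. The property is
  tested at \(10^{-6}\).
* **Scaled-down refits.** Bootstrap refits inside the large harnesses use
  `nAGQ = 0` (PIRLS-only) for speed; the full Laplace refit is the default
  everywhere else.
* **Ties and boundaries.** A SIR exactly on a funnel limit is *inside*
  (strict exceedance flags); interval endpoints count as covering; funnel
  levels default to 95% and 99.8% with no overdispersion inflation of the
  limits (an extension hook, not a default, as there is no evidence the
  reference analysis used one).
* **Zero-event centers.** Continuity correction \(O^* = 0.5\) with a flag,
  configurable to exclusion.

## Known limitations

* Only a scalar random intercept: no random slopes, crossed effects, or the
  Poisson model for aggregated counts (a deliberate non-goal, left to future
  comparison work).
* Covariate independence in the generator means the risk model is always
  correctly specified in simulations; none of the checks here speak to
  robustness under model misspecification.
* The cluster ("centers") bootstrap is a rough option: per-center variances
  average over the copies of a center within each replicate and should be
  treated as exploratory.
* JAGS's slice sampler mixes slowly for strongly correlated fixed effects;
  the per-center \(\hat R\)/ESS diagnostics are the guard, and short chains
  will be flagged `unconverged` rather than hidden.
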