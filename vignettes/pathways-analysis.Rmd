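---
title: "Pathways analysis for pair-matched cluster-randomised trials: models, estimators and design choices"
author: "crtpathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathways analysis for pair-matched CRTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtpathways)
```

## The scientific problem

Community-mobilisation interventions aim to reduce intimate partner violence
(IPV) not by enrolling individuals into programmes but by shifting the
normative climate of whole communities. Evaluations of such interventions are
pair-matched cluster-randomised trials (CRTs): communities are matched into
similar pairs, one community per pair receives the intervention, and
cross-sectional surveys of residents aged 18–49 are taken at baseline and
follow-up. Showing that the intervention reduced IPV is only half the
question; the other half is *how* — which community-, relationship- and
individual-level changes carried the effect. This package implements that
pathways analysis as a tested, reusable chain:

1. **Indicator construction** — item-level survey responses become binary
   composite indicators (the outcome and 27 candidate mediators) with
   correct eligibility denominators.
2. **Community aggregation** — community-level constructs (norms) are
   measured ecologically, as enumeration-area (EA) level prevalences.
3. **Intervention effects** — a pair-matched, covariate-adjusted
   cluster-level intention-to-treat (ITT) risk-ratio estimator.
4. **Mediator–outcome associations** — individual-level modified Poisson
   regression with cluster-robust variance.
5. **Mediation by attenuation** — how much of the intervention effect
   survives adjustment for each mediator, on the excess risk-ratio scale.

Because the motivating trial's individual-level data are available on
request only, the package ships a synthetic-data module whose ground truth
(a known mediated fraction) makes every stage testable.

## Composite indicators and denominators

Each indicator is a declarative rule over survey items: `any_of` an act list
("at least one of the following"), `all_of` several items, a qualifying
response set on a single item (`value_in`), a `negation`, or a shallow
`composite` (e.g. *responded to witnessed violence*: said they helped AND
reported at least one qualifying action). Eligibility predicates give each
indicator its denominator — partnered in the past year, cohabiting,
witnessed IPV, non-polygamous, or experiencing/perpetrating IPV — and
"where applicable" items carry a separate applicability predicate.
Every respondent × indicator cell is therefore in exactly one of four
states: `true`, `false`, `ineligible` (fails eligibility/applicability or is
the wrong reporter), or `missing`.

**Missingness policy** (the survey literature is rarely explicit here, so
the package documents its own): for `any_of` rules a missing item is
non-qualifying unless *all* items are missing, in which case the indicator
is missing and excluded from numerator and denominator; `all_of` and
`composite` rules with any missing component are missing; single-item rules
are missing when the item is. This is the conservative convention for
act-list violence measures: a woman who reports one act and skips the rest
still counts as experiencing IPV, while one who skips the whole battery is
not counted as a non-case.

## The cluster-level ITT estimator

With eight communities, individual-level models cannot carry the
between-community randomisation inference. The estimator therefore works at
the cluster level:

1. Fit an individual-level **logistic model of the outcome on covariates
   only** (age group, marital status, baseline EA-level outcome
   prevalence), pooled over both arms and *without* the arm term.
2. For each community \(j\), compute expected events
   \(E_j = \sum_{i \in j} \hat p_i\) and observed events \(O_j\); the ratio
   residual \(R_j = O_j / E_j\) carries the whole intervention contrast.
3. For each pair \(p\), form \(\ell_p = \log R_{I,p} - \log R_{C,p}\); the
   point estimate is \(\exp\) of the size-weighted mean of the \(\ell_p\)
   and the CI uses the t distribution with (pairs − 1) df.

Design choices worth stating: the combination is done on the **log scale**
(ratio estimands are symmetric there, and the t-based CI matches standard
cluster-summary methodology); pair weights are the **pair total sample
size** (a harmonic-mean-of-cluster-sizes option is provided); zero-event
clusters receive a 0.5 continuity correction to both \(O_j\) and \(E_j\),
flagged in the output; and the expected-events model deliberately excludes
the arm term — otherwise the residuals would be purged of the very contrast
being estimated. Since the model includes an intercept, the maximum
likelihood score equation forces \(\sum_j E_j = \sum_j O_j\), which the
tests verify numerically.

## Modified Poisson regression, from first principles

Associations and mediation models need adjusted risk ratios for binary
outcomes. Logistic regression gives odds ratios, which overstate risk
ratios at the outcome prevalences seen here (9–49%). The package therefore
fits **log-link Poisson regression on the binary outcome** ("modified
Poisson"): the coefficient exponentials are risk ratios, and the
misspecified Poisson variance is repaired by a cluster-robust sandwich.

Fitting is by iteratively reweighted least squares, written in the package
rather than delegated: both links are canonical, so the score is
\(X'(y-\mu)\) and the expected information \(A = X'WX\) with \(W\) the
variance function. The sandwich is \(A^{-1} B A^{-1}\) with
\(B = \sum_g s_g s_g'\), \(s_g\) the per-cluster score sum, multiplied by
the small-sample factor \(G/(G-1)\); the uncorrected form is retained too.
CIs use normal quantiles on the log scale (the trial reports give no df
correction). Numerical care: IRLS converges on relative coefficient change
below 1e−8 (max 100 iterations) with step-halving towards the previous
iterate whenever a full step would increase the deviance — log-link fits on
binary data genuinely oscillate without this. Fitted means above 1 are
legal for the log link and are counted and reported rather than hidden.
Separation or non-convergence is an explicit error carrying the step-norm
trace; an independently-coded `stats::glm` + `sandwich::vcovCL` pair serves
as the test oracle (coefficients to 1e−6, robust SEs to 1e−4), never as the
implementation.

Clustering is at the **EA level** — the sampling stage at which respondents
are correlated — and site-pair enters all individual-level models as fixed
effects. The interaction screen adds an arm × risk-factor product term and
Wald-tests it on the robust covariance; a product collinear with the main
effects (e.g. a risk factor identical to arm) is reported as untestable
rather than tested.

## Mediation by attenuation, and why the excess-RR scale

The mediation ledger compares the arm risk ratio from a base model
(site-pair, age group, marital status, baseline EA-level IPV prevalence) to
the same model with one mediator added. The percent attenuation is

\[ A = 100 \cdot \frac{RR_\text{med} - RR_\text{base}}{1 - RR_\text{base}}, \]

the share of the *excess* risk ratio removed by adjustment; positive values
mean the effect moved toward the null. Display rounding is
half-away-from-zero.

The scale matters and is pinned by a falsification test: for a base aRR of
0.44 moving to 0.83 after adjustment, the excess-RR scale gives 70% while a
log-RR reconstruction gives 77%. Across all 48 published (base, adjusted,
percent) triples of the motivating trial's mediation table, the excess-RR
formula reproduces every printed integer within one point; the log-RR
formula misses many rows by far more. The package computes attenuation with
no CI by default (none are published for this quantity); a cluster-bootstrap
CI is available as a clearly-labelled extension.

Community-level mediators enter individual models ecologically: each
respondent receives their own EA's prevalence of the mediator, divided by
10 so that risk ratios read "per 10 percentage-point change in community
prevalence". The respondent's own response is included in their EA
prevalence by default (the difference is O(1/n) at ~28 respondents per EA);
a leave-one-out switch is provided. The per-10 and per-1 entries are linked
by the exact identity \(RR_{10} = RR_1^{10}\), which the tests assert on
fitted models.

This is deliberately *not* a counterfactual mediation analysis: no natural
direct/indirect effects, no joint multi-mediator decomposition. With a web
of mutually reinforcing social variables measured cross-sectionally at
follow-up, single-mediator attenuation is an honest description of which
factors *play a role*, not a causal apportionment — confounding between
mediators can inflate individual attenuations.

## The synthetic trial generator

The generator emulates the motivating trial's design: 4 matched pairs
(8 communities), 12 single-sex EAs per community (half female, half male),
EA sizes from a discretised truncated normal with mean 28 on \[18, 35\]
(matching the only printed moments), respondents aged 18–49 with marital
status, education, childhood abuse exposure and eligibility flags, and two
cross-sectional waves. Community- and pair-level random effects are shared
between waves so that baseline EA prevalences are informative covariates;
the baseline wave has every arm coefficient forced to zero.

The data-generating process, per follow-up respondent \(i\) in EA \(e\) of
community \(c\) in pair \(p\):

* attitude logit: \(\eta_{ce} = \alpha + \delta \cdot \text{arm}_c + u_p +
  v_c + w_e\) with \(u, v, w\) normal; the individual's violence-accepting
  attitude is Bernoulli(\(\text{logit}^{-1}(\eta_{ce})\));
* the **realized EA norm** \(\bar a_e\) is the share of attitude-holders
  actually sampled in the respondent's EA;
* outcome risk: \(\pi_i = \text{clamp}\big(\pi_0 \exp\{x_i'\beta +
  (1-\lambda)\beta_a \text{arm} + \theta(\bar a_e - \bar a_{\text{ctrl}}) +
  \beta_{\text{att}} a_i\}\big)\), with \(\beta_a = \log 0.45\) by default
  and \(\lambda \in [0,1]\) the mediated fraction.

\(\theta\) is **calibrated by root-finding against a Monte-Carlo estimate**
of the marginal arm risk ratio (common random numbers, ~400k virtual
respondents), so the total marginal effect equals \(\exp(\beta_a)\) at every
\(\lambda\); `true_marginal_rr()` re-checks this with an independent draw of
at least 10^6 respondents, and the tests require agreement within 0.02 at
\(\lambda \in \{0, 0.5, 1\}\).

Two design choices deserve emphasis:

* **Risk model on the log link with clamping.** The estimands are risk
  ratios, so the DGP is multiplicative in risk; probabilities are clamped
  into (0,1) and the clamp rate is surfaced as a diagnostic (warning above
  a configurable threshold, default 2%). Under default settings the rate is
  ~0 except at high mediated fractions, where it stays in the low percents.
* **The norm pathway runs through the realized EA prevalence**, not the
  latent super-population norm. The measured mediator in the analysis *is*
  the EA prevalence; a pathway through the latent parameter would make the
  measured mediator an error-prone proxy (binomial noise at n≈28 dominates
  within-arm community variance), capping recoverable attenuation far below
  the generated mediated fraction. Scientifically this says a person's risk
  environment is the attitudes of the people actually around them — which
  is also what makes \(\lambda\) recoverable: at \(\lambda = 1\) the
  mediation ledger should, and does, attribute essentially the whole effect
  to the community norm.

Item-level responses are generated consistently with the latents: the
12-scenario acceptability battery contains at least one "yes" exactly when
the latent attitude is positive, the women's act list mirrors the latent
outcome, and the men's anonymous card equals it; single-item mediators are
drawn conditional on the attitude. Derived indicators therefore equal the
latent columns, which is itself a tested property, and lets large
simulation loops skip item generation without changing any latent draw
(each (wave, community, EA) owns its own seeded substream).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: reporting and recall bias, intervention dosage
heterogeneity, attrition and non-response, EA turnover between waves (the
same EAs appear in both waves here), mediator–mediator confounding beyond
what the single attitude latent induces, and any sex difference in the
outcome model. Recovery results on synthetic data validate the *estimators*,
not the substantive conclusions of any one trial.

Where the motivating trial gives no value, defaults are the package's own:
\(\sigma_\text{pair} = 0.30\), \(\sigma_\text{community} = 0.25\),
\(\sigma_\text{EA} = 0.25\) on the logit scale (chosen so that within-arm
EA-level prevalence spread, including binomial noise, lands near the
reported 7–13 percentage-point SDs), control-arm attitude prevalence 50%
with an intervention shift of −1.0 logits (reproducing the reported ~51% vs
~28% contrast), control outcome risk 0.30, and modest covariate effects.
The between-community variance values are explicitly artifact choices: the
trial reports only that inter-community variation increased over the study.

## Simulation sizes used by the tests and acceptance script

Estimator recovery runs at the default trial size (~2,700 respondents per
wave): 500 replicates for ITT recovery and CI coverage and for the
mediation ledger at \(\lambda \in \{0, 1\}\), and 400 null replicates for
the interaction-screen size, with fixed base seeds; unit tests use a
smaller two-pair configuration where only arithmetic, not power, is at
stake. The acceptance script re-runs the same checks at 200–300 replicates
seeded from its `--seed` argument. At these sizes the Monte-Carlo SE of the
mean ITT estimate is ~0.002 on the RR scale.

## Known limitations

* Inference for the cluster-level estimator rests on 4 pairs (3 df);
  simulation shows honest coverage under the generator's conditions, but
  heavy-tailed pair heterogeneity would strain it.
* Attenuation percentages carry no uncertainty by default; the bootstrap
  extension is approximate (it resamples EAs, not communities).
* The robust-Wald interaction screen is slightly liberal at 48 clusters
  (size ~0.06 in the sex-stratified variant); the shipped calibration runs
  on the pooled sample with 96 EA clusters.
* Quasi-separation (a zero-event covariate cell) is an explicit error, not
  a silently inflated fit; small subgroup analyses should coarsen
  categories before fitting.
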