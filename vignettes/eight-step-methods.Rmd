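---
title: "Methods: the eight-step assessment of meta-analytic significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the eight-step assessment of meta-analytic significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octostep)
```

## Why a multi-step assessment

A meta-analysis of randomised trials reported only as a pooled estimate with a
95% confidence interval and a P-value overstates what the data show. The
threshold for significance ignores how many primary outcomes were compared,
whether the accumulated number of participants is anywhere near what a
well-powered trial of the same question would need, how often the evidence was
re-tested as the review was updated, whether the result is actually more
compatible with the anticipated clinical effect than with no effect, and how
fragile it is to attrition, bias and selective publication. `octostep`
implements an operational eight-step procedure that confronts a pooled result
with all of these checks before statistical significance is declared, and only
then prompts a judgement of clinical significance.

`eight_steps(trials, outcomes, config)` is the fitting function; it returns a
classed object with one verdict per outcome, printable, summarisable and
serialisable to JSON/TSV. Every step is also exposed as a standalone function.

## Step 1 — pooling and the conservative-result rule

Per-trial effects (log relative risk by default; log odds ratio, risk
difference, mean difference, Hedges' g available) are pooled with the
inverse-variance fixed-effect model and the DerSimonian–Laird random-effects
model, the latter by default carried to Hartung–Knapp–Sidik–Jonkman (HKSJ)
variance with t-based inference. Both results are always reported; the model
with the *larger* P-value becomes the main result. Exact ties (no observed
heterogeneity) resolve to the random-effects model, whose assumption of
trial-to-trial variation is usually the more realistic. A weight-dominance
diagnostic flags fixed-effect analyses in which one or two trials carry at
least 80% (configurable) of the weight, the setting where random-effects
down-weighting of large trials misleads.

Numerical choices: the HKSJ variance is implemented unmodified (no
fixed-effect variance floor). When the weighted dispersion around the pooled
estimate is numerically zero — all trials identical — the HKSJ variance
degenerates to zero, and the DerSimonian–Laird standard error is reused with a
warning rather than reporting an impossible zero-width interval. Zero cells in
2x2 tables receive the conventional 0.5 added to all four cells of the
affected table; trials with zero events in both arms carry no information
about a ratio measure and are dropped from ratio pooling with a message.

## Step 2 — heterogeneity

Cochran's Q, I² = max(0, (Q−(k−1))/Q), the DerSimonian–Laird τ², and the
diversity D² = (v_R − v_F)/v_R (the between-trial share of the random-effects
variance, always ≥ I² on the same data) are reported. Whether trials should be
excluded for clinical heterogeneity is a judgement; the package only raises a
reporting flag when I² exceeds 50%.

## Step 3 — multiplicity

With m co-primary outcomes the true family-wise-adjusted threshold lies
between no adjustment and Bonferroni. The pragmatic halfway rule divides the
base threshold by (1+m)/2: with a 0.05 base, one primary outcome keeps 0.05,
two give 0.0333…, three give 0.025. The adjusted value is kept at full
precision internally and reported to four significant digits; the matching
confidence level 1 − α_adj is fed to the pooling functions so intervals widen
in step. The adjustment is applied to primary outcomes only; secondary
outcomes keep the base threshold and are labelled hypothesis-generating.
Outcomes measured at several time points are expected to pre-specify one
primary time point rather than adjust per time point.

## Step 4 — required information size and trial sequential analysis

The diversity-adjusted required information size (DIS) is the number of
participants a conclusive meta-analysis needs:

* dichotomous: n = 4 (z₁₋α/₂ + z₁₋β)² p̄(1−p̄) / (p_c − p_e)², with the
  experimental risk p_e implied by the anticipated effect and the anticipated
  control risk p_c, p̄ their mean;
* continuous: n = 4 (z₁₋α/₂ + z₁₋β)² σ² / MD²;
* DIS = ⌈n / (1 − D²)⌉.

The α entering the formula (and the spending function below) is the
multiplicity-adjusted value for primary outcomes; β defaults to 0.10 (0.20 is
the other conventional choice). When the primary model is random-effects, the
observed D² is used; if it is zero, a fallback diversity of 25% is substituted
and recorded, since zero observed heterogeneity in a small meta-analysis is
weak evidence of true homogeneity. When the primary model is fixed-effect the
between-trial variance is zero by assumption and no inflation is applied.

The cumulative z-curve re-pools the trials after each addition, ordered by
publication year (ties by trial id), giving z_k = θ̂_k/SE_k at information
fraction t_k = cumulative randomised participants / DIS. Information is
participant counts throughout; event-driven information is not implemented.
The random-effects z-curve uses DerSimonian–Laird z-statistics: the boundary
construction assumes asymptotically normal increments, so the HKSJ
t-adjustment enters only the step-1 inference, not the sequential monitoring.

Monitoring boundaries for benefit and harm spend the two-sided α over the
looks with the O'Brien–Fleming-type Lan–DeMets spending function
α*(t) = 2(1 − Φ(z₁₋α/₂/√t)), which spends almost nothing early and exactly α
at full information. Boundary values solve the first-crossing equations by
recursive numerical integration over the joint law of the sequential
z-statistics: the continuation sub-density is propagated on a trapezoid grid
(512 nodes per look by default; convergence was verified by doubling — the
two-look boundary changes by under 1e-5 between 512 and 8192 nodes, and the
test suite checks 2–5-look boundaries against an independent fixed-grid
Simpson implementation at 4001 nodes to 1e-3). When the incremental spending
at an early look underflows (below 1e-10) the boundary is reported at a
display cap of 8 and flagged. Looks beyond full information use the
conventional fixed-sample critical value: once t ≥ 1 the sequential adjustment
has nothing left to protect.

Futility uses a beta-spending function of the same O'Brien–Fleming type under
the drift implied by the anticipated effect and the DIS,
drift = (z₁₋α/₂ + z₁₋β)·√(DIS/n_raw), which is identical to the standard
information parameterisation θ_A√(DIS)/(2σ) for both outcome types. The
boundaries are *non-binding* — efficacy boundaries are computed ignoring the
wedge — because a binding construction would license stopping rules the
review authors never committed to; crossing the wedge rejects the anticipated
effect but never contributes to a claim of effect. On the benefit-oriented z
scale the wedge at look k is (−f_k, f_k), reported only where non-empty; it
closes at the conventional critical value at full information.

The TSA-adjusted confidence interval is θ̂ ± u·SE with u the current-look
boundary, equal to the conventional interval once t ≥ 1. Two sensitivity
reruns use, as anticipated effects, the meta-analysis point estimate and the
confidence limit closest to no effect; when that limit crosses the null no
information size is defined and the rerun is reported as not computable.

## Step 5 — Bayes factor

With the pooled estimate treated as normal with standard deviation SE under
both hypotheses, the Bayes factor against the anticipated effect μ_A is the
likelihood ratio

BF = φ(θ̂; 0, SE) / φ(θ̂; μ_A, SE) = exp[(μ_A² − 2 μ_A θ̂)/(2 SE²)].

It equals 1 exactly when θ̂ = μ_A/2 and decreases strictly as the observed
effect approaches the anticipated one. Values below 0.1 (data ten times more
compatible with the alternative) count as significant; if the DIS has not
been reached the verdict carries a caution note, since sparse data inflate
both P-values and Bayes factors. A sceptical sensitivity Bayes factor uses
the relative risk halfway between the anticipated ratio and 1.0; "halfway" is
ambiguous between the natural and the log scale, so the natural-ratio scale
is the default with a log-scale option (`sceptical_effect(scale = "log")`).
Bayes factors are computed for primary outcomes only.

## Step 6 — bias

A trial is overall low risk of bias only when all seven domains (sequence
generation, allocation concealment, blinding of participants/providers,
blinding of outcome assessors, incomplete outcome data, selective reporting,
funding) are judged low; *unclear counts as not-low*, deliberately
conservative. The low- vs high-risk subgroups are pooled separately under the
step-1 primary model and compared with Q_between on G−1 degrees of freedom;
the low-risk-only pooled result is designated the basis of the main
conclusion. Funding is exposed as a plain ternary judgement; no attempt is
made to grade mixed funding.

Attrition scenarios re-include participants lost to follow-up under extreme
imputations: best-worst (experimental losses get the beneficial outcome,
control losses the harmful one) and worst-best (the reverse), with
"beneficial" resolved through the outcome's benefit direction. Dichotomous
denominators become the randomised counts — intention-to-treat accounting,
since the losses are re-included with imputed outcomes. Continuous losses are
imputed at the observed group mean ± j·SD (j = 2 by default, 1 as
sensitivity) and the combined mean and SD are recomputed from exact sums and
sums of squares. The scenarios reuse the step-1 primary model rather than
re-running the conservative selection, so the scenario range isolates the
effect of the imputation.

## Step 7 — publication bias

Funnel-based assessment requires at least 10 trials; below that the block is
marked not assessed (the tests stay callable directly, with a warning).
Funnel data carry significance-contour bands at P = 0.10, 0.05, 0.01. Three
asymmetry tests are provided: Egger (OLS of θ/SE on 1/SE, intercept t-test
with k−2 df), Begg (tie-corrected Kendall correlation between
variance-stabilised deviates and variances, normal approximation), and the
Harbord score test for 2x2 tables (regression of Z/√V on √V; dichotomous
outcomes only, since the score and information are table quantities).
Trim-and-fill iterates fixed-effect centring with the L0 rank estimator
(R0 available), side chosen automatically from the signed-rank imbalance,
midranks for ties and zero deviations excluded; filled mirror-image studies
are pooled under both models and labelled hypothesis-generating. When no
trial is individually significant, asymmetry cannot plausibly be explained by
publication bias and the flag is suppressed.

## Step 8 — the significance gate and GRADE imprecision

An outcome is statistically significant only when all gates pass: the
conservative P-value beats the multiplicity-adjusted threshold; the
sequential boundaries for benefit or harm are crossed (or full information is
reached with |z| above the conventional threshold); and, for primary
outcomes, the Bayes factor is below its threshold. Only then is the
clinical-significance checklist emitted (effect size vs minimal clinically
relevant difference, benefit–harm balance, population extrapolation,
surrogate-outcome caveat, NNT for dichotomous outcomes). The checklist is
deliberately a prompt for judgement, not an automated decision.

The GRADE imprecision cascade rates the evidence from the TSA: with a
realistic anticipated effect, any boundary crossed means no downgrade and
none crossed means two levels; with an unrealistic anticipated effect the
analysis is repeated with the CI-limit effect (crossed: no downgrade), then
with the point estimate (crossed: one level; otherwise two). Whether the
anticipated effect is realistic cannot be derived from the data and is a
required field of the outcome specification (default `TRUE`, surfaced in the
report).

## The synthetic review generator

`simulate_review(sim_spec(...))` draws each trial's latent effect from
Normal(true effect, τ²), binomial arm counts from the control risk and the
effect-implied experimental risk (or normal summary statistics for continuous
outcomes), binomial losses removed from the analysed counts, and an optional
left-tail suppression rule that removes non-significant trials on the null
side with a given probability — the mechanism funnel-plot methods are meant
to detect. Sub-streams are indexed per trial so increasing k never reshuffles
earlier trials. The generator emulates summary-level trial data only: no
individual-patient data, no correlated multi-outcome structure, no
time-to-event outcomes, and its trials are exactly two-armed and unbiased
apart from the suppression rule. Passing tests on these fixtures therefore
demonstrates the arithmetic and the operating characteristics of the
procedure under its own assumptions, not robustness to the messiness of real
reviews (selective outcome reporting within trials, non-normal effect
distributions, correlated outcomes).

Default study conditions used by the operating-characteristic tests: the
type-I-error check runs 2,000 null meta-analyses of 10 trials (250 per arm,
control risk 0.2, ten equal-information looks, two-sided α = 0.05) and
requires the benefit/harm crossing fraction to stay at or below 6%;
τ² recovery uses k = 50–100 continuous trials of 150–200 per arm over
200–500 replicates, requiring the mean DerSimonian–Laird estimate within 15%
of truth. These sizes keep the whole suite within a few minutes on one CPU
while leaving Monte-Carlo error well inside the asserted margins.

## Known limitations

* No REML or Paule–Mandel τ² estimators; no meta-regression or network
  meta-analysis.
* Information is participant-based; event-driven TSA is not implemented.
* Hazard ratios are accepted only as pre-computed effect/SE records.
* The multiplicity rule ignores correlation between outcomes (it is rarely
  known); the halfway rule is a pragmatic bound, not an exact correction.
* Penalties for adaptive information-size estimation (anticipated effects
  derived from trials that re-enter the review) are not implemented; no
  defined method exists.
* The clinical-significance step is a checklist, never a verdict.
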