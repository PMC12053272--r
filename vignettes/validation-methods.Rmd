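---
title: "Methods: simulating and validating an adaptive executive-function battery"
author: "efbattery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and validating an adaptive executive-function battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`efbattery` packages two things that usually live apart: a faithful
implementation of the mechanics of a gamified, adaptive battery of
executive-function (EF) tasks, and the psychometric pipeline by which such a
battery is validated — test-retest reliability, partial-correlation network
structure with community detection, confirmatory factor comparison, multigroup
invariance, and concurrent validity. Because no participant data ship with the
package, a generative virtual-respondent cohort supplies data whose latent
structure is known exactly, so every stage of the pipeline can be checked
against ground truth at desk scale.

## The adaptive response window

Most tasks in the battery share a closed-loop staircase on the *response
window*: the deadline within which a correct response earns "green" feedback.
A correct response inside the window shortens it, an incorrect or late
response lengthens it:

* after the s-th consecutive correct-and-on-time trial the window shrinks by
  `10 ms * 2^s`,
* after the s-th consecutive incorrect-or-late trial it grows by
  `40 ms * 2^s`,

where `s` counts *previous* consecutive outcomes (so a streak's first step
uses `2^0`). Feedback is tri-color: green (correct, on time), yellow (correct,
late), red (incorrect). Yellow feeds the lapse streak, because increments
apply to "incorrect or late" alike.

With streak scaling disabled the window is a random walk with step −10 on
green and +40 otherwise. Zero drift requires `p·10 = (1−p)·40`, so the
stationary green rate is `40/(10+40) = 0.8` for any continuous response-time
distribution — the window self-titrates to each respondent's 80th percentile.
`equilibrium_rate()` exposes this closed form and the acceptance suite
verifies the Monte-Carlo rate to ±0.02 over 10,000 trials.

Numerical choices the source design leaves open, fixed here as defaults:
initial window 1500 ms; clamp bounds [200, 5000] ms (clamping never resets
streaks); streak exponent capped at 6, which is behaviorally invisible since
an uncapped seventh step would already exceed the clamp range; an omitted
response on a response-required trial classifies red (the battery defines no
separate omission class). The two continuous performance tasks bypass the
window entirely so that the deadline cannot itself redirect attention.

## Task battery

Eleven paradigms are implemented as trial-schedule generators plus
controllers: basic response time (right block then left block; its mean RT is
the processing-speed covariate, not a scored metric), forward and backward
spatial span, flanker, impulsive and sustained continuous performance (80%
and 20% targets), Stroop (4 response options), visual search in four fixed
blocks (feature-4, feature-12, conjunction-4, conjunction-12), cueing
(neutral/congruent/incongruent), task switching (50% switch), and
tap-and-trace (tap, dual, trace blocks; only the detection responses of the
tap and dual blocks generate records, and the metric uses the dual block
only). Condition counts honor the stated proportions exactly via
largest-remainder rounding. Per-block trial counts are unspecified by the
design and default to plausible 5-10 minute administrations (flanker 40,
Stroop 48, 50 per CPT, 4×16 search, 48 cueing, 48 switching, 2×20 basic RT,
3×30 tap-and-trace); all are configurable.

The spans start at sequence length 3 (range 3-9), advance after two
successful recalls in a row, and terminate after three consecutive failures;
the alternative "three correct, allow one miss" advancement described for a
related battery is implemented as a selectable variant, with the same
termination rule (the source states no other). At the cap the controller
stays at 9 until the failure criterion fires. *Object span* is the longest
length attempted on two consecutive trials — note that by this (verbatim)
definition the three terminal failures at a just-out-of-reach length count as
attempts, so a respondent who deterministically recalls up to length 5 scores
6. The controller is exhaustively equivalent to a brute-force simulator over
every success/failure string up to length 12.

## The virtual cohort

Ten scored task metrics get a latent ability vector `eta` drawn from a
multivariate normal whose precision matrix is *planted*: unit diagonal, so
partial correlations read back exactly as the negated off-diagonal entries.
The default plants three communities — set reconfiguration (both spans, task
switching), attentional control (both CPTs), interference resolution
(flanker, Stroop, search, cueing, tap-and-trace) — as rings at partial
correlation 0.30 plus eight bridge edges at 0.15, for 17 nonzero edges on 10
nodes (the edge count the pruned empirical network reportedly kept). The
older group sits 0.4 SD lower with scale 0.8 and *identical* edges, giving
the invariance ladder a planted equal-edges/different-moments configuration;
session-to-session stability is `eta_2 = 0.7·eta_1 + sqrt(1−0.49)·zeta`, and
the comparator battery is `0.45·eta_j + sqrt(1−0.45²)·noise`, so latent
retest reliability and concurrent validity are 0.70 and 0.45 by construction.

Trial behavior follows a lognormal-plus-lapse model: with small probability
the trial is an *anticipation* (uniform 80-199 ms, blind guess); otherwise
RT = `t0 + LogNormal(meanlog_task + condition_cost − 0.12·eta, sigma)` and
the response is correct with probability
`(1−lapse)·logistic(1.5·eta + b_condition) + lapse/n_options`. Span recall
succeeds with probability `logistic(1.2·(kappa − length))`,
`kappa = 5.8 + eta`. All constants live in one calibration file
(`inst/extdata/calibration.yaml`), chosen once so that simulated task means
land inside the ranges reported across the comparable-task literature (e.g.
basic RT ≈ 345 ms within 231-518; Stroop ≈ 715 ms within 594-818; object
span ≈ 6.3). Response correctness and RT do not depend on the current
window — the window only classifies timeliness — which is what makes the
stationary-rate algebra exact and trial generation vectorizable.

What the generator deliberately does **not** emulate: practice and fatigue
effects, diffusion-style speed-accuracy trade-offs within a trial,
item-level difficulty, device or platform heterogeneity, and real bad-actor
behavior (screening flags are planted at nominal rates merely so the rules
execute). Passing tests therefore demonstrate that the *pipeline* is correct
and well calibrated on data with known structure — not that real battery
data satisfy the model's assumptions.

## Scoring and cleaning

The cleaning cascade runs in the published order, and removal tallies are
conserved at every stage: (1) anticipatory trials (RT < 200 ms) out first;
(2) trials beyond 3 SDs of the individual's own mean RT, computed per
participant × task on stage-1 survivors (zero SD removes nothing); (3) task
scores; (4) scores dropped for fewer than 5 surviving trials in any
condition or below-chance accuracy — *strictly* below, so exactly-at-chance
is retained, and go/no-go tasks use hit-rate − false-alarm-rate ≤ 0 since
they have no symmetric option count; (5) score outliers beyond ±3 MAD of
the task median, with the 1.4826 normal-consistency constant (raw-MAD mode
available) and a zero MAD removing nothing.

Rate correct score (RCS) is computed as correct responses per second of
summed response time — the "average number of correct responses over one
second" reading; the literal product-of-trials reading is reconciled by
taking "total response time" as the per-trial mean (N × mean = sum) and is
available behind a config switch for sensitivity analysis.
Correct-but-late responses count as correct (the metric text carries no
timeliness qualifier). Mean-correct-RT metrics are oriented by −x/100, and
every scored metric is residualized on the hand-appropriate basic-RT mean
(two-hand average for two-hand tasks, dominant-hand block mean otherwise).

Test-retest reliability uses the two-way random-effects,
absolute-agreement, single-measures ICC — sessions are a random facet of
the design — with the consistency variant selectable, the F test of the
participant mean square against residual, and the 0.75/0.60/0.40
qualitative thresholds.

## Network, factor, and invariance estimation

The Gaussian graphical model is fit by maximum likelihood in the
`Sigma = Delta (I − Omega)^{-1} Delta` parametrization (Omega the
partial-correlation matrix, Delta the scalings). With complete data the
saturated solution is the analytic inverse of the ML covariance; with
missing data an EM algorithm maximizes the casewise ("full information")
normal likelihood and reduces to the analytic solution when nothing is
missing. Edges are pruned one-shot at two-sided p > .05 — Fisher-z with
effective sample size n − (p−2) — and the model is refit with those
entries fixed to zero. Zero partial correlation is zero concentration, so
the constrained refit uses the classical iterative conditional-regression
MLE for graphical models with structural zeros; it is exact (the implied
covariance reproduces the sample covariance on all free moments) and needs
no general-purpose optimizer. An iterative re-pruning mode is available by
feeding the pruned fit back in.

Fit indices follow the standard likelihood-ratio forms: `chi2 = 2(LL_sat −
LL_model)`; CFI against the independence baseline; `RMSEA =
sqrt(max(chi2−df,0)/(df(n−1)))` with the 90% CI from inverting the
noncentral chi-square distribution (root-bracketing on [0, 10·chi2]);
AIC/BIC count means, scalings, and free edges. The chi-square test's
empirical type-I error for a correctly specified pruned model is 0.05 ±
0.02 in the acceptance suite.

Communities come from the spin-glass search in its negative-weight
extension (igraph's implementation), replicated with distinct seeds —
default resolution γ = 1 and 10 spins, since the source names neither —
and partitions are canonicalized by order of first appearance before
frequency counting, so label permutations never split the count.
Disconnected components are partitioned separately; isolates form their
own communities. Edge stability uses a case-resampling bootstrap of the
entire saturated-prune-refit pipeline with 95% percentile intervals and
inclusion frequencies.

The confirmatory models are the correlated three-factor model (each task
on exactly one community-derived factor, factor correlations free) and the
bifactor model (a general factor on all ten tasks plus mutually orthogonal
specific factors), both identified by unit factor variance and fit by BFGS
on the ML discrepancy with analytic gradients and up to ten jittered
restarts. Residual variances are deliberately unbounded so improper
(Heywood) solutions remain observable: the two-indicator attentional-
control specific factor reliably drives one residual variance negative on
network-structured data, and the fit reports it as a warning naming the
variable rather than hiding it behind a bound (a bounded mode exists). On
the default cohort the pruned network beats both factor models on every
information criterion in the overwhelming majority of full-pipeline
replications — the qualitative ordering the validation design expects.

Invariance between groups fits four nested models on one shared pruned
sparsity pattern (estimated from the pooled within-group covariance):
unconstrained, equal edge weights, plus equal means, plus equal scalings.
Adjacent models are compared by chi-square likelihood-ratio tests with df
equal to the parameter-count difference, and all four by AIC/BIC, with the
preferred model reported separately per criterion since they can — and in
the planted scenario should — disagree with the raw LRT. The constrained
fits use analytic gradients of the multigroup −2 log-likelihood; the fully
constrained model has an exact pooled solution, as does the unconstrained
one (per-group refits). One caveat worth knowing: with ~37 simultaneous
constraints the plain LRT is mildly anticonservative at a few hundred
cases per group (empirical type-I ≈ 0.065 at 300/group, mean statistic
37.9 against 37 df); calibration is exact in the large-sample regime, and
the package reports the plain statistic as the source analyses do.

## Problem sizes and reproducibility

The test and acceptance workloads use the cohort scale of the source
design's adult arm — n = 600 for network, CFA, and invariance analyses,
n = 250 with two sessions for retest, n = 132 for concurrent validity —
with replication counts chosen so each check runs in seconds to a few
minutes: 200 replications for edge-recovery sensitivity, 500 for
chi-square calibration, 200 for invariance scenarios, 100 spinglass
replications on a fixed network, 50 full-pipeline model-comparison
replications, 1000 ICC replications. Every random stage derives its seed
deterministically from one run seed (`child_seed()`), so the full report
bundle is byte-identical across runs with the same seed, and changing one
stage's seed leaves the others' outputs untouched.

## Known limitations

Structure recovery through the full trial pipeline is attenuated relative
to ability-level data: trial noise shrinks the weaker bridge partial
correlations toward zero, so pruning at n = 600 retains roughly 80-85% of
planted edges from battery-derived scores versus ~98% from abilities. The
generative respondent is intentionally simple (no sequential dependencies,
no speed-accuracy coupling beyond the shared ability), span metrics are
coarse integers with restricted range (their lower retest reliability is a
property of the metric, as the source discusses), and the spinglass
frequency on a planted, well-separated structure is near 1.0 — higher than
the 85% reported for empirical data, as expected when the truth is clean.
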