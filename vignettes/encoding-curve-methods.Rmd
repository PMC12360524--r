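---
title: "Methods: sensitivity estimation and encoding-curve fitting for same-different discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitivity estimation and encoding-curve fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perclearn)
```

## The scientific question and the data model

perclearn analyses same-different discrimination experiments in which the
first stimulus of each pair is presented for a variable *encoding duration*
`t` and terminated by a backward mask, so that `t` controls how long
stimulus information is available for perceptual encoding. Across a
multi-session design — evaluation sessions interleaved with discrimination
training sessions, closed by a generalization session with novel exemplars
of the trained category — the package asks how training changes three
traits of early visual processing: the asymptotic sensitivity, the rate at
which information is extracted after stimulus onset, and the onset at which
information first becomes available.

The data unit is a trial: participant, session, trial index, encoding
duration, pair type (`same`/`different`), response (`same`/`different`/
`none`), and response time. The default schedule places training at
sessions 2, 3, 5, 6, 8, 9 (360 trials each, 100 ms encoding), evaluation at
sessions 1, 4, 7, 10 and generalization at session 11 (480 trials: 60 per
duration at 17, 50, 84, 117, 150, 234, 500, 1000 ms, half same, half
different).

Two filters precede all estimation. Trials are kept when the response time
lies in the closed interval [0.2, 5.0] s; the interval is closed so that
responses at the 5 s deadline remain analysable ("between 0.2 and 5.0 s"
does not by itself fix the endpoints, and excluding an exactly-at-deadline
response would be arbitrary). Participants are included when sensitivity
improved by at least 0.4 d' between the first session and the fifth
training session (session 8), with `>=` inclusive at the threshold.
Omitted responses are excluded from the hit/false-alarm counts and reported
separately; only responded trials enter the rates.

## Sensitivity for same-different data

"Different" pairs are the signal class: a hit is a "different" response to
a different pair and a false alarm a "different" response to a same pair.
The yes-no statistic `d' = z(H) - z(FA)` is invariant to swapping this
labelling, so the choice only fixes reporting conventions.

Because a same-different judgement involves two observations, the mapping
from (H, FA) to d' depends on the observer's decision rule, and the
package implements the three standard models:

* **yesno** — `d' = z(H) - z(FA)`, treating the task as a single-interval
  detection problem. Simple, but it underestimates the underlying
  discriminability of a same-different design.
* **differencing** — respond "different" when `|x1 - x2| > k`. The forward
  equations `FA = 2*pnorm(-k/sqrt(2))`,
  `H = pnorm((d'-k)/sqrt(2)) + pnorm((-d'-k)/sqrt(2))` are inverted by
  bracketed root finding on d' in [0, 10] (residual < 1e-9); the criterion
  follows in closed form from FA.
* **independent_observation** (default) — the likelihood-ratio rule. With
  equal-variance unit Gaussians at means 0 and d' and
  `g(x) = exp(d'(x - d'/2))`, the likelihood ratio of a pair is
  `LR = (g(x1) + g(x2)) / (1 + g(x1) g(x2))` and the observer responds
  "different" when `LR > beta`. For fixed `x1` the acceptance region in
  `x2` is a half-line, so the response probabilities reduce to
  one-dimensional integrals; these are evaluated by 64-node Gauss-Legendre
  quadrature after mapping through the normal CDF, split at the point
  where the inequality direction flips (a necessary split: at `beta = 1`
  the inner probability is a step function of `x1`, and unsplit quadrature
  is inaccurate there). At `beta = 1` the rule reduces to "the two
  observations fall on opposite sides of d'/2", which yields the classical
  unbiased maximum `pc = pnorm(d'/2)^2 + pnorm(-d'/2)^2` — an exact check
  used in the tests, together with million-sample Monte-Carlo simulation of
  the raw decision rule. Inversion solves the false-alarm equation for
  `ln beta` (monotone) inside a bracketed search for d' on [0.01, 10]; the
  log-likelihood-ratio scale is of order d'^2, so below d' = 0.01 the
  surface is numerically flat and such rate gaps are reported as d' = 0.

The default model is the independent-observation rule; the estimator used
for any given dataset is recorded in every estimate (`model`,
`correction` columns), since different rules imply systematically
different d' scales and results should never silently mix them.

**Extreme proportions.** With 30 same and 30 different trials per cell,
perfect cells occur regularly. The default correction is the half-count
rule (0 and 1 replaced by `1/(2N)` and `1 - 1/(2N)`), which puts the
ceiling for a 30-trial cell at `z(59/60) - z(1/60) = 4.256` in yes-no
units — comfortably above the largest group means the design produces, so
the ceiling does not truncate realistic data. The log-linear rule
(`(count + 0.5)/(N + 1)` everywhere) is available; `none` returns raw
proportions and flags degenerate cells instead of fabricating finite d'.

## The shifted-exponential encoding curve

Group-mean sensitivity as a function of encoding duration is modelled as

d'(t) = A (1 - exp(-R (t - I))) for t > I, and d'(t) = 0 otherwise,

with asymptote `A` (d' units), rate `R` (per ms internally; *reported*
multiplied by 1000 as d'/s, so 0.00708/ms prints as 7.08 d'/s) and onset
`I` (ms). The curve is continuous at `t = I`.

**Fitting.** `fit_encoding_curve()` minimises unweighted SSE over the box
A in [1, 10], R in [0.0001, 10] per ms, I in [1e-7, 500] ms using
Levenberg-Marquardt (`minpack.lm::nlsLM`, the standard R implementation of
the algorithm) from 64 starting points. Starts are a Latin hypercube over
the box, with the rate dimension sampled log-uniformly because its box
spans five decades — linear sampling would start almost every run in the
saturated-rate regime. The lowest-SSE converged solution wins; SSE ties
below 1e-10 are broken toward the smaller onset. Solutions at a bound are
flagged (`at_bound`), which matters for well-trained sessions whose onset
estimates sit at the lower bound.

**The objective is the smooth exponential.** By default the zero clamp
below the onset applies to *predictions* but not to the least-squares
objective (`clamp_objective = FALSE`). The two objectives differ only when
the onset exceeds the smallest duration, which happens for untrained
observers (onset near 15 ms, smallest duration 17 ms). The smooth
objective is the package default because it is what the field's standard
fitting pipelines (nlsLM on the bare model expression) actually minimise,
it keeps the objective differentiable — Levenberg-Marquardt assumes a
smooth residual surface — and it makes the fitted parameters of the
no-training session reproducible; the clamped objective is retained as an
option and the difference between the two is documented rather than
hidden.

**Goodness of fit and uncertainty.** `R^2 = 1 - SSE/SST` with SST about
the mean of the observed values. Standard errors come from the linearised
covariance `s^2 (J'J)^{-1}` at the optimum (`J` the Jacobian of the
predictions in the parameters, `s^2 = SSE/(n-3)`); this is the
conventional frequentist approximation for nonlinear least squares, and
the tests cross-check it against an analytic-Jacobian recomputation. When
`J'J` is singular — typically the onset at a bound with no leverage — the
standard errors are reported as undefined rather than propagated.

**Inversion.** The duration at which the curve reaches a target
sensitivity is closed-form, `t = I - ln(1 - target/A)/R`. The
conventional target d' = 1.68 corresponds to 80% correct for an unbiased
equal-variance yes-no observer via `d' = 2 z(pc)`.

## Inferential layer

Repeated-measures ANOVA is computed by the balanced within-subject
sums-of-squares decomposition, each effect tested against its own
subject-by-effect interaction. Greenhouse-Geisser epsilon and Mauchly's W
are computed per effect from the covariance of the contrast-transformed
scores (main effects in a two-factor design use the scores averaged over
the other factor; the interaction uses the Kronecker contrast basis). Both
uncorrected and corrected p values are always reported; the analysis
convention is to rely on the corrected value when Mauchly's test is
significant at .05. The one-factor path is cross-checked in the tests
against `stats::mauchly.test` and `anova.mlm(test = "Spherical")`, and the
two-factor path against `aov` with error strata.

Paired Cohen's d is the mean of the paired differences divided by their
SD — the variant that matches effect sizes reported alongside paired
tests; users comparing against pooled-SD variants should rescale. The
one-sample t-test accepts printed summary statistics (mean, SD, n) because
published results are often reproducible only from summaries.
Benjamini-Hochberg correction implements the step-up rule explicitly and
also returns monotone adjusted p values (identical to
`p.adjust(method = "BH")`); contrast families in the report apply the
correction within each family of related comparisons.

## The synthetic-observer generator

The simulator exists so that every pipeline stage has a ground truth. Each
observer owns per-session encoding-curve parameters drawn from normal
distributions truncated to the fit bounds around session-dependent
population means, with one latent quantile per parameter per observer so
that individual differences persist across sessions. Defaults follow the
design scale the analysis targets: 27 observers; population means equal to
the fitted group curves at the four training levels; between-subject SDs
(A: 0.5, R: 2.5 d'/s, I: 6 ms) chosen to produce per-cell group d' SDs of
roughly 0.3-0.9, the range real group tables show. Responses are drawn
from the configured decision model at an observer-specific criterion
(`ln beta ~ N(0, 0.3)`), a 1% lapse rate replaces responses with a fair
coin, 0.2% of trials are omissions, and response times are lognormal with
a 2% outlier mass placed outside the [0.2, 5] s window so the filter path
is always exercised. The training course of true d' at 100 ms is a
saturating exponential in training ordinal (start 1.0, end 2.1, rate 0.5
per session) — a simulator choice for generating plausible learning
curves, not a claim about any particular dataset. The generalization
session reuses session-10 parameters with a mild decrement (A x 0.97,
R x 0.89), mirroring the small drop seen with novel exemplars.

What the simulator does *not* emulate: sequential dependencies between
trials, attention or fatigue drifts within a session, stimulus-specific
difficulty, and non-stationary criteria. Passing parameter-recovery tests
therefore shows that the estimators are consistent under the stated
generating assumptions — not that real data satisfy those assumptions.

## Problem sizes and numerical choices in the tests

The test suite fits the five bundled group-mean datasets, checks the
Levenberg-Marquardt solutions against a 50x50x50 grid-search oracle over
the parameter box, verifies both same-different forward models against
10^6-sample Monte-Carlo simulation of their decision rules (3 Monte-Carlo
SEs), and runs a 20-seed parameter-recovery study at the design scale (27
observers, 60 trials per duration, session-10 parameters), requiring the
group curve back within A ± 0.15, R ± 15%, I ± 10 ms in at least 16 of 20
seeds. Recovery is scored against each seed's *realized* generating
parameters — the mean of the sampled observer curves, which the study
manifest records — because with 27 observers the sample mean of the
generating asymptote alone has a standard error of about 0.1 d', and
scoring against the nominal population value would measure that sampling
noise rather than estimation error. Recovery is not exact by construction: averaging heterogeneous
exponentials biases the group rate slightly downward, lapses compress
extreme rates, and the half-count correction pulls ceiling cells inward —
the tolerance band is the honest envelope of those effects at this design
scale. The independent-observation inversion memoises results per (H, FA)
pair, since count data on a fixed trial budget produce at most
(N+1)^2 distinct rate pairs.

## Known limitations

* The independent-observation inversion treats rate gaps below d' = 0.01
  as zero sensitivity; at 60-trial cells this is far below measurement
  resolution.
* Parameter standard errors are linearised approximations; near-bound
  onsets make them optimistic.
* Onset estimates are extrapolations below the smallest measured duration
  and inherit the model's functional form; they are lower limits, not
  direct measurements.
* The generalization-session fit inherits the precision of its input
  means; means printed to two decimals do not pin down the rate and onset
  to published precision (the asymptote and R^2 are stable).

## A worked example

```{r example, eval = FALSE}
ref <- load_reference_sensitivity()
fits <- fit_report_from_table(ref)
fits[["1"]]
inversion_table(fits, target_dprime = dprime_from_pc(0.80))
```

Simulating and analysing a complete study end to end:

```{r pipeline, eval = FALSE}
cfg <- simulation_config(n_participants = 27, seed = 1)
study <- simulate_study(cfg)
report <- run_analysis(study$trials, analysis_config())
report$group_table
report$inversions
```
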