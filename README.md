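# perclearn

Signal-detection and encoding-curve analysis of perceptual learning in
same-different discrimination experiments.

## What problem this solves

In masked same-different tasks, the first stimulus of a pair is shown for a
controlled *encoding duration* `t` (milliseconds) and then terminated by a
backward mask, so performance as a function of `t` traces how quickly
stimulus information becomes available to the observer. perclearn is for
researchers running such designs across multi-session training studies: it
takes trial-level behavioral logs and produces participant- and group-level
sensitivity estimates, fitted encoding curves per training level, and the
accompanying inferential statistics — or, given only a published table of
group means, reproduces the curve fits directly.

The core model is the shifted-exponential encoding curve

    d'(t) = A (1 − e^(−R (t − I)))   for t > I,   d'(t) = 0 otherwise

where `A` is asymptotic sensitivity (d'), `R` the rate of information
extraction (reported as d'/s) and `I` the onset of information availability
(ms). Sensitivity itself is computed from hit and false-alarm rates under a
same-different decision model — the likelihood-ratio
(independent-observation) rule by default, with the differencing rule and
plain yes-no `d' = z(H) − z(FA)` as alternatives — after a closed-interval
[0.2, 5.0] s response-time filter and a half-count correction for extreme
proportions. Curves are fitted by bounded multi-start Levenberg-Marquardt
least squares; inference uses repeated-measures ANOVA with
Greenhouse-Geisser correction, paired/one-sample t-tests with Cohen's d,
and Benjamini-Hochberg FDR control. A synthetic-observer simulator
generates complete studies with known parameters, so every stage is
validated by parameter recovery.

## Worked example

Fit the bundled group-mean sensitivities (four evaluation sessions of a
Kanji discrimination training study, n = 27, plus its generalization
session, n = 16) and invert the fitted curves at the 80%-correct criterion:

```r
library(perclearn)

ref  <- load_reference_sensitivity()
fits <- fit_report_from_table(ref)
fits[["1"]]
#> Shifted-exponential encoding curve (n = 8 points)
#>   asymptote A = 2.884 d'   (SE 0.118)
#>   rate      R = 7.08 d'/s (SE 0.93)
#>   onset     I = 14.71 ms   (SE 6.53)
#>   R^2 = 0.9844, SSE = 0.1082

inversion_table(fits[c("1", "4")], target_dprime = dprime_from_pc(0.80))
#>   session target_dprime duration_ms
#> 1       1      1.683242   138.46420
#> 2       4      1.683242    59.91535
```

Read: before training, sensitivity saturates at d' ≈ 2.9, information
extraction proceeds at ≈ 7 d'/s, and nothing is available before ≈ 15 ms;
the 80%-correct level (d' = 1.68) needs ≈ 140 ms of encoding. After two
training sessions (session 4) the same level is reached in ≈ 60 ms.

A full pipeline run on simulated data:

```r
cfg    <- simulation_config(n_participants = 27, seed = 1)
study  <- simulate_study(cfg)
report <- run_analysis(study$trials, analysis_config())
report$group_table    # mean ± SD d' per session × duration
report$fits           # five fitted encoding curves
report$inversions     # durations at the target d'
```

A thin command-line interface over the same functions is in
`inst/scripts/perclearn-cli.R` (subcommands `simulate`, `sensitivity`,
`fit`, `run`).

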