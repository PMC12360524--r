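## Signal-detection sensitivity for same-different data.
##
## Three decision models are supported:
##   yesno                    d' = z(H) - z(FA)
##   differencing             respond "different" when |x1 - x2| > k
##   independent_observation  likelihood-ratio rule on the observation pair
##
## The independent-observation forward model integrates the likelihood-ratio
## decision region exactly (to quadrature accuracy); see the methods vignette
## for the derivation.

SDT_MODELS <- c("independent_observation", "differencing", "yesno")
RATE_CORRECTIONS <- c("half_count", "log_linear", "none")

#' Correct hit/false-alarm proportions for extreme counts
#'
#' Raw proportions of 0 or 1 make d' infinite. `half_count` replaces 0 and 1
#' by 1/(2N) and 1 - 1/(2N) with the cell's own trial count; `log_linear`
#' applies (count + 0.5)/(N + 1) to every cell; `none` returns raw
#' proportions and flags degenerate ones.
#'
#' @param n_hit,n_different_trials Hit count and number of different-pair
#'   trials (signal trials).
#' @param n_fa,n_same_trials False-alarm count and number of same-pair
#'   trials (noise trials).
#' @param method Correction method.
#' @return List of class `rate_estimate`: `h`, `f`, `correction`,
#'   `degenerate` (logical) and the source counts.
#' @export
correct_rates <- function(n_hit, n_different_trials, n_fa, n_same_trials,
                          method = c("half_count", "log_linear", "none")) {
  method <- match.arg(method)
  stopifnot(n_different_trials >= 1, n_same_trials >= 1,
            n_hit >= 0, n_hit <= n_different_trials,
            n_fa >= 0, n_fa <= n_same_trials)
  half <- function(k, n) {
    p <- k / n
    if (p == 0) 1 / (2 * n) else if (p == 1) 1 - 1 / (2 * n) else p
  }
  h <- switch(method,
              none = n_hit / n_different_trials,
              half_count = half(n_hit, n_different_trials),
              log_linear = (n_hit + 0.5) / (n_different_trials + 1))
  f <- switch(method,
              none = n_fa / n_same_trials,
              half_count = half(n_fa, n_same_trials),
              log_linear = (n_fa + 0.5) / (n_same_trials + 1))
  degenerate <- method == "none" && (h %in% c(0, 1) || f %in% c(0, 1))
  structure(list(h = h, f = f, correction = method, degenerate = degenerate,
                 counts = list(n_hit = n_hit,
                               n_different_trials = n_different_trials,
                               n_fa = n_fa, n_same_trials = n_same_trials)),
            class = "rate_estimate")
}

check_rates <- function(h, f) {
  if (!(h > 0 && h < 1 && f > 0 && f < 1))
    stop("rates must lie strictly in (0,1); apply correct_rates() first")
}

new_sensitivity <- function(dprime, model, criterion, h, f)
  structure(list(dprime = dprime, model = model, criterion = criterion,
                 h = h, f = f), class = "sensitivity_estimate")

#' Yes-no d'
#'
#' `d' = z(h) - z(f)`; the criterion returned is `c = -(z(h) + z(f))/2`.
#' Unlike the same-different models this may be negative (h < f).
#'
#' @param h,f Hit and false-alarm rates in (0,1).
#' @return A `sensitivity_estimate`.
#' @export
dprime_yesno <- function(h, f) {
  check_rates(h, f)
  new_sensitivity(qnorm(h) - qnorm(f), "yesno", -(qnorm(h) + qnorm(f)) / 2, h, f)
}

#' Forward differencing model
#'
#' Response probabilities of the differencing rule (respond "different" when
#' `|x1 - x2| > k`, observations unit-variance Gaussian, means 0 and d'):
#' `FA = 2 * pnorm(-k/sqrt(2))` and
#' `H = pnorm((d' - k)/sqrt(2)) + pnorm((-d' - k)/sqrt(2))`.
#'
#' @param dprime Sensitivity (>= 0).
#' @param k Decision criterion on the absolute difference (>= 0).
#' @return Named vector `c(h, f)`.
#' @export
samediff_differencing_rates <- function(dprime, k) {
  c(h = pnorm((dprime - k) / sqrt(2)) + pnorm((-dprime - k) / sqrt(2)),
    f = 2 * pnorm(-k / sqrt(2)))
}

#' Differencing-model d'
#'
#' Inverts the differencing rule: the criterion follows directly from the
#' false-alarm rate, `k = -sqrt(2) * qnorm(f/2)`, and d' is found by
#' bracketed root finding of the hit-rate equation on \[0, 10\] to
#' |residual| < 1e-9. By convention `h <= f` maps to d' = 0.
#'
#' @inheritParams dprime_yesno
#' @return A `sensitivity_estimate` with the criterion `k`.
#' @export
dprime_samediff_differencing <- function(h, f) {
  check_rates(h, f)
  k <- -sqrt(2) * qnorm(f / 2)
  if (h <= f) return(new_sensitivity(0, "differencing", k, h, f))
  g <- function(d) samediff_differencing_rates(d, k)[["h"]] - h
  if (g(10) < 0)
    stop("outside model range: hit rate unreachable with d' in [0, 10]")
  d <- uniroot(g, c(0, 10), tol = 1e-12)$root
  new_sensitivity(d, "differencing", k, h, f)
}

## ---- independent-observation (likelihood-ratio) model ----------------------
##
## Observations x1, x2 are unit-variance Gaussians with mean 0 (stimulus A)
## or d' (stimulus B). Same pairs are <A,A> or <B,B> (equiprobable),
## different pairs <A,B> or <B,A>. With g(x) = exp(d'(x - d'/2)) the
## likelihood ratio different:same is LR = (g(x1) + g(x2)) / (1 + g(x1)g(x2));
## the observer responds "different" when LR > beta. For fixed x1 the region
## in x2 is a half-line, so the outer integral is one-dimensional; it is
## split at the point where the inequality direction flips (ln beta +
## d'(x1 - d'/2) = 0) and each smooth piece is integrated by Gauss-Legendre
## quadrature mapped through the normal CDF. At beta = 1 the rule reduces to
## "x1, x2 on opposite sides of d'/2", giving the classic unbiased maximum
## pc = pnorm(d'/2)^2 + pnorm(-d'/2)^2.

.gl_nodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(64, 0, 1)
    cache
  }
})

## P(respond "different") when x1 ~ N(mu1,1), x2 ~ N(mu2,1)
lr_pdifferent <- function(dprime, lnbeta, mu1, mu2) {
  gl <- .gl_nodes()
  ustar <- pnorm(dprime / 2 - lnbeta / dprime - mu1)  # where 1 - beta*g1 flips
  pfun <- function(u) {
    ## keep quadrature nodes strictly inside (0,1): the mapped endpoints can
    ## round to 0 or 1 when the split point sits in an extreme tail
    u <- pmin(pmax(u, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
    x1 <- mu1 + qnorm(u)
    L1 <- dprime * (x1 - dprime / 2)              # log g(x1)
    apos <- lnbeta + L1 < 0                       # sign of 1 - beta*g1
    ## log threshold on g2: thr = (beta - g1)/(1 - beta*g1), computed in
    ## log space so extreme criteria do not overflow
    logthr <- rep(NA_real_, length(u))
    i <- apos & L1 < lnbeta                       # a>0, b>0
    logthr[i] <- lnbeta + log1p(-exp(L1[i] - lnbeta)) -
      log1p(-exp(lnbeta + L1[i]))
    j <- !apos & L1 > lnbeta                      # a<0, b<0
    logthr[j] <- L1[j] + log1p(-exp(lnbeta - L1[j])) -
      (lnbeta + L1[j]) - log1p(-exp(-(lnbeta + L1[j])))
    p <- numeric(length(u))
    x2thr <- dprime / 2 + logthr / dprime
    p[i] <- pnorm(mu2 - x2thr[i])                 # need g2 > thr
    p[apos & !i] <- 1                             # thr <= 0: always different
    p[j] <- pnorm(x2thr[j] - mu2)                 # need g2 < thr
    p[!apos & !j] <- 0                            # thr <= 0: never different
    p
  }
  lo <- if (ustar > 0) sum(gl$w * pfun(gl$x * ustar)) * ustar else 0
  hi <- if (ustar < 1) sum(gl$w * pfun(ustar + gl$x * (1 - ustar))) * (1 - ustar) else 0
  lo + hi
}

#' Forward independent-observation model
#'
#' Hit and false-alarm probabilities of the likelihood-ratio decision rule
#' for a same-different pair of independent equal-variance Gaussian
#' observations, at sensitivity `dprime` and criterion `exp(lnbeta)`.
#' `lnbeta = 0` is the unbiased observer, for which
#' `h = 1 - f = pnorm(dprime/2)^2 + pnorm(-dprime/2)^2`.
#'
#' @param dprime Sensitivity (> 0; at 0 the likelihood ratio is flat and the
#'   model returns `h = f = 0.5`, a guessing observer).
#' @param lnbeta Log likelihood-ratio criterion.
#' @return Named vector `c(h, f)`.
#' @export
samediff_independent_rates <- function(dprime, lnbeta) {
  if (dprime < 1e-8) return(c(h = 0.5, f = 0.5))
  h <- lr_pdifferent(dprime, lnbeta, 0, dprime)
  f <- 0.5 * (lr_pdifferent(dprime, lnbeta, 0, 0) +
                lr_pdifferent(dprime, lnbeta, dprime, dprime))
  c(h = h, f = f)
}

#' Independent-observation d'
#'
#' Inverts the likelihood-ratio (independent-observation) decision rule:
#' finds the (d', ln beta) pair whose forward response probabilities equal
#' the observed rates. For fixed d' the false-alarm equation is solved for
#' ln beta (monotone), then d' by bracketed root finding on \[0, 10\];
#' residuals below 1e-9. By convention `h <= f` maps to d' = 0.
#'
#' @inheritParams dprime_yesno
#' @return A `sensitivity_estimate`; `criterion` is ln beta.
#' @export
## memoization for the independent-observation inversion: count data on a
## fixed trial budget produce few distinct (h, f) pairs, so repeated cells
## are resolved once
.indep_cache <- new.env(parent = emptyenv())

dprime_samediff_independent <- function(h, f) {
  check_rates(h, f)
  key <- paste(format(h, digits = 17), format(f, digits = 17))
  hit <- .indep_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- dprime_samediff_independent_impl(h, f)
  .indep_cache[[key]] <- out
  out
}

dprime_samediff_independent_impl <- function(h, f) {
  if (h <= f) return(new_sensitivity(0, "independent_observation", 0, h, f))
  solve_lnbeta <- function(d) {
    g <- function(l) samediff_independent_rates(d, l)[["f"]] - f
    lo <- -2; hi <- 2
    while (isTRUE(g(hi) > 0) && hi < 400) hi <- hi * 2  # f decreasing in lnbeta
    while (isTRUE(g(lo) < 0) && lo > -400) lo <- lo * 2
    uniroot(g, c(lo, hi), tol = 1e-13)$root
  }
  gh <- function(d) samediff_independent_rates(d, solve_lnbeta(d))[["h"]] - h
  ## below d' ~ 0.01 the likelihood-ratio surface is flat (log LR scales
  ## with d'^2) and h -> f; a rate gap that small is indistinguishable
  ## from zero sensitivity
  if (gh(0.01) >= 0)
    return(new_sensitivity(0, "independent_observation", solve_lnbeta(0.01),
                           h, f))
  if (gh(10) < 0)
    stop("outside model range: rates unreachable with d' in [0, 10]")
  d <- uniroot(gh, c(0.01, 10), tol = 1e-9)$root
  new_sensitivity(d, "independent_observation", solve_lnbeta(d), h, f)
}

#' Sensitivity estimate dispatcher
#'
#' @param h,f Corrected rates.
#' @param model One of `"independent_observation"`, `"differencing"`,
#'   `"yesno"`.
#' @return A `sensitivity_estimate`.
#' @export
dprime_estimate <- function(h, f, model = SDT_MODELS) {
  model <- match.arg(model)
  switch(model,
         yesno = dprime_yesno(h, f),
         differencing = dprime_samediff_differencing(h, f),
         independent_observation = dprime_samediff_independent(h, f))
}

#' Per-cell sensitivity table
#'
#' Tallies hits and false alarms per grouping cell (via
#' [summarize_counts()]), corrects the rates and estimates d' under the
#' requested decision model. Cells with fewer responded trials than
#' `min_trials` are estimated but flagged; empty cells are absent from the
#' output (never fabricated). The input is expected to be RT-filtered
#' already.
#'
#' @param table A `trial_table`.
#' @param model Decision model.
#' @param correction Extreme-proportion correction (see [correct_rates()]).
#' @param grouping Cell-defining trial fields.
#' @param min_trials Minimum responded trials per cell before flagging.
#' @return Data frame with the grouping columns plus `n_trials`, `h`, `f`,
#'   `dprime`, `criterion`, `model`, `correction`, `flagged`.
#' @export
sensitivity_table <- function(table, model = SDT_MODELS,
                              correction = RATE_CORRECTIONS,
                              grouping = c("participant_id", "session_index",
                                           "encoding_duration_ms"),
                              min_trials = 10L) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  counts <- summarize_counts(table, grouping)
  keep <- counts$n_different_trials >= 1 & counts$n_same_trials >= 1
  counts <- counts[keep, , drop = FALSE]
  est <- lapply(seq_len(nrow(counts)), function(i) {
    rt <- correct_rates(counts$n_hit[i], counts$n_different_trials[i],
                        counts$n_fa[i], counts$n_same_trials[i], correction)
    dprime_estimate(rt$h, rt$f, model)
  })
  out <- counts[grouping]
  out$n_trials <- counts$n_different_trials + counts$n_same_trials
  out$h <- vapply(est, `[[`, numeric(1), "h")
  out$f <- vapply(est, `[[`, numeric(1), "f")
  out$dprime <- vapply(est, `[[`, numeric(1), "dprime")
  out$criterion <- vapply(est, `[[`, numeric(1), "criterion")
  out$model <- model
  out$correction <- correction
  out$flagged <- out$n_trials < min_trials
  rownames(out) <- NULL
  out
}

#' Serialize a sensitivity table
#'
#' @param sens Data frame from [sensitivity_table()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_sensitivity_table <- function(sens, path) {
  utils::write.table(sens, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
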