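## Inferential layer: balanced within-subject ANOVA with sphericity
## handling, t-tests with effect sizes, Benjamini-Hochberg FDR control and
## normality checks.

## orthonormal contrast basis (k-1 x k) orthogonal to the unit vector
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)          # k x (k-1)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  t(C)
}

## Greenhouse-Geisser epsilon and Mauchly test for one effect. `Y` holds
## per-subject scores: raw cell scores (one column per level, an orthonormal
## contrast basis is applied here) or, with `transformed = TRUE`, scores
## already projected onto the effect's contrast space.
sphericity_stats <- function(Y, transformed = FALSE) {
  n <- nrow(Y)
  p <- if (transformed) ncol(Y) else ncol(Y) - 1
  if (p < 2)
    return(list(epsilon = 1, mauchly_W = 1, mauchly_p = NA_real_))
  M <- if (transformed) stats::cov(Y) else {
    C <- orthonormal_contrasts(ncol(Y))
    C %*% stats::cov(Y) %*% t(C)
  }
  eps <- sum(diag(M))^2 / (p * sum(M^2))
  W <- det(M) / (sum(diag(M)) / p)^p
  if (!is.finite(W) || W <= 0) {
    mp <- NA_real_
  } else {
    ## chi-square approximation with the second-order series term, as in
    ## the classical Mauchly test (k = number of original levels)
    k <- if (transformed) p + 1 else ncol(Y)
    nd <- n - 1
    rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nd)
    w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * k + 2) /
      (288 * (nd * p * rho)^2)
    z <- -nd * rho * log(W)
    f <- p * (p + 1) / 2 - 1
    pr1 <- pchisq(z, f, lower.tail = FALSE)
    pr2 <- pchisq(z, f + 4, lower.tail = FALSE)
    mp <- pr1 + w2 * (pr2 - pr1)
  }
  list(epsilon = eps, mauchly_W = W, mauchly_p = mp)
}

#' Repeated-measures ANOVA (one or two within-subject factors)
#'
#' Balanced, complete within-subject sums-of-squares decomposition with
#' per-effect Greenhouse-Geisser epsilon, Mauchly sphericity test and
#' partial eta squared. Each effect is tested against its own
#' subject-by-effect error term. Both uncorrected and Greenhouse-Geisser
#' corrected p values are always reported; the convention is to rely on the
#' corrected value when Mauchly's test is significant.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the participant identifier column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @return Data frame of class `rm_anova`: one row per effect with columns
#'   `effect`, `df_num`, `df_den`, `F`, `p_uncorrected`, `gg_epsilon`,
#'   `df_num_gg`, `df_den_gg`, `p_gg`, `partial_eta_sq`, `mauchly_W`,
#'   `mauchly_p`.
#' @export
rm_anova <- function(data, dv, subject, within) {
  stopifnot(length(within) %in% 1:2,
            all(c(dv, subject, within) %in% names(data)))
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  levs <- lapply(data[within], levels)
  if (any(vapply(levs, length, 1L) < 2)) stop("each factor needs >= 2 levels")
  ## complete balanced check + cell matrix (subjects x cells)
  f <- if (length(within) == 1) data[[within[1]]] else
    interaction(data[[within[1]]], data[[within[2]]], lex.order = TRUE)
  tab <- table(data[[subject]], f)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop(sprintf("design not complete/balanced: participant %s, cell %s",
                 rownames(tab)[bad[1]], colnames(tab)[bad[2]]))
  }
  n <- nlevels(data[[subject]])
  Y <- matrix(NA_real_, n, nlevels(f),
              dimnames = list(levels(data[[subject]]), levels(f)))
  Y[cbind(as.integer(data[[subject]]), as.integer(f))] <- data[[dv]]
  grand <- mean(Y)
  subj_mean <- rowMeans(Y)

  one_effect <- function(name, Yeff, df_num, df_den, ss_eff, ss_err,
                         transformed = FALSE) {
    Fv <- if (ss_err == 0 && ss_eff == 0) 0 else
      (ss_eff / df_num) / (ss_err / df_den)
    sph <- sphericity_stats(Yeff, transformed)
    p_unc <- pf(Fv, df_num, df_den, lower.tail = FALSE)
    p_gg <- pf(Fv, sph$epsilon * df_num, sph$epsilon * df_den,
               lower.tail = FALSE)
    data.frame(effect = name, df_num = df_num, df_den = df_den, F = Fv,
               p_uncorrected = p_unc, gg_epsilon = sph$epsilon,
               df_num_gg = sph$epsilon * df_num,
               df_den_gg = sph$epsilon * df_den, p_gg = p_gg,
               partial_eta_sq = if (ss_eff + ss_err == 0) 0 else
                 ss_eff / (ss_eff + ss_err),
               mauchly_W = sph$mauchly_W, mauchly_p = sph$mauchly_p)
  }

  if (length(within) == 1) {
    k <- ncol(Y)
    cond_mean <- colMeans(Y)
    ss_eff <- n * sum((cond_mean - grand)^2)
    ss_subj <- k * sum((subj_mean - grand)^2)
    ss_tot <- sum((Y - grand)^2)
    ss_err <- ss_tot - ss_eff - ss_subj
    out <- one_effect(within[1], Y, k - 1, (n - 1) * (k - 1), ss_eff, ss_err)
  } else {
    a <- length(levs[[1]]); b <- length(levs[[2]])
    idxA <- rep(seq_len(a), each = b)   # lex.order = TRUE: A slow, B fast
    idxB <- rep(seq_len(b), times = a)
    YA <- t(apply(Y, 1, function(r) tapply(r, idxA, mean)))  # n x a
    YB <- t(apply(Y, 1, function(r) tapply(r, idxB, mean)))  # n x b
    mA <- colMeans(YA); mB <- colMeans(YB)
    cellm <- colMeans(Y)                                      # length a*b
    ss_A <- n * b * sum((mA - grand)^2)
    ss_B <- n * a * sum((mB - grand)^2)
    ss_AB <- n * sum((cellm - mA[idxA] - mB[idxB] + grand)^2)
    ## error terms
    ss_sA <- b * sum((YA - outer(subj_mean, rep(1, a)) -
                        outer(rep(1, n), mA) + grand)^2)
    ss_sB <- a * sum((YB - outer(subj_mean, rep(1, b)) -
                        outer(rep(1, n), mB) + grand)^2)
    ss_tot <- sum((Y - grand)^2)
    ss_subj <- a * b * sum((subj_mean - grand)^2)
    ss_sAB <- ss_tot - ss_subj - ss_A - ss_B - ss_AB - ss_sA - ss_sB
    ## effect-specific transformed scores for sphericity
    CA <- orthonormal_contrasts(a); CB <- orthonormal_contrasts(b)
    avgB <- kronecker(diag(a), matrix(1 / b, 1, b))   # a x ab
    avgA <- kronecker(matrix(1 / a, 1, a), diag(b))   # b x ab
    out <- rbind(
      one_effect(within[1], Y %*% t(avgB), a - 1, (n - 1) * (a - 1),
                 ss_A, ss_sA),
      one_effect(within[2], Y %*% t(avgA), b - 1, (n - 1) * (b - 1),
                 ss_B, ss_sB),
      one_effect(paste(within, collapse = ":"),
                 Y %*% t(kronecker(CA, CB)),
                 (a - 1) * (b - 1), (n - 1) * (a - 1) * (b - 1),
                 ss_AB, ss_sAB, transformed = TRUE))
  }
  rownames(out) <- NULL
  structure(out, class = c("rm_anova", "data.frame"))
}

t_result <- function(t, df, p, ci, d, kind, mean_val, se) {
  structure(list(t = t, df = df, p_two_tailed = p, ci_low = ci[1],
                 ci_high = ci[2], cohens_d = d, kind = kind,
                 estimate = mean_val, se = se),
            class = "t_test_result")
}

t_from_summary <- function(m, s, n, mu0, kind) {
  if (n < 2) stop("need n >= 2")
  if (s == 0) {
    if (m == mu0)
      return(t_result(0, n - 1, 1, c(mu0, mu0), 0, kind, m, 0))
    stop("degenerate: zero variance with nonzero mean difference")
  }
  se <- s / sqrt(n)
  tv <- (m - mu0) / se
  df <- n - 1
  p <- 2 * pt(abs(tv), df, lower.tail = FALSE)
  crit <- qt(0.975, df)
  t_result(tv, df, p, c(m - crit * se, m + crit * se), (m - mu0) / s, kind,
           m, se)
}

#' Paired t-test with Cohen's d
#'
#' Two-tailed paired t-test; Cohen's d is the mean of the paired
#' differences divided by their standard deviation. Identical vectors give
#' the conventional null result (t = 0, p = 1, d = 0).
#'
#' @param x,y Matched numeric vectors.
#' @return A `t_test_result` (t, df, two-tailed p, 95% CI of the mean
#'   difference, Cohen's d).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  t_from_summary(mean(d), sd(d), length(d), 0, "paired")
}

#' One-sample t-test from a vector or summary statistics
#'
#' Accepts either a raw vector `x` or printed summary statistics
#' (`mean`, `sd`, `n`) — the latter reproduces published tests whose raw
#' data are not available. Cohen's d is `(mean - mu0) / sd`.
#'
#' @param x Numeric vector (or `NULL` when using summaries).
#' @param mu0 Null value.
#' @param mean,sd,n Summary statistics, used when `x` is `NULL`.
#' @return A `t_test_result`.
#' @export
one_sample_t <- function(x = NULL, mu0 = 0, mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(x)) {
    stopifnot(length(x) >= 2)
    return(t_from_summary(base::mean(x), stats::sd(x), length(x), mu0,
                          "one_sample"))
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stop("provide either x or all of mean, sd, n")
  if (sd <= 0) stop("degenerate: sd must be positive for summary input")
  t_from_summary(mean, sd, n, mu0, "one_sample")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t-test: t(%d) = %.3f, p = %.4g, 95%% CI [%.3f, %.3f], Cohen's d = %.2f\n",
              x$kind, x$df, x$t, x$p_two_tailed, x$ci_low, x$ci_high,
              x$cohens_d))
  invisible(x)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Orders the raw p values, compares `p_(i)` with the rank threshold
#' `(i/m) q`, and rejects all hypotheses up to the largest rank where
#' `p_(i) <= (i/m) q`. Also returns monotone BH-adjusted p values
#' (identical to `p.adjust(method = "BH")`).
#'
#' @param p_values Raw p values in \[0, 1\].
#' @param q False discovery rate (default 0.05).
#' @return List of class `bh_result`: `p_raw`, `order`, `thresholds`
#'   (per rank, in sorted order), `rejected` (in input order),
#'   `p_adjusted` (input order), `q`, `n_rejected`.
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  stopifnot(q > 0, q < 1)
  m <- length(p_values)
  if (m == 0)
    return(structure(list(p_raw = numeric(0), order = integer(0),
                          thresholds = numeric(0), rejected = logical(0),
                          p_adjusted = numeric(0), q = q, n_rejected = 0L),
                     class = "bh_result"))
  if (any(p_values < 0 | p_values > 1)) stop("p values must lie in [0, 1]")
  ord <- order(p_values)
  sorted <- p_values[ord]
  thresholds <- seq_len(m) / m * q
  below <- which(sorted <= thresholds)
  istar <- if (length(below)) max(below) else 0L
  rejected <- logical(m)
  if (istar > 0) rejected[ord[seq_len(istar)]] <- TRUE
  structure(list(p_raw = p_values, order = ord, thresholds = thresholds,
                 rejected = rejected,
                 p_adjusted = p.adjust(p_values, method = "BH"),
                 q = q, n_rejected = sum(rejected)),
            class = "bh_result")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] (Royston's algorithm) with
#' explicit degenerate-input errors.
#'
#' @param x Numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 finite values")
  if (length(unique(x)) == 1L) stop("degenerate: constant vector")
  r <- shapiro.test(x)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Serialize a table of test results
#'
#' Writes a TSV with one row per contrast/effect.
#'
#' @param df Data frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
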