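## Shifted-exponential encoding curve: d'(t) = A(1 - exp(-R(t - I))) for
## t > I, 0 otherwise. A is the asymptotic sensitivity (d' units), R the rate
## of information extraction (per ms internally; reported as d'/s), I the
## onset of information availability (ms).

#' Encoding-curve parameter container
#'
#' @param A Asymptote in d' units.
#' @param R Rate per millisecond.
#' @param I Onset (intercept) in milliseconds.
#' @param bounds Box constraints, see [encoding_bounds()].
#' @return List of class `shifted_exp_params`.
#' @export
shifted_exp_params <- function(A, R, I, bounds = encoding_bounds()) {
  stopifnot(A >= bounds$lower[["A"]], A <= bounds$upper[["A"]],
            R >= bounds$lower[["R"]], R <= bounds$upper[["R"]],
            I >= bounds$lower[["I"]], I <= bounds$upper[["I"]])
  structure(list(A = A, R = R, I = I), class = "shifted_exp_params")
}

#' Default search box for the encoding-curve parameters
#'
#' Asymptote 1.0-10.0 d', rate 0.0001-10.0 per ms, onset 1e-7-500 ms
#' (1e-7 ms is numerically zero at the millisecond scale).
#'
#' @return List with named vectors `lower` and `upper`.
#' @export
encoding_bounds <- function() {
  list(lower = c(A = 1.0, R = 1e-4, I = 1e-7),
       upper = c(A = 10.0, R = 10.0, I = 500.0))
}

#' Predicted sensitivity at an encoding duration
#'
#' `A * (1 - exp(-R * (t - I)))` for `t > I`, exactly 0 otherwise
#' (continuous at `t = I`).
#'
#' @param params A `shifted_exp_params` (or list with `A`, `R`, `I`).
#' @param t Encoding durations in ms (vectorized, must be >= 0).
#' @param clamp If `FALSE`, return the smooth exponential also below the
#'   onset (used as the least-squares objective; see the methods vignette).
#' @return Predicted d' values.
#' @export
predict_encoding <- function(params, t, clamp = TRUE) {
  stopifnot(all(t >= 0))
  y <- params$A * (1 - exp(-params$R * (t - params$I)))
  if (clamp) y[t <= params$I] <- 0
  y
}

#' Coefficient of determination
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return R-squared (<= 1; negative when the model is worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("degenerate observations: zero total sum of squares")
  1 - sum((observed - predicted)^2) / sst
}

## evaluate/restore the RNG state so seeded fitting does not disturb the
## caller's random stream
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fit the shifted-exponential encoding curve
#'
#' Bounded nonlinear least squares via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) from multiple starting points (Latin hypercube
#' over the bound box; the rate dimension is sampled log-uniformly because
#' the box spans five decades). The lowest-SSE converged solution wins;
#' ties below 1e-10 in SSE are broken by the smallest onset.
#'
#' By default the objective is the smooth exponential at all durations
#' (`clamp_objective = FALSE`); the zero clamp below the onset applies to
#' predictions ([predict_encoding()]) but not to the fitting criterion.
#'
#' @param durations_ms Strictly increasing encoding durations (>= 4 values).
#' @param mean_dprime Observed mean sensitivities, one per duration.
#' @param bounds Parameter box, see [encoding_bounds()].
#' @param n_starts Number of Levenberg-Marquardt starts (default 64).
#' @param seed Seed for the start-point hypercube.
#' @param clamp_objective Clamp predictions to 0 below the onset inside the
#'   least-squares objective.
#' @return List of class `encoding_fit`: `params`, `rate_per_s` (R x 1000),
#'   `se` (named, linearized; see [param_standard_errors()]), `sse`,
#'   `r_squared`, `n_points`, `converged`, `n_starts_used`, `at_bound`.
#' @export
fit_encoding_curve <- function(durations_ms, mean_dprime,
                               bounds = encoding_bounds(), n_starts = 64L,
                               seed = 1L, clamp_objective = FALSE) {
  stopifnot(length(durations_ms) == length(mean_dprime))
  if (length(durations_ms) < 4)
    stop("need at least 4 points to fit 3 parameters")
  if (any(diff(durations_ms) <= 0))
    stop("durations must be strictly increasing")
  lw <- bounds$lower; up <- bounds$upper
  model <- if (clamp_objective) {
    function(t, A, R, I) ifelse(t > I, A * (1 - exp(-R * (t - I))), 0)
  } else {
    function(t, A, R, I) A * (1 - exp(-R * (t - I)))
  }
  cube <- with_local_seed(seed, lhs::randomLHS(n_starts, 3L))
  starts <- data.frame(
    A = lw[["A"]] + cube[, 1] * (up[["A"]] - lw[["A"]]),
    R = exp(log(lw[["R"]]) + cube[, 2] * (log(up[["R"]]) - log(lw[["R"]]))),
    I = lw[["I"]] + cube[, 3] * (up[["I"]] - lw[["I"]]))
  t <- durations_ms; y <- mean_dprime
  best <- NULL; n_used <- 0L
  for (i in seq_len(n_starts)) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ model(t, A, R, I), start = as.list(starts[i, ]),
      lower = lw, upper = up,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                           ptol = 1e-12))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    n_used <- n_used + 1L
    sse <- sum(stats::residuals(fit)^2)
    cf <- stats::coef(fit)
    if (is.null(best) || sse < best$sse - 1e-10 ||
        (abs(sse - best$sse) <= 1e-10 && cf[["I"]] < best$cf[["I"]])) {
      best <- list(sse = sse, cf = cf)
    }
  }
  if (is.null(best))
    return(structure(list(params = NULL, converged = FALSE,
                          n_starts_used = n_used,
                          message = "no Levenberg-Marquardt start converged"),
                     class = "encoding_fit"))
  params <- shifted_exp_params(best$cf[["A"]], best$cf[["R"]], best$cf[["I"]],
                               bounds)
  pred <- predict_encoding(params, t, clamp = clamp_objective)
  tol_rel <- 1e-6
  at_bound <- c(
    A = params$A <= lw[["A"]] * (1 + tol_rel) || params$A >= up[["A"]] * (1 - tol_rel),
    R = params$R <= lw[["R"]] * (1 + tol_rel) || params$R >= up[["R"]] * (1 - tol_rel),
    I = params$I <= lw[["I"]] * (1 + tol_rel) || params$I >= up[["I"]] * (1 - tol_rel))
  fit <- structure(list(params = params,
                        rate_per_s = params$R * 1000,
                        sse = best$sse,
                        r_squared = r_squared(y, pred),
                        n_points = length(t),
                        converged = TRUE,
                        n_starts_used = n_used,
                        at_bound = at_bound,
                        durations_ms = t, observed = y,
                        clamp_objective = clamp_objective),
                   class = "encoding_fit")
  fit$se <- param_standard_errors(fit)
  fit
}

#' Linearized parameter standard errors
#'
#' Standard errors from the linearized covariance `s^2 (J'J)^-1` at the
#' optimum, where `J` is the numerical Jacobian of the model predictions
#' with respect to (A, R, I) and `s^2 = SSE / (n - 3)`. When `J'J` is
#' singular (e.g. the onset sits at a bound with no leverage) the affected
#' standard errors are `NA` and the result carries a `degenerate` flag.
#'
#' @param fit A converged `encoding_fit`.
#' @return Named vector `c(A, R, I)` of standard errors (R per ms, as
#'   fitted), with attribute `degenerate`.
#' @export
param_standard_errors <- function(fit) {
  stopifnot(inherits(fit, "encoding_fit"), isTRUE(fit$converged))
  n <- fit$n_points
  if (n - 3 < 1) stop("no residual degrees of freedom")
  p <- c(fit$params$A, fit$params$R, fit$params$I)
  t <- fit$durations_ms
  predfun <- function(th) {
    pr <- list(A = th[1], R = th[2], I = th[3])
    predict_encoding(pr, t, clamp = isTRUE(fit$clamp_objective))
  }
  J <- matrix(0, n, 3)
  for (j in 1:3) {
    hstep <- max(1e-7, 1e-6 * abs(p[j]))
    up <- p; up[j] <- up[j] + hstep
    dn <- p; dn[j] <- dn[j] - hstep
    J[, j] <- (predfun(up) - predfun(dn)) / (2 * hstep)
  }
  s2 <- fit$sse / (n - 3)
  jtj <- crossprod(J)
  cv <- try(solve(jtj), silent = TRUE)
  if (inherits(cv, "try-error") || any(!is.finite(diag(cv))) ||
      any(diag(cv) < 0)) {
    se <- c(A = NA_real_, R = NA_real_, I = NA_real_)
    attr(se, "degenerate") <- TRUE
    return(se)
  }
  se <- sqrt(s2 * diag(cv))
  names(se) <- c("A", "R", "I")
  attr(se, "degenerate") <- FALSE
  se
}

#' Invert the encoding curve at a target sensitivity
#'
#' Returns the unique duration `t = I - ln(1 - target/A) / R` at which the
#' fitted curve reaches `target` (0 <= target < A).
#'
#' @param params A `shifted_exp_params`.
#' @param target_dprime Target sensitivity.
#' @return Duration in ms.
#' @export
invert_duration <- function(params, target_dprime) {
  if (target_dprime < 0) stop("target must be nonnegative")
  if (target_dprime >= params$A)
    stop("above asymptote: the curve never reaches d' = ", target_dprime)
  params$I - log(1 - target_dprime / params$A) / params$R
}

#' Convert proportion correct to d' (unbiased yes-no correspondence)
#'
#' `d' = 2 * qnorm(pc)` for an unbiased equal-variance observer; 80%
#' correct corresponds to d' of about 1.68.
#'
#' @param pc Proportion correct in (0.5, 1).
#' @return Sensitivity d'.
#' @export
dprime_from_pc <- function(pc) {
  if (any(pc <= 0.5 | pc >= 1)) stop("pc must lie in (0.5, 1)")
  2 * qnorm(pc)
}

#' @rdname dprime_from_pc
#' @param dprime Sensitivity (> 0).
#' @export
pc_from_dprime <- function(dprime) {
  if (any(dprime <= 0)) stop("dprime must be positive")
  pnorm(dprime / 2)
}

#' Serialize an encoding fit to JSON
#'
#' Writes `{A, R_per_s, I_ms, se_A, se_R_per_s, se_I_ms, r_squared, sse,
#' n_points, converged, at_bound}` (plus an optional session label).
#'
#' @param fit An `encoding_fit`.
#' @param path Output path.
#' @param session Optional session label.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, session = NULL) {
  obj <- encoding_fit_summary(fit, session)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

encoding_fit_summary <- function(fit, session = NULL) {
  if (!isTRUE(fit$converged))
    return(list(session = session, converged = FALSE))
  list(session = session,
       A = fit$params$A,
       R_per_s = fit$rate_per_s,
       I_ms = fit$params$I,
       se_A = unname(fit$se[["A"]]),
       se_R_per_s = unname(fit$se[["R"]]) * 1000,
       se_I_ms = unname(fit$se[["I"]]),
       r_squared = fit$r_squared,
       sse = fit$sse,
       n_points = fit$n_points,
       converged = TRUE,
       at_bound = as.list(fit$at_bound))
}

#' @export
print.encoding_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Encoding-curve fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("Shifted-exponential encoding curve (n = %d points)\n",
              x$n_points))
  cat(sprintf("  asymptote A = %.3f d'   (SE %.3f)\n", x$params$A,
              x$se[["A"]]))
  cat(sprintf("  rate      R = %.2f d'/s (SE %.2f)\n", x$rate_per_s,
              x$se[["R"]] * 1000))
  cat(sprintf("  onset     I = %.2f ms   (SE %.2f)\n", x$params$I,
              x$se[["I"]]))
  cat(sprintf("  R^2 = %.4f, SSE = %.4f\n", x$r_squared, x$sse))
  invisible(x)
}
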