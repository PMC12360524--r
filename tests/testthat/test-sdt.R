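test_that("rate corrections handle extreme proportions", {
  ## symmetric cell is untouched by any correction
  for (m in c("none", "half_count", "log_linear")) {
    r <- correct_rates(15, 30, 15, 30, m)
    expect_equal(r$h, ifelse(m == "log_linear", 15.5 / 31, 0.5))
    expect_equal(r$h, 0.5)
    expect_false(r$degenerate)
  }
  expect_equal(correct_rates(30, 30, 0, 30, "half_count")$h, 59 / 60)
  expect_equal(correct_rates(30, 30, 0, 30, "half_count")$f, 1 / 60)
  expect_equal(correct_rates(0, 30, 0, 30, "log_linear")$h, 0.5 / 31)
  expect_equal(correct_rates(7, 30, 3, 30, "log_linear")$h, 7.5 / 31)
  expect_true(correct_rates(30, 30, 0, 30, "none")$degenerate)
})

test_that("yes-no d' matches quantile arithmetic and is antisymmetric", {
  expect_equal(dprime_yesno(0.3, 0.3)$dprime, 0)
  expect_equal(dprime_yesno(0.9, 0.1)$dprime, 2.5631031, tolerance = 1e-6)
  ## ceiling for 30-trial cells under half-count correction
  expect_equal(dprime_yesno(59 / 60, 1 / 60)$dprime, 4.2560905,
               tolerance = 1e-6)
  for (hf in list(c(0.7, 0.2), c(0.9, 0.4), c(0.55, 0.5))) {
    expect_equal(dprime_yesno(hf[1], hf[2])$dprime,
                 -dprime_yesno(hf[2], hf[1])$dprime)
  }
  expect_error(dprime_yesno(1, 0.5), "strictly")
})

test_that("differencing model inverts its forward equations", {
  expect_equal(dprime_samediff_differencing(0.3, 0.3)$dprime, 0)
  ## forward-evaluated example: d' = 2, k = 1.8124
  hf <- samediff_differencing_rates(2, 1.8124)
  expect_equal(unname(hf["f"]), 0.2, tolerance = 1e-4)
  est <- dprime_samediff_differencing(hf[["h"]], hf[["f"]])
  expect_equal(est$dprime, 2, tolerance = 1e-6)
  expect_equal(est$criterion, 1.8124, tolerance = 1e-4)
  ## round trip on a grid of (d', k)
  for (d in c(0.5, 1, 2, 4)) for (k in c(0.5, 1.5, 3)) {
    fw <- samediff_differencing_rates(d, k)
    if (fw[["h"]] >= 1 - 1e-12 || fw[["f"]] <= 1e-12) next
    back <- dprime_samediff_differencing(fw[["h"]], fw[["f"]])
    expect_equal(back$dprime, d, tolerance = 1e-6)
  }
})

test_that("differencing forward model agrees with Monte-Carlo simulation", {
  set.seed(101)
  n <- 1e6
  d <- 1.6; k <- 1.2
  ## |x1 - x2| > k rule; same pairs share a mean, different pairs differ by d
  same_diffabs <- abs(rnorm(n) - rnorm(n))
  diff_diffabs <- abs(rnorm(n) - (rnorm(n) + d))
  fw <- samediff_differencing_rates(d, k)
  mc_f <- mean(same_diffabs > k); mc_h <- mean(diff_diffabs > k)
  se_f <- sqrt(mc_f * (1 - mc_f) / n); se_h <- sqrt(mc_h * (1 - mc_h) / n)
  expect_lt(abs(fw[["f"]] - mc_f), 3 * se_f)
  expect_lt(abs(fw[["h"]] - mc_h), 3 * se_h)
})

test_that("independent-observation model matches its closed forms", {
  expect_equal(dprime_samediff_independent(0.4, 0.4)$dprime, 0)
  ## unbiased observer: h = 1 - f = pnorm(d'/2)^2 + pnorm(-d'/2)^2
  for (d in c(1, 2, 3.5)) {
    hf <- samediff_independent_rates(d, 0)
    pc <- pnorm(d / 2)^2 + pnorm(-d / 2)^2
    expect_equal(unname(hf["h"]), pc, tolerance = 1e-9)
    expect_equal(unname(1 - hf["f"]), pc, tolerance = 1e-9)
  }
  expect_equal(pnorm(1)^2 + pnorm(-1)^2, 0.7330, tolerance = 1e-4)
})

test_that("independent-observation inversion round-trips on a grid", {
  for (d in c(0.5, 1, 2, 3, 5)) for (lb in c(-0.8, 0, 0.8)) {
    fw <- samediff_independent_rates(d, lb)
    est <- dprime_samediff_independent(fw[["h"]], fw[["f"]])
    expect_equal(est$dprime, d, tolerance = 1e-6)
    fw2 <- samediff_independent_rates(est$dprime, est$criterion)
    expect_equal(unname(fw2), unname(fw), tolerance = 1e-6)
  }
})

test_that("independent-observation forward model agrees with Monte-Carlo", {
  set.seed(202)
  n <- 1e6
  d <- 1.5; lb <- 0.7
  g <- function(x) exp(d * (x - d / 2))
  lr <- function(a, b) (g(a) + g(b)) / (1 + g(a) * g(b))
  mc_f <- 0.5 * (mean(lr(rnorm(n), rnorm(n)) > exp(lb)) +
                   mean(lr(rnorm(n) + d, rnorm(n) + d) > exp(lb)))
  mc_h <- mean(lr(rnorm(n), rnorm(n) + d) > exp(lb))
  fw <- samediff_independent_rates(d, lb)
  se_f <- sqrt(mc_f * (1 - mc_f) / n); se_h <- sqrt(mc_h * (1 - mc_h) / n)
  expect_lt(abs(fw[["f"]] - mc_f), 3 * se_f)
  expect_lt(abs(fw[["h"]] - mc_h), 3 * se_h)
})

test_that("all models return 0 at h = f and increase with the hit rate", {
  for (m in c("yesno", "differencing", "independent_observation")) {
    expect_equal(dprime_estimate(0.35, 0.35, m)$dprime, 0)
    hs <- seq(0.25, 0.95, by = 0.1)
    ds <- vapply(hs, function(h) dprime_estimate(h, 0.2, m)$dprime,
                 numeric(1))
    expect_true(all(diff(ds) > 0))
  }
})

test_that("every count combination on a 30/30 cell is invertible", {
  ## ceiling-to-floor sweep under the default correction never errors
  for (nh in c(0, 1, 15, 29, 30)) for (nf in c(0, 1, 15, 29, 30)) {
    r <- correct_rates(nh, 30, nf, 30, "half_count")
    est <- dprime_samediff_independent(r$h, r$f)
    expect_true(is.finite(est$dprime))
    expect_gte(est$dprime, 0)
  }
})

test_that("sensitivity table estimates hand-computable cells", {
  ## 8-trial cell: 3/4 hits, 1/4 false alarms
  df <- make_trials(data.frame(
    pair_type = rep(c("different", "same"), each = 4),
    response = c("different", "different", "different", "same",
                 "different", "same", "same", "same"),
    response_time_s = 1))
  sens <- sensitivity_table(as_trial_table(df), model = "yesno",
                            correction = "half_count", min_trials = 4)
  expect_equal(sens$h, 0.75)
  expect_equal(sens$f, 0.25)
  expect_equal(sens$dprime, qnorm(0.75) - qnorm(0.25))
  expect_false(sens$flagged)
  ## balanced null cell estimates ~0 under the default model
  df0 <- make_trials(data.frame(
    pair_type = rep(c("different", "same"), each = 10),
    response = rep(c("different", "same"), 10),
    response_time_s = 1))
  s0 <- sensitivity_table(as_trial_table(df0), min_trials = 4)
  expect_equal(s0$dprime, 0, tolerance = 1e-6)
})
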