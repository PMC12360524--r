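test_that("one-factor RM-ANOVA with two levels reproduces the paired t-test", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0.3)
    long <- data.frame(id = rep(seq_len(n), 2),
                       cond = rep(c("a", "b"), each = n),
                       score = c(x, y))
    an <- rm_anova(long, dv = "score", subject = "id", within = "cond")
    tt <- paired_t(x, y)
    expect_equal(an$F, tt$t^2, tolerance = 1e-8)
    expect_equal(an$p_uncorrected, tt$p_two_tailed, tolerance = 1e-8)
    expect_equal(an$gg_epsilon, 1)   # k = 2: epsilon is exactly 1
  }
})

test_that("RM-ANOVA sums of squares equal a from-definitions oracle", {
  set.seed(12)
  n <- 5; k <- 4
  Y <- matrix(rnorm(n * k, mean = rep(c(0, 0.5, 1, 0.2), each = n)), n, k)
  long <- data.frame(id = rep(seq_len(n), k),
                     cond = rep(letters[1:k], each = n),
                     score = as.vector(Y))
  an <- rm_anova(long, dv = "score", subject = "id", within = "cond")
  ## oracle: direct sums over definitions
  grand <- mean(Y)
  ss_eff <- n * sum((colMeans(Y) - grand)^2)
  ss_err <- sum((Y - outer(rowMeans(Y), colMeans(Y), "+") + grand)^2)
  F_oracle <- (ss_eff / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(an$F, F_oracle, tolerance = 1e-10)
  expect_equal(an$partial_eta_sq, ss_eff / (ss_eff + ss_err),
               tolerance = 1e-10)
  expect_equal(an$df_num, k - 1)
  expect_equal(an$df_den, (n - 1) * (k - 1))
  expect_equal(an$df_num_gg, an$gg_epsilon * an$df_num)
  expect_true(an$gg_epsilon >= 1 / (k - 1) && an$gg_epsilon <= 1)
})

test_that("Mauchly and Greenhouse-Geisser agree with the mlm machinery", {
  set.seed(13)
  n <- 12; k <- 4
  Y <- matrix(rnorm(n * k), n, k)
  Y[, 1] <- Y[, 1] * 2  # break sphericity
  long <- data.frame(id = rep(seq_len(n), k),
                     cond = rep(letters[1:k], each = n),
                     score = as.vector(Y))
  an <- rm_anova(long, dv = "score", subject = "id", within = "cond")
  ## oracle: stats::mauchly.test on the fitted mlm
  mlm <- lm(Y ~ 1)
  idata <- data.frame(cond = factor(letters[1:k]))
  mt <- mauchly.test(mlm, X = ~1, idata = idata)
  expect_equal(an$mauchly_W, unname(mt$statistic), tolerance = 1e-8)
  expect_equal(an$mauchly_p, mt$p.value, tolerance = 1e-8)
  ## the GG-corrected p implies the epsilon: matching p at matching F and
  ## dfs pins the correction down
  sph <- anova(mlm, X = ~1, idata = idata, test = "Spherical")
  expect_equal(an$F, sph$F[1], tolerance = 1e-8)
  expect_equal(an$p_gg, sph$`G-G Pr`[1], tolerance = 1e-8)
})

test_that("identical scores across conditions give a null effect", {
  long <- expand.grid(id = 1:6, cond = c("a", "b", "c"))
  long$score <- rnorm(6)[long$id]   # constant within participant
  an <- rm_anova(long, dv = "score", subject = "id", within = "cond")
  expect_equal(an$F, 0)
  expect_equal(an$partial_eta_sq, 0)
})

test_that("two-factor RM-ANOVA decomposes effects against their own errors", {
  set.seed(14)
  n <- 8; a <- 3; b <- 4
  d <- expand.grid(id = seq_len(n), A = letters[1:a], B = LETTERS[1:b])
  d$score <- rnorm(nrow(d)) + 0.8 * (d$A == "b") + 0.4 * (d$B == "C") +
    0.5 * (d$A == "c") * (d$B == "D") + rnorm(n)[d$id]
  an <- rm_anova(d, dv = "score", subject = "id", within = c("A", "B"))
  expect_equal(an$effect, c("A", "B", "A:B"))
  expect_equal(an$df_num, c(a - 1, b - 1, (a - 1) * (b - 1)))
  expect_equal(an$df_den, (n - 1) * an$df_num)
  ## oracle: aov with Error strata
  fit <- summary(aov(score ~ A * B + Error(factor(id) / (A * B)), data = d))
  getF <- function(nm) {
    tab <- fit[[paste0("Error: factor(id):", nm)]][[1]]
    tab[trimws(rownames(tab)) == nm, "F value"]
  }
  expect_equal(an$F[1], getF("A"), tolerance = 1e-8)
  expect_equal(an$F[2], getF("B"), tolerance = 1e-8)
  expect_equal(an$F[3], getF("A:B"), tolerance = 1e-8)
  expect_true(all(an$gg_epsilon >= 1 / an$df_num) && all(an$gg_epsilon <= 1))
  expect_true(all(an$partial_eta_sq >= 0 & an$partial_eta_sq <= 1))
})

test_that("missing cells are reported by participant and condition", {
  long <- expand.grid(id = 1:4, cond = c("a", "b", "c"))
  long$score <- rnorm(nrow(long))
  expect_error(rm_anova(long[-1, ], dv = "score", subject = "id",
                        within = "cond"), "not complete")
})

test_that("t-tests match stats::t.test and printed-summary arithmetic", {
  set.seed(15)
  x <- rnorm(20); y <- x + rnorm(20, 0.2)
  ours <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p_two_tailed, ref$p.value)
  expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-10)
  expect_equal(ours$cohens_d, mean(x - y) / sd(x - y))
  ## identical vectors: conventional null result
  same <- paired_t(x, x)
  expect_equal(c(same$t, same$p_two_tailed, same$cohens_d), c(0, 1, 0))
  ## one-sample from vector vs oracle
  o1 <- one_sample_t(x, mu0 = 0.1)
  r1 <- t.test(x, mu = 0.1)
  expect_equal(o1$t, unname(r1$statistic))
  expect_equal(o1$p_two_tailed, r1$p.value)
  ## summary input: 3-point hand example
  h <- one_sample_t(mean = 2, sd = 1, n = 3, mu0 = 0)
  expect_equal(h$t, 2 / (1 / sqrt(3)))
  expect_error(one_sample_t(mean = 1, sd = 0, n = 5), "degenerate")
})

test_that("Benjamini-Hochberg is a step-up rule containing Bonferroni", {
  res <- bh_adjust(c(0.001, 0.013, 0.04, 0.22), q = 0.05)
  ## thresholds 0.0125, 0.025, 0.0375, 0.05: reject exactly the first two
  expect_equal(res$thresholds, c(0.0125, 0.025, 0.0375, 0.05))
  expect_equal(res$rejected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$p_adjusted, p.adjust(c(0.001, 0.013, 0.04, 0.22), "BH"))
  expect_equal(bh_adjust(rep(1, 5))$n_rejected, 0L)
  expect_true(bh_adjust(0.04, q = 0.05)$rejected)
  expect_equal(bh_adjust(numeric(0))$n_rejected, 0L)
  ## step-up: everything below the pivot is rejected, even above its own bar
  res2 <- bh_adjust(c(0.01, 0.024, 0.026, 0.9), q = 0.05)
  expect_equal(res2$n_rejected, 3L)
  set.seed(16)
  for (i in 1:50) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    bh <- bh_adjust(p, q = 0.05)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(bh$rejected[bonf]))        # BH set contains Bonferroni
    bh10 <- bh_adjust(p, q = 0.10)
    expect_gte(bh10$n_rejected, bh$n_rejected) # monotone in q
  }
})

test_that("Shapiro-Wilk wrapper detects skew and rejects bad input", {
  set.seed(17)
  big <- rnorm(500)
  expect_gt(shapiro_wilk(big)$p, 0.01)
  hits <- mean(replicate(100, shapiro_wilk(rexp(50))$p < 0.01))
  expect_gt(hits, 0.7)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})
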