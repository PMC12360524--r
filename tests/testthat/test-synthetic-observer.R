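test_that("population sampling is deterministic and respects its config", {
  cfg <- simulation_config(n_participants = 6, seed = 123)
  p1 <- sample_population(cfg)
  p2 <- sample_population(cfg)
  expect_identical(p1, p2)
  ## zero between-subject SDs collapse everyone onto the population means
  cfg0 <- simulation_config(n_participants = 4, sd_A = 0, sd_R_per_s = 0,
                            sd_I_ms = 0, sd_lnbeta = 0, seed = 5)
  pop0 <- sample_population(cfg0)
  for (o in pop0) {
    expect_equal(o$curves[["1"]]$A, 2.88)
    expect_equal(o$curves[["10"]]$R * 1000, 14.96)
    expect_equal(o$curves[["4"]]$I, 0.28)
  }
})

test_that("sampled parameters match the truncated-normal mean", {
  cfg <- simulation_config(n_participants = 3000, seed = 31)
  pop <- sample_population(cfg)
  A1 <- vapply(pop, function(o) o$curves[["1"]]$A, numeric(1))
  b <- encoding_bounds()
  mu <- perclearn:::truncnorm_mean(2.88, 0.5, b$lower[["A"]], b$upper[["A"]])
  se <- sd(A1) / sqrt(length(A1))
  expect_lt(abs(mean(A1) - mu), 3 * se)
  I10 <- vapply(pop, function(o) o$curves[["10"]]$I, numeric(1))
  muI <- perclearn:::truncnorm_mean(0, 6, 0, b$upper[["I"]])
  expect_lt(abs(mean(I10) - muI), 3 * sd(I10) / sqrt(length(I10)))
  expect_true(all(I10 >= 0))
})

test_that("evaluation sessions have the designed trial composition", {
  cfg <- simulation_config(n_participants = 1, seed = 7)
  obs <- sample_population(cfg)[[1]]
  tab <- simulate_evaluation_session(obs, 1, cfg, seed = 42)
  expect_equal(nrow(tab), 480)
  comp <- table(tab$encoding_duration_ms, tab$pair_type)
  expect_true(all(comp == 30))            # 30 same / 30 different per duration
  expect_setequal(unique(tab$encoding_duration_ms), evaluation_durations())
  expect_equal(sort(tab$trial_index), 1:480)
  ## determinism given an explicit seed
  tab2 <- simulate_evaluation_session(obs, 1, cfg, seed = 42)
  expect_identical(tab, tab2)
})

test_that("a floor-level observer produces matched hit and false-alarm rates", {
  cfg <- simulation_config(n_participants = 1, sd_lnbeta = 0, seed = 9)
  obs <- sample_population(cfg)[[1]]
  null_curve <- list(A = 1, R = 1e-4, I = 500)  # d' ~ 0 at every duration
  tab <- simulate_evaluation_session(obs, 1, cfg, curve = null_curve,
                                     seed = 10)
  ct <- summarize_counts(as_trial_table(tab), "participant_id")
  h <- ct$n_hit / ct$n_different_trials
  f <- ct$n_fa / ct$n_same_trials
  se <- sqrt(0.5 * 0.5 * (1 / ct$n_different_trials + 1 / ct$n_same_trials))
  expect_lt(abs(h - f), 3 * se)
})

test_that("large samples reproduce the generating response probabilities", {
  cfg <- simulation_config(n_participants = 1, durations_ms = c(50, 234),
                           trials_per_duration = 20000, lapse_rate = 0,
                           omission_prob = 0, sd_lnbeta = 0, seed = 77)
  obs <- sample_population(cfg)[[1]]
  tab <- simulate_evaluation_session(obs, 1, cfg, seed = 78)
  ct <- summarize_counts(as_trial_table(tab),
                         c("participant_id", "encoding_duration_ms"))
  for (i in seq_len(nrow(ct))) {
    t <- ct$encoding_duration_ms[i]
    d_true <- predict_encoding(obs$curves[["1"]], t)
    hf <- samediff_independent_rates(d_true, obs$lnbeta)
    h_emp <- ct$n_hit[i] / ct$n_different_trials[i]
    f_emp <- ct$n_fa[i] / ct$n_same_trials[i]
    expect_lt(abs(h_emp - hf[["h"]]),
              3 * sqrt(hf[["h"]] * (1 - hf[["h"]]) / ct$n_different_trials[i]))
    expect_lt(abs(f_emp - hf[["f"]]),
              3 * sqrt(hf[["f"]] * (1 - hf[["f"]]) / ct$n_same_trials[i]))
  }
})

test_that("generated tables round-trip and carry the configured RT outliers", {
  cfg <- simulation_config(n_participants = 2, seed = 55)
  obs <- sample_population(cfg)
  tab <- do.call(rbind, lapply(obs, simulate_evaluation_session,
                               session_index = 4, config = cfg))
  path <- tempfile(fileext = ".csv")
  write_trials(as_trial_table(tab), path)
  back <- read_trials(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$response_time_s, tab$response_time_s)
  res <- filter_by_rt(as_trial_table(tab))
  frac_removed <- sum(res$report$n_removed) / sum(res$report$n_input)
  n <- nrow(tab)
  se <- sqrt(0.02 * 0.98 / n)
  expect_lt(abs(frac_removed - 0.02), 4 * se)
})

test_that("the training course produces a detectable learning effect", {
  detected <- vapply(1:8, function(s) {
    cfg <- simulation_config(n_participants = 27, training_trials = 120,
                             seed = 600 + s)
    tc <- simulate_training_course(cfg)
    sens <- sensitivity_table(as_trial_table(tc$trials), model = "yesno",
                              grouping = c("participant_id", "session_index"))
    an <- rm_anova(sens, dv = "dprime", subject = "participant_id",
                   within = "session_index")
    an$p_gg < 0.001
  }, logical(1))
  expect_gte(sum(detected), 7)
  ## true trajectory rises toward its configured endpoint
  cfg <- simulation_config(seed = 1)
  tc <- simulate_training_course(cfg, sample_population(cfg))
  traj <- colMeans(tc$true_dprime)
  expect_true(all(diff(traj) > 0))
  expect_equal(traj[[1]], 1.0, tolerance = 0.35)  # 27 observers, SD 0.5
})

test_that("a full study has the designed size and a faithful manifest", {
  cfg <- simulation_config(n_participants = 3, seed = 99)
  study <- simulate_study(cfg)
  expect_equal(nrow(study$trials), 3 * (6 * 360 + 4 * 480 + 480))
  per <- table(study$trials$participant_id)
  expect_true(all(per == 4560))
  expect_setequal(unique(study$trials$session_index), 1:11)
  ## determinism: identical tables from identical (config, seed)
  study2 <- simulate_study(simulation_config(n_participants = 3, seed = 99))
  expect_identical(as.data.frame(study$trials), as.data.frame(study2$trials))
  ## manifest round-trips the generating parameters
  dir <- tempfile()
  write_study(study, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 99)
  expect_equal(man$observers$participant_id, c("P01", "P02", "P03"))
  o1 <- sample_population(cfg)[[1]]
  expect_equal(man$observers$curves$`1`$A[1], o1$curves[["1"]]$A)
  expect_equal(length(list.files(dir, pattern = "session_.*csv")), 11)
  back <- read_trials(file.path(dir, "session_01.csv"))
  expect_equal(nrow(back), 3 * 480)
})

test_that("a flat training trajectory yields null session differences", {
  cfg <- simulation_config(n_participants = 20, training_trials = 200,
                           training_start = 1.5, training_end = 1.5,
                           sd_training_dprime = 0, seed = 8)
  tc <- simulate_training_course(cfg)
  sens <- sensitivity_table(as_trial_table(tc$trials), model = "yesno",
                            grouping = c("participant_id", "session_index"))
  an <- rm_anova(sens, dv = "dprime", subject = "participant_id",
                 within = "session_index")
  expect_gt(an$p_uncorrected, 0.01)
})
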