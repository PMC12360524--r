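## Synthetic-observer simulator: generates complete studies (training,
## evaluation and generalization sessions) from known encoding-curve
## parameters so every analysis stage can be validated by parameter
## recovery. The generating model mirrors the analysis assumptions: each
## observer owns a shifted-exponential encoding curve per evaluation
## session, responds through a same-different decision model at an
## observer-specific criterion, lapses occasionally, and produces lognormal
## response times with a small outlier mass outside the analysis window.

#' Study simulation configuration
#'
#' Defaults emulate the study design the analysis targets: 27 participants;
#' six training sessions (indices 2, 3, 5, 6, 8, 9) of 360 trials at 100 ms;
#' four evaluation sessions (1, 4, 7, 10) of 480 trials — 60 per encoding
#' duration (17, 50, 84, 117, 150, 234, 500, 1000 ms), half same, half
#' different; one generalization session (11) with novel exemplars.
#'
#' Population means of the evaluation-session curve parameters follow the
#' fitted group curves at the four training levels (asymptote 2.88, 3.37,
#' 3.53, 3.60 d'; rate 7.08, 11.62, 14.74, 14.96 d'/s; onset 14.71, 0.28,
#' 2.83, 0 ms). Between-subject SDs are simulator assumptions chosen to
#' produce group-level d' SDs of roughly 0.3-0.9 per cell. The training
#' trajectory of true d' at 100 ms is a saturating exponential in training
#' ordinal (start 1.0, end 2.1). Generalization uses the session-10
#' parameters scaled by `generalization_decrement`.
#'
#' @param n_participants Number of observers.
#' @param durations_ms Evaluation encoding durations.
#' @param trials_per_duration Trials per duration per evaluation session.
#' @param training_trials Trials per training session (at 100 ms).
#' @param model Response-generation decision model.
#' @param pop_A,pop_R_per_s,pop_I_ms Population means per evaluation
#'   session (sessions 1, 4, 7, 10).
#' @param sd_A,sd_R_per_s,sd_I_ms Between-subject SDs (truncated-normal
#'   draws within the fit bounds).
#' @param sd_lnbeta SD of the observer log decision criterion (mean 0).
#' @param lapse_rate Probability that a response is replaced by a fair coin.
#' @param omission_prob Probability of no keypress (`response = "none"`).
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (seconds).
#' @param rt_outlier_prob Mass of response times outside \[0.2, 5\] s.
#' @param training_start,training_end,training_rate Saturating learning
#'   trajectory of true d' at 100 ms across the six training sessions.
#' @param sd_training_dprime Between-subject SD of the training-course d'.
#' @param generalization_decrement Multiplicative factors on (A, R) for the
#'   generalization session relative to session 10.
#' @param seed Mandatory integer seed; the whole study is a deterministic
#'   function of (config, seed).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 27L,
                              durations_ms = evaluation_durations(),
                              trials_per_duration = 60L,
                              training_trials = 360L,
                              model = c("independent_observation",
                                        "differencing", "yesno"),
                              pop_A = c(2.88, 3.37, 3.53, 3.60),
                              pop_R_per_s = c(7.08, 11.62, 14.74, 14.96),
                              pop_I_ms = c(14.71, 0.28, 2.83, 0.0),
                              sd_A = 0.5, sd_R_per_s = 2.5, sd_I_ms = 6,
                              sd_lnbeta = 0.3, lapse_rate = 0.01,
                              omission_prob = 0.002,
                              rt_meanlog = log(0.75), rt_sdlog = 0.35,
                              rt_outlier_prob = 0.02,
                              training_start = 1.0, training_end = 2.1,
                              training_rate = 0.5,
                              sd_training_dprime = 0.5,
                              generalization_decrement = c(A = 0.97, R = 0.89),
                              seed = 1L) {
  model <- match.arg(model)
  schedule <- default_session_schedule()
  stopifnot(n_participants >= 1, trials_per_duration %% 2 == 0,
            training_trials %% 2 == 0, lapse_rate >= 0, lapse_rate <= 0.1,
            length(pop_A) == length(schedule$evaluation),
            length(pop_R_per_s) == length(schedule$evaluation),
            length(pop_I_ms) == length(schedule$evaluation),
            !is.null(seed))
  bounds <- encoding_bounds()
  if (any(pop_A < bounds$lower[["A"]] | pop_A > bounds$upper[["A"]]) ||
      any(pop_R_per_s / 1000 < bounds$lower[["R"]] |
            pop_R_per_s / 1000 > bounds$upper[["R"]]) ||
      any(pop_I_ms < 0 | pop_I_ms > bounds$upper[["I"]]))
    stop("population means outside the encoding-curve bounds")
  cfg <- as.list(environment())
  cfg$schedule <- schedule
  cfg$bounds <- bounds
  structure(cfg, class = "simulation_config")
}

## inverse-CDF truncated normal: maps a uniform quantile u into
## N(mean, sd) truncated to [lower, upper]
qtruncnorm <- function(u, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, length(u)))
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

## mean of the truncated normal (oracle for tests)
truncnorm_mean <- function(mean, sd, lower, upper) {
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Draw a population of synthetic observers
#'
#' Per observer and evaluation session, encoding-curve parameters are drawn
#' from normal distributions truncated to the fit bounds around the
#' session-dependent population means (onset truncated at zero). Criterion,
#' lapse and response-time parameters are drawn once per observer. The
#' output is a deterministic function of (config, seed).
#'
#' @param config A `simulation_config`.
#' @return List of class `observer_params` entries, one per participant:
#'   `participant_id`, per-session `curves` (A, R per ms, I ms), `lnbeta`,
#'   `lapse_rate`, `rt_meanlog`, `rt_sdlog`, `training_dprime` (true d' at
#'   100 ms for the six training sessions).
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ns <- length(config$schedule$evaluation)
  n <- config$n_participants
  bounds <- config$bounds
  traj <- config$training_end - (config$training_end - config$training_start) *
    exp(-config$training_rate * (seq_along(config$schedule$training) - 1))
  observers <- vector("list", n)
  for (i in seq_len(n)) {
    curves <- vector("list", ns)
    names(curves) <- as.character(config$schedule$evaluation)
    ## one latent quantile per parameter per observer, shared across
    ## sessions, so individual differences persist over the study while
    ## each session's marginal is the truncated normal around its mean
    uA <- runif(1); uR <- runif(1); uI <- runif(1)
    for (s in seq_len(ns)) {
      A <- qtruncnorm(uA, config$pop_A[s], config$sd_A,
                      bounds$lower[["A"]], bounds$upper[["A"]])
      R <- qtruncnorm(uR, config$pop_R_per_s[s] / 1000,
                      config$sd_R_per_s / 1000,
                      bounds$lower[["R"]], bounds$upper[["R"]])
      I <- qtruncnorm(uI, config$pop_I_ms[s], config$sd_I_ms,
                      0, bounds$upper[["I"]])
      curves[[s]] <- list(A = A, R = R, I = I)
    }
    observers[[i]] <- structure(
      list(participant_id = sprintf("P%02d", i),
           curves = curves,
           lnbeta = rnorm(1, 0, config$sd_lnbeta),
           lapse_rate = config$lapse_rate,
           rt_meanlog = config$rt_meanlog,
           rt_sdlog = config$rt_sdlog,
           training_dprime = pmax(0, traj + rnorm(1, 0,
                                                  config$sd_training_dprime))),
      class = "observer_params")
  }
  observers
}

## response-generation probabilities P("different" | pair type)
response_probs <- function(dprime, lnbeta, model) {
  if (dprime < 1e-8) {
    p <- plogis(-lnbeta)  # flat likelihood ratio: bias-only guessing
    return(c(different = p, same = p))
  }
  hf <- switch(model,
               independent_observation = samediff_independent_rates(dprime, lnbeta),
               differencing = samediff_differencing_rates(
                 dprime, k = max(0, dprime / 2 + lnbeta)),
               yesno = c(h = pnorm(dprime / 2 - lnbeta),
                         f = pnorm(-dprime / 2 - lnbeta)))
  c(different = unname(hf[["h"]]), same = unname(hf[["f"]]))
}

simulate_trials <- function(observer, session_index, phase, durations_ms,
                            trials_per_duration, dprime_at, config) {
  per_dur <- lapply(durations_ms, function(t) {
    n <- trials_per_duration
    pair <- rep(c("different", "same"), each = n / 2)
    data.frame(encoding_duration_ms = t, pair_type = pair)
  })
  df <- do.call(rbind, per_dur)
  df <- df[sample.int(nrow(df)), , drop = FALSE]   # randomized trial order
  n <- nrow(df)
  p_diff <- lapply(durations_ms, function(t)
    response_probs(dprime_at(t), observer$lnbeta, config$model))
  names(p_diff) <- as.character(durations_ms)
  pr <- mapply(function(t, pt) p_diff[[as.character(t)]][[pt]],
               df$encoding_duration_ms, df$pair_type, USE.NAMES = FALSE)
  resp_diff <- runif(n) < pr
  lapse <- runif(n) < observer$lapse_rate
  resp_diff[lapse] <- runif(sum(lapse)) < 0.5
  response <- ifelse(resp_diff, "different", "same")
  response[runif(n) < config$omission_prob] <- "none"
  rt <- rlnorm(n, observer$rt_meanlog, observer$rt_sdlog)
  rt <- pmin(pmax(rt, 0.2), 5.0)
  out_lo <- runif(n) < config$rt_outlier_prob
  side <- runif(n) < 0.5
  rt[out_lo & side] <- runif(sum(out_lo & side), 0.02, 0.19)
  rt[out_lo & !side] <- runif(sum(out_lo & !side), 5.01, 6.5)
  data.frame(participant_id = observer$participant_id,
             session_index = session_index,
             phase = phase,
             trial_index = seq_len(n),
             encoding_duration_ms = df$encoding_duration_ms,
             pair_type = df$pair_type,
             response = response,
             response_time_s = round(rt, 4))
}

#' Simulate one evaluation (or generalization) session for one observer
#'
#' True sensitivity at each duration comes from the observer's encoding
#' curve for that session; responses are drawn from the configured
#' same-different decision model at the observer's criterion, with lapses
#' replaced by a fair coin.
#'
#' @param observer An `observer_params` entry from [sample_population()].
#' @param session_index Evaluation or generalization session index.
#' @param config A `simulation_config`.
#' @param curve Curve override (list A/R/I); defaults to the observer's
#'   curve for `session_index` (generalization uses scaled session-10
#'   parameters).
#' @param seed Optional seed for standalone use; inside [simulate_study()]
#'   the study seed governs the stream.
#' @return Data frame of trials (one session, canonical columns).
#' @export
simulate_evaluation_session <- function(observer, session_index, config,
                                        curve = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phase <- session_phase(session_index, config$schedule)
  if (phase == "training") stop("use simulate_training_course for training")
  if (is.null(curve)) {
    if (phase == "generalization") {
      base <- observer$curves[[as.character(max(config$schedule$evaluation))]]
      dec <- config$generalization_decrement
      curve <- list(A = max(base$A * dec[["A"]], config$bounds$lower[["A"]]),
                    R = base$R * dec[["R"]], I = base$I)
    } else {
      curve <- observer$curves[[as.character(session_index)]]
      if (is.null(curve)) stop("no curve for session ", session_index)
    }
  }
  dprime_at <- function(t) predict_encoding(curve, t, clamp = TRUE)
  simulate_trials(observer, session_index, phase, config$durations_ms,
                  config$trials_per_duration, dprime_at, config)
}

#' Simulate the six-session training course for all observers
#'
#' True d' at the 100 ms training duration follows each observer's
#' saturating learning trajectory.
#'
#' @param config A `simulation_config`.
#' @param observers Population from [sample_population()]; drawn afresh if
#'   omitted.
#' @return List with `trials` (data frame across all training sessions and
#'   observers) and `true_dprime` (observer x training-session matrix).
#' @export
simulate_training_course <- function(config, observers = NULL) {
  if (is.null(observers)) observers <- sample_population(config)
  set.seed(config$seed + 1L)
  sessions <- config$schedule$training
  rows <- list()
  true_d <- matrix(NA_real_, length(observers), length(sessions),
                   dimnames = list(vapply(observers, `[[`, "", "participant_id"),
                                   as.character(sessions)))
  for (i in seq_along(observers)) {
    obs <- observers[[i]]
    for (s in seq_along(sessions)) {
      d <- obs$training_dprime[s]
      true_d[i, s] <- d
      rows[[length(rows) + 1L]] <- simulate_trials(
        obs, sessions[s], "training", durations_ms = 100,
        trials_per_duration = config$training_trials,
        dprime_at = function(t) d, config)
    }
  }
  list(trials = do.call(rbind, rows), true_dprime = true_d)
}

#' Simulate a complete 11-session study
#'
#' Assembles training, evaluation and generalization sessions under the
#' default schedule and records every generating parameter in a manifest
#' for parameter-recovery scoring. Byte-identical output for identical
#' (config, seed).
#'
#' @param config A `simulation_config`.
#' @return List of class `synthetic_study`: `trials` (a `trial_table` over
#'   all sessions), `manifest` (generating parameters: config fields,
#'   per-observer curves, criteria, training trajectories).
#' @export
simulate_study <- function(config) {
  observers <- sample_population(config)
  training <- simulate_training_course(config, observers)
  set.seed(config$seed + 2L)
  rows <- list(training$trials)
  for (s in c(config$schedule$evaluation, config$schedule$generalization)) {
    for (obs in observers) {
      rows[[length(rows) + 1L]] <- simulate_evaluation_session(obs, s, config)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$participant_id, df$session_index, df$trial_index), ]
  rownames(df) <- NULL
  manifest <- list(
    seed = config$seed,
    model = config$model,
    n_participants = config$n_participants,
    durations_ms = config$durations_ms,
    trials_per_duration = config$trials_per_duration,
    training_trials = config$training_trials,
    pop_A = config$pop_A, pop_R_per_s = config$pop_R_per_s,
    pop_I_ms = config$pop_I_ms,
    sd_A = config$sd_A, sd_R_per_s = config$sd_R_per_s,
    sd_I_ms = config$sd_I_ms,
    lapse_rate = config$lapse_rate,
    generalization_decrement = as.list(config$generalization_decrement),
    observers = lapply(observers, function(o)
      list(participant_id = o$participant_id, curves = o$curves,
           lnbeta = o$lnbeta, training_dprime = o$training_dprime)))
  table <- new_trial_table(validate_trials(df, config$schedule),
                           meta = list(source = "synthetic",
                                       seed = config$seed, filters = list()))
  structure(list(trials = table, manifest = manifest,
                 true_training_dprime = training$true_dprime),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' One trial-log CSV per session plus a JSON manifest of generating
#' parameters.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return Invisible character vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in sort(unique(study$trials$session_index))) {
    sub <- study$trials[study$trials$session_index == s, , drop = FALSE]
    p <- file.path(dir, sprintf("session_%02d.csv", s))
    write_trials(new_trial_table(sub, trial_meta(study$trials)), p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(study$manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
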