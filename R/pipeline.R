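## Orchestration: runs the full analysis (filter -> inclusion ->
## sensitivity -> group aggregation -> encoding-curve fits -> inferential
## stats -> curve inversions) on trial-level logs, or the fit/inversion
## stages alone on a published-style summary table.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the study's defaults:
#' response-time window 0.2-5 s, independent-observation d' with half-count
#' correction, inclusion by >= 0.4 d' improvement between sessions 1 and 8,
#' 64-start bounded Levenberg-Marquardt fits, Benjamini-Hochberg q = 0.05,
#' inversion target d' = 1.68 (80% correct for an unbiased yes-no
#' observer).
#'
#' @param rt_lo_s,rt_hi_s Response-time window (inclusive).
#' @param model,correction Sensitivity model and rate correction.
#' @param delta_min,baseline_session,criterion_session Inclusion rule.
#' @param apply_inclusion Apply the inclusion rule (needs both sessions).
#' @param schedule Session schedule.
#' @param bounds,n_starts,fit_seed Encoding-curve fit settings.
#' @param bh_q False discovery rate for multiple comparisons.
#' @param target_dprime Sensitivity at which fitted curves are inverted.
#' @param min_trials Per-cell minimum responded trials before flagging.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(rt_lo_s = 0.2, rt_hi_s = 5.0,
                            model = "independent_observation",
                            correction = "half_count",
                            delta_min = 0.4, baseline_session = 1,
                            criterion_session = 8, apply_inclusion = TRUE,
                            schedule = default_session_schedule(),
                            bounds = encoding_bounds(), n_starts = 64L,
                            fit_seed = 1L, bh_q = 0.05,
                            target_dprime = dprime_from_pc(0.80),
                            min_trials = 10L) {
  stopifnot(rt_lo_s < rt_hi_s, bh_q > 0, bh_q < 1)
  structure(as.list(environment()), class = "analysis_config")
}

## per-participant, per-session pooled d' (all durations collapsed),
## used for the learning curve and the inclusion criterion
session_dprime <- function(table, config) {
  sensitivity_table(table, model = config$model,
                    correction = config$correction,
                    grouping = c("participant_id", "session_index"),
                    min_trials = config$min_trials)
}

#' Group sensitivity table (mean, SD, SEM per session x duration)
#'
#' @param sens Per-participant sensitivity table from
#'   [sensitivity_table()] with `session_index` and `encoding_duration_ms`
#'   columns.
#' @return Data frame with `session`, `duration_ms`, `n`, `mean_dprime`,
#'   `sd_dprime`, `sem_dprime` (SD/SEM are `NA` for single-participant
#'   cells).
#' @export
tabulate_group_sensitivity <- function(sens) {
  by <- list(session = sens$session_index,
             duration_ms = sens$encoding_duration_ms)
  out <- aggregate(sens$dprime, by = by,
                   FUN = function(x) c(n = length(x), m = mean(x),
                                       s = if (length(x) > 1) sd(x) else NA_real_))
  out <- data.frame(session = out$session, duration_ms = out$duration_ms,
                    n = out$x[, "n"], mean_dprime = out$x[, "m"],
                    sd_dprime = out$x[, "s"])
  out$sem_dprime <- out$sd_dprime / sqrt(out$n)
  out <- out[order(out$session, out$duration_ms), ]
  rownames(out) <- NULL
  out
}

#' Fit encoding curves to a summary table
#'
#' Runs the shifted-exponential fit on each session of a summary table of
#' group-mean sensitivities (the format of [load_reference_sensitivity()]),
#' which is what makes published results directly reproducible without
#' trial-level data.
#'
#' @param summary_df Data frame with columns `session`, `duration_ms`,
#'   `mean_dprime`.
#' @param config An `analysis_config` (fit settings are taken from it).
#' @return Named list of `encoding_fit` objects, one per session.
#' @export
fit_report_from_table <- function(summary_df, config = analysis_config()) {
  stopifnot(all(c("session", "duration_ms", "mean_dprime") %in%
                  names(summary_df)))
  sessions <- sort(unique(summary_df$session))
  fits <- lapply(sessions, function(s) {
    sub <- summary_df[summary_df$session == s, ]
    sub <- sub[order(sub$duration_ms), ]
    fit_encoding_curve(sub$duration_ms, sub$mean_dprime,
                       bounds = config$bounds, n_starts = config$n_starts,
                       seed = config$fit_seed)
  })
  names(fits) <- as.character(sessions)
  fits
}

#' Durations at which fitted curves reach a target sensitivity
#'
#' @param fits Named list of `encoding_fit` objects.
#' @param target_dprime Target d'.
#' @return Data frame `session`, `target_dprime`, `duration_ms` (`NA` where
#'   the target exceeds the asymptote).
#' @export
inversion_table <- function(fits, target_dprime) {
  ses <- names(fits)
  dur <- vapply(ses, function(s) {
    f <- fits[[s]]
    if (!isTRUE(f$converged) || target_dprime >= f$params$A) NA_real_
    else invert_duration(f$params, target_dprime)
  }, numeric(1))
  data.frame(session = ses, target_dprime = target_dprime,
             duration_ms = unname(dur))
}

## paired t-tests over a family of contrasts with BH correction
contrast_family <- function(wide, pairs, label) {
  rows <- lapply(pairs, function(pr) {
    a <- wide[[as.character(pr[1])]]; b <- wide[[as.character(pr[2])]]
    ok <- complete.cases(a, b)
    tt <- paired_t(b[ok], a[ok])
    data.frame(family = label,
               contrast = paste(pr[1], "vs", pr[2]),
               n = sum(ok), t = tt$t, df = tt$df, p_raw = tt$p_two_tailed,
               cohens_d = tt$cohens_d)
  })
  out <- do.call(rbind, rows)
  bh <- bh_adjust(out$p_raw, q = 0.05)
  out$p_bh_adjusted <- bh$p_adjusted
  out$significant <- bh$rejected
  out
}

to_wide <- function(df, id, key, value) {
  keys <- sort(unique(df[[key]]))
  ids <- sort(unique(df[[id]]))
  wide <- data.frame(id = ids)
  for (k in keys) {
    sub <- df[df[[key]] == k, c(id, value)]
    wide[[as.character(k)]] <- sub[[value]][match(ids, sub[[id]])]
  }
  wide
}

#' Run the full analysis pipeline
#'
#' Stages, in order: response-time filter; participant inclusion (when
#' training data for the baseline and criterion sessions are present);
#' per-participant sensitivity by session and encoding duration; group
#' aggregation; shifted-exponential fits per evaluation/generalization
#' session; learning-curve statistics (one-factor repeated-measures ANOVA
#' over training sessions, successive-session paired contrasts with BH
#' correction); inversion of every fitted curve at the target sensitivity.
#' Partial inputs produce a partial report with explicit `NULL` gaps.
#'
#' @param trials A `trial_table` covering at least one evaluation session.
#' @param config An `analysis_config`.
#' @return List of class `analysis_report` with elements `filter_report`,
#'   `inclusion`, `sensitivity`, `session_dprime`, `group_table`, `fits`,
#'   `learning_anova`, `learning_contrasts`, `inversions`, `config`, `log`.
#' @export
run_analysis <- function(trials, config = analysis_config()) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  n0 <- nrow(trials)

  flt <- filter_by_rt(trials, config$rt_lo_s, config$rt_hi_s)
  tbl <- flt$table
  note("rt_filter: kept %d of %d trials", nrow(tbl), n0)
  if (nrow(tbl) == 0L)
    stop("stage rt_filter removed every trial; check the window [",
         config$rt_lo_s, ", ", config$rt_hi_s, "] s")

  sess_d <- session_dprime(tbl, config)
  inclusion <- NULL
  eval_sessions <- intersect(unique(tbl$session_index),
                             c(config$schedule$evaluation,
                               config$schedule$generalization))
  if (length(eval_sessions) == 0L)
    stop("stage sensitivity: no evaluation or generalization sessions present")

  if (isTRUE(config$apply_inclusion) &&
      all(c(config$baseline_session, config$criterion_session) %in%
            tbl$session_index)) {
    dps <- data.frame(participant_id = sess_d$participant_id,
                      session_index = sess_d$session_index,
                      dprime = sess_d$dprime)
    inclusion <- apply_inclusion_criterion(dps, config$delta_min,
                                           config$baseline_session,
                                           config$criterion_session)
    if (length(inclusion$included) == 0L)
      stop("stage inclusion: no participants pass; deltas: ",
           paste(sprintf("%s=%.2f", inclusion$report$participant_id,
                         inclusion$report$delta), collapse = ", "))
    keep <- tbl$participant_id %in% inclusion$included
    tbl <- new_trial_table(as.data.frame(tbl)[keep, , drop = FALSE],
                           trial_meta(tbl))
    note("inclusion: %d included, %d excluded, %d undetermined",
         length(inclusion$included), length(inclusion$excluded),
         length(inclusion$undetermined))
    sess_d <- sess_d[sess_d$participant_id %in% inclusion$included, ]
  } else {
    note("inclusion: skipped (sessions absent or disabled)")
  }

  eval_tbl <- new_trial_table(
    as.data.frame(tbl)[tbl$session_index %in% eval_sessions, , drop = FALSE],
    trial_meta(tbl))
  sens <- sensitivity_table(eval_tbl, model = config$model,
                            correction = config$correction,
                            min_trials = config$min_trials)
  note("sensitivity: %d cells over sessions %s", nrow(sens),
       paste(sort(eval_sessions), collapse = ","))
  group <- tabulate_group_sensitivity(sens)

  fits <- fit_report_from_table(
    data.frame(session = group$session, duration_ms = group$duration_ms,
               mean_dprime = group$mean_dprime), config)
  note("fits: %d sessions, %d converged", length(fits),
       sum(vapply(fits, function(f) isTRUE(f$converged), logical(1))))

  learning_anova <- NULL; learning_contrasts <- NULL
  train_sessions <- intersect(unique(tbl$session_index),
                              config$schedule$training)
  if (length(train_sessions) >= 2) {
    train_d <- sess_d[sess_d$session_index %in% train_sessions, ]
    complete_ids <- names(which(table(train_d$participant_id) ==
                                  length(train_sessions)))
    train_d <- train_d[train_d$participant_id %in% complete_ids, ]
    if (length(complete_ids) >= 3) {
      learning_anova <- rm_anova(train_d, dv = "dprime",
                                 subject = "participant_id",
                                 within = "session_index")
      wide <- to_wide(train_d, "participant_id", "session_index", "dprime")
      ses <- sort(train_sessions)
      pairs <- Map(c, ses[-length(ses)], ses[-1])
      learning_contrasts <- contrast_family(wide, pairs,
                                            "successive training sessions")
      note("learning: ANOVA over %d sessions, %d participants",
           length(train_sessions), length(complete_ids))
    }
  }

  report <- list(filter_report = flt$report,
                 inclusion = inclusion,
                 sensitivity = sens,
                 session_dprime = sess_d,
                 group_table = group,
                 fits = fits,
                 learning_anova = learning_anova,
                 learning_contrasts = learning_contrasts,
                 inversions = inversion_table(fits, config$target_dprime),
                 config = config,
                 log = log)
  class(report) <- "analysis_report"
  report
}

#' Write an analysis report to a directory
#'
#' TSV tables, a JSON fit summary and a plain-text run log.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return Invisible vector of written paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_stats_table(report$group_table, file.path(dir, "group_sensitivity.tsv")),
    write_sensitivity_table(report$sensitivity, file.path(dir, "sensitivity.tsv")),
    write_stats_table(report$inversions, file.path(dir, "inversions.tsv")))
  fits <- lapply(names(report$fits), function(s)
    encoding_fit_summary(report$fits[[s]], session = s))
  jsonlite::write_json(fits, file.path(dir, "fits.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(report$learning_contrasts))
    paths <- c(paths, write_stats_table(report$learning_contrasts,
                                        file.path(dir, "learning_contrasts.tsv")))
  if (!is.null(report$learning_anova))
    paths <- c(paths, write_stats_table(as.data.frame(report$learning_anova),
                                        file.path(dir, "learning_anova.tsv")))
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(c(paths, file.path(dir, "fits.json"), file.path(dir, "run.log")))
}

#' Bundled published sensitivity summary
#'
#' Group-level mean (± SD) sensitivity per encoding duration, as printed
#' for the four evaluation sessions (n = 27) and the generalization session
#' (n = 16) of a Kanji same-different discrimination training study. These
#' summaries are the inputs that make the published curve fits reproducible
#' at desk scale.
#'
#' @return Data frame with columns `session`, `duration_ms`, `mean_dprime`,
#'   `sd_dprime`, `n`.
#' @export
load_reference_sensitivity <- function() {
  path <- system.file("extdata", "kanji_sensitivity_summary.tsv",
                      package = "perclearn", mustWork = TRUE)
  utils::read.delim(path)
}
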