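## Trial-level data model, I/O and filtering for same-different experiments.

TRIAL_COLUMNS <- c("participant_id", "session_index", "phase", "trial_index",
                   "encoding_duration_ms", "pair_type", "response",
                   "response_time_s")

PHASES <- c("training", "evaluation", "generalization")
PAIR_TYPES <- c("same", "different")
RESPONSES <- c("same", "different", "none")

#' Default 11-session schedule
#'
#' The default experimental schedule: four evaluation sessions (1, 4, 7, 10)
#' interleaved with six training sessions (2, 3, 5, 6, 8, 9), followed by a
#' generalization session (11) with novel exemplars of the trained category.
#'
#' @return Named list with integer vectors `training`, `evaluation` and
#'   `generalization`.
#' @export
default_session_schedule <- function() {
  list(training = c(2L, 3L, 5L, 6L, 8L, 9L),
       evaluation = c(1L, 4L, 7L, 10L),
       generalization = 11L)
}

#' Map session indices to phases
#'
#' @param session_index Integer vector of session indices.
#' @param schedule Schedule list as returned by [default_session_schedule()].
#' @return Character vector of phases (`"training"`, `"evaluation"`,
#'   `"generalization"`).
#' @export
session_phase <- function(session_index, schedule = default_session_schedule()) {
  out <- rep(NA_character_, length(session_index))
  for (ph in names(schedule)) out[session_index %in% schedule[[ph]]] <- ph
  if (anyNA(out)) {
    bad <- unique(session_index[is.na(out)])
    stop("session index not in schedule: ", paste(bad, collapse = ", "))
  }
  out
}

#' Evaluation-session encoding durations (ms)
#'
#' The eight first-stimulus durations used in evaluation and generalization
#' sessions; multiples of a 60 Hz frame. Training trials always use 100 ms.
#'
#' @return Numeric vector of durations in milliseconds.
#' @export
evaluation_durations <- function() c(17, 50, 84, 117, 150, 234, 500, 1000)

#' Session design specification
#'
#' Describes the trial composition of one session: 360 trials at 100 ms for
#' training; 480 trials for evaluation/generalization (60 per encoding
#' duration, 30 same / 30 different). The stimulus onset asynchrony recorded
#' as metadata is the encoding duration plus the 0.5 s backward mask.
#'
#' @param phase One of `"training"`, `"evaluation"`, `"generalization"`.
#' @param durations_ms Encoding durations; defaults depend on phase.
#' @param trials_per_duration Trials per duration (split 1:1 same:different).
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(phase = c("evaluation", "training", "generalization"),
                         durations_ms = NULL, trials_per_duration = NULL) {
  phase <- match.arg(phase)
  if (is.null(durations_ms))
    durations_ms <- if (phase == "training") 100 else evaluation_durations()
  if (is.null(trials_per_duration))
    trials_per_duration <- if (phase == "training") 360 else 60
  if (trials_per_duration %% 2 != 0)
    stop("trials_per_duration must be even (equal same/different counts)")
  spec <- list(phase = phase,
               durations_ms = durations_ms,
               trials_per_duration = trials_per_duration,
               n_trials = trials_per_duration * length(durations_ms),
               same_per_duration = trials_per_duration / 2,
               soa_s = durations_ms / 1000 + 0.5)
  class(spec) <- "session_spec"
  spec
}

new_trial_table <- function(df, meta = list()) {
  stopifnot(is.data.frame(df))
  if (is.null(meta$filters)) meta$filters <- list()
  structure(df, meta = meta, class = c("trial_table", "data.frame"))
}

#' Trial-table metadata
#'
#' @param table A `trial_table`.
#' @return Provenance list: source path, append-only filter history, seed for
#'   synthetic tables, preserved extra columns.
#' @export
trial_meta <- function(table) attr(table, "meta")

append_filter_record <- function(table, record) {
  meta <- trial_meta(table)
  meta$filters <- c(meta$filters, list(record))
  attr(table, "meta") <- meta
  table
}

validate_trials <- function(df, schedule = default_session_schedule(),
                            check_schedule = TRUE) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("trial log is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  row_err <- function(rows, what) {
    stop(sprintf("invalid trial rows (%s) at line(s): %s", what,
                 paste(utils::head(rows, 10L), collapse = ", ")))
  }
  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  for (col in c("session_index", "trial_index", "encoding_duration_ms",
                "response_time_s")) {
    v <- num(col)
    if (anyNA(v)) row_err(which(is.na(v)), paste("unparsable", col))
    df[[col]] <- v
  }
  if (any(df$response_time_s < 0))
    row_err(which(df$response_time_s < 0), "negative response_time_s")
  if (any(df$encoding_duration_ms <= 0))
    row_err(which(df$encoding_duration_ms <= 0), "non-positive encoding duration")
  if (any(df$trial_index < 1))
    row_err(which(df$trial_index < 1), "trial_index < 1")
  for (col in c("phase", "pair_type", "response")) df[[col]] <- as.character(df[[col]])
  allowed <- list(phase = PHASES, pair_type = PAIR_TYPES, response = RESPONSES)
  for (col in names(allowed)) {
    bad <- !(df[[col]] %in% allowed[[col]])
    if (any(bad)) row_err(which(bad), paste("unknown", col, "value"))
  }
  if (check_schedule) {
    ph <- session_phase(df$session_index, schedule)
    bad <- ph != df$phase
    if (any(bad)) row_err(which(bad), "phase inconsistent with session schedule")
  }
  key <- paste(df$participant_id, df$session_index, df$trial_index)
  if (anyDuplicated(key))
    row_err(which(duplicated(key)), "duplicate (participant, session, trial) key")
  df$correct <- df$response == df$pair_type  # FALSE for "none" by construction
  df
}

#' Read a trial log
#'
#' Reads a delimited trial log (comma by default, tab accepted) with the
#' canonical header `participant_id, session_index, phase, trial_index,
#' encoding_duration_ms, pair_type, response, response_time_s`. Unknown extra
#' columns are preserved and listed in the table metadata. A derived logical
#' column `correct` (`response == pair_type`) is added; it is always `FALSE`
#' for omitted (`"none"`) responses.
#'
#' @param path Path to the file.
#' @param sep Field separator, `","` or `"\t"`.
#' @param schedule Session schedule used to cross-check the `phase` column;
#'   set `check_schedule = FALSE` for non-standard designs.
#' @param check_schedule Validate `phase` against `schedule`?
#' @return A `trial_table` (data frame subclass with provenance metadata).
#' @export
read_trials <- function(path, sep = ",", schedule = default_session_schedule(),
                        check_schedule = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  df <- validate_trials(df, schedule, check_schedule)
  extra <- setdiff(names(df), c(TRIAL_COLUMNS, "correct"))
  new_trial_table(df, meta = list(source = path, extra_columns = extra,
                                  filters = list()))
}

#' Write a trial log
#'
#' Inverse of [read_trials()]; writes the canonical columns (plus any
#' preserved extras) so that a read/write cycle round-trips field for field.
#'
#' @param table A `trial_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path, sep = ",") {
  df <- as.data.frame(table)
  df$correct <- NULL  # derived; recomputed on read
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter trials by response time
#'
#' Keeps trials whose response time lies in the closed interval
#' `[lo_s, hi_s]` (0.2 to 5.0 s by default, the response deadline). The
#' report accounts for every input trial: kept + removed = input, per
#' participant and session.
#'
#' @param table A `trial_table`.
#' @param lo_s,hi_s Window bounds in seconds, inclusive.
#' @return List with elements `table` (filtered `trial_table`) and `report`
#'   (data frame: participant_id, session_index, n_input, n_kept, n_removed).
#' @export
filter_by_rt <- function(table, lo_s = 0.2, hi_s = 5.0) {
  stopifnot(lo_s < hi_s)
  df <- as.data.frame(table)
  keep <- df$response_time_s >= lo_s & df$response_time_s <= hi_s
  if (nrow(df) == 0L) {
    report <- data.frame(participant_id = character(), session_index = numeric(),
                         n_input = integer(), n_kept = integer(),
                         n_removed = integer())
  } else {
    by <- df[c("participant_id", "session_index")]
    report <- aggregate(cbind(n_input = rep(1L, nrow(df)), n_kept = keep),
                        by = by, FUN = sum)
    report$n_removed <- report$n_input - report$n_kept
    report <- report[order(report$participant_id, report$session_index), ]
    rownames(report) <- NULL
  }
  out <- new_trial_table(df[keep, , drop = FALSE], trial_meta(table))
  out <- append_filter_record(out, list(filter = "rt_window", lo_s = lo_s,
                                        hi_s = hi_s, kept = sum(keep),
                                        removed = sum(!keep)))
  list(table = out, report = structure(report, class = c("filter_report",
                                                         "data.frame")))
}

#' Serialize a filter report
#'
#' @param report A `filter_report` from [filter_by_rt()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(report), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Participant inclusion by training improvement
#'
#' A participant is included when sensitivity improved by at least
#' `delta_min` between a baseline and a criterion session
#' (d'(criterion) - d'(baseline) >= delta_min; default sessions 1 and 8,
#' minimum improvement 0.4 d'). Participants missing either session are
#' flagged `"undetermined"` and belong to neither list.
#'
#' @param dprime_by_session Data frame with columns `participant_id`,
#'   `session_index`, `dprime` (one row per participant and session).
#' @param delta_min Minimum d' improvement (inclusive).
#' @param baseline_session,criterion_session Session indices compared.
#' @return List with `included`, `excluded`, `undetermined` (character
#'   vectors) and `report` (per-participant deltas and decisions).
#' @export
apply_inclusion_criterion <- function(dprime_by_session, delta_min = 0.4,
                                      baseline_session = 1,
                                      criterion_session = 8) {
  req <- c("participant_id", "session_index", "dprime")
  if (!all(req %in% names(dprime_by_session)))
    stop("dprime_by_session needs columns: ", paste(req, collapse = ", "))
  ids <- unique(as.character(dprime_by_session$participant_id))
  pick <- function(id, s) {
    v <- dprime_by_session$dprime[
      dprime_by_session$participant_id == id &
        dprime_by_session$session_index == s]
    if (length(v) == 1L && is.finite(v)) v else NA_real_
  }
  base <- vapply(ids, pick, numeric(1), s = baseline_session)
  crit <- vapply(ids, pick, numeric(1), s = criterion_session)
  delta <- crit - base
  ## inclusive threshold with a numerical guard: a participant whose
  ## improvement equals delta_min must not be excluded by rounding of the
  ## subtraction
  eps <- sqrt(.Machine$double.eps)
  decision <- ifelse(is.na(delta), "undetermined",
                     ifelse(delta >= delta_min - eps, "included", "excluded"))
  report <- data.frame(participant_id = ids, dprime_baseline = base,
                       dprime_criterion = crit, delta = delta,
                       decision = decision, row.names = NULL)
  list(included = ids[decision == "included"],
       excluded = ids[decision == "excluded"],
       undetermined = ids[decision == "undetermined"],
       report = report)
}

#' Tally hits, false alarms and omissions per cell
#'
#' Builds the count table feeding d' estimation. "Different" pairs are the
#' signal class: a hit is a "different" response to a different pair, a
#' false alarm a "different" response to a same pair. Omissions (`"none"`
#' responses) are counted separately and excluded from the same/different
#' trial totals, so `n_hit <= n_different_trials` and
#' `n_fa <= n_same_trials` hold with responded trials only.
#'
#' @param table A `trial_table`.
#' @param grouping Character vector of trial fields defining the cells.
#' @return Data frame of class `count_table`: one row per cell with columns
#'   `n_different_trials`, `n_same_trials`, `n_hit`, `n_fa`, `n_omit`.
#' @export
summarize_counts <- function(table,
                             grouping = c("participant_id", "session_index",
                                          "encoding_duration_ms")) {
  df <- as.data.frame(table)
  bad <- setdiff(grouping, names(df))
  if (length(bad)) stop("grouping field(s) not in trial table: ",
                        paste(bad, collapse = ", "))
  responded <- df$response != "none"
  agg <- function(x) {
    out <- aggregate(x, by = df[grouping], FUN = sum)
    names(out)[ncol(out)] <- "n"
    out
  }
  base <- aggregate(rep(1L, nrow(df)), by = df[grouping], FUN = sum)
  names(base)[ncol(base)] <- "n_total"
  add <- function(res, flag, nm) {
    a <- aggregate(as.integer(flag), by = df[grouping], FUN = sum)
    names(a)[ncol(a)] <- nm
    merge(res, a, by = grouping, sort = FALSE)
  }
  res <- base
  res <- add(res, responded & df$pair_type == "different", "n_different_trials")
  res <- add(res, responded & df$pair_type == "same", "n_same_trials")
  res <- add(res, responded & df$pair_type == "different" &
               df$response == "different", "n_hit")
  res <- add(res, responded & df$pair_type == "same" &
               df$response == "different", "n_fa")
  res <- add(res, !responded, "n_omit")
  res <- res[do.call(order, res[grouping]), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("count_table", "data.frame"))
}
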