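#' Read a long-format event table
#'
#' Expects a delimited file with header columns `subject_id`, `event`,
#' `time`, `status` (status 1 = observed, 0 = censored).  Duplicate
#' `(subject, event)` rows are collapsed to the earliest time, matching
#' the convention that the first onset of a recurring diagnosis defines
#' the event.  Times given in days are converted to the 1-52 week grid
#' with [to_weeks()]; censored records then carry the sentinel week 53.
#'
#' @param path CSV or TSV file path.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.tsv` means tab, otherwise comma).
#' @param time_unit `"weeks"` (leave times untouched) or `"days"`
#'   (convert).
#' @return A validated long-format data frame (`subject_id`, `event`,
#'   `time`, `status`).
#' @export
read_events <- function(path, sep = NULL, time_unit = c("weeks", "days")) {
  time_unit <- match.arg(time_unit)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "event", "time", "status")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad_time <- which(!is.finite(suppressWarnings(as.numeric(df$time))))
  if (length(bad_time))
    stop("non-numeric time value(s) at data line(s) ",
         paste(head(bad_time, 5), collapse = ", "))
  df$time <- as.numeric(df$time)
  bad_status <- which(!(df$status %in% c(0, 1)))
  if (length(bad_status))
    stop("status outside {0, 1} at data line(s) ",
         paste(head(bad_status, 5), collapse = ", "))
  # earliest occurrence wins for duplicated (subject, event) records;
  # among ties an observed record beats a censored one
  df <- df[order(df$subject_id, df$event, df$time, -df$status), ]
  df <- df[!duplicated(df[, c("subject_id", "event")]), ]
  if (time_unit == "days") {
    obs <- df$status == 1
    df$time[obs] <- to_weeks(df$time[obs])
    df$time[!obs] <- 53
  }
  rownames(df) <- NULL
  check_event_table(df)
}

#' Convert a day of the year to a study week
#'
#' `week = ceiling(day / 7)`, capped at 52 so that the full year maps onto
#' the 1-52 analysis grid (week 53 is reserved as the censoring sentinel
#' and is assigned by the censoring rule, not by this function).
#'
#' @param day Day number(s), `1 <= day <= 366`.
#' @return Integer week(s) in 1..52.
#' @export
to_weeks <- function(day) {
  if (any(day < 1) || any(day > 366)) stop("day must be in 1..366")
  pmin(as.integer(ceiling(day / 7)), 52L)
}

#' Filter subjects by number of observed events
#'
#' Retains subjects with at least `min_events` observed events.  With
#' `fully_observed = TRUE` only subjects whose every event in the table is
#' observed are kept (the uncensored subgroup).
#'
#' @param table Long-format event table.
#' @param min_events Minimum number of observed events per subject.
#' @param fully_observed Keep only subjects with no censored events.
#' @return The filtered table.
#' @export
filter_patients <- function(table, min_events = 2, fully_observed = FALSE) {
  check_event_table(table)
  obs_counts <- tapply(table$status, table$subject_id, sum)
  keep <- names(obs_counts)[obs_counts >= min_events]
  if (fully_observed) {
    tot <- tapply(table$status, table$subject_id, length)
    all_obs <- names(obs_counts)[obs_counts == tot]
    keep <- intersect(keep, all_obs)
  }
  out <- table[table$subject_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select frequently observed events
#'
#' Event labels whose observed fraction across subjects exceeds
#' `min_rate`, sorted by rate descending.  Mirrors restricting an analysis
#' to diagnoses with a high enough diagnosis rate for precedence and
#' network analysis to be reliable.
#'
#' @param table Long-format event table.
#' @param min_rate Minimum observed fraction (default 0.70).
#' @return Character vector of selected labels (attribute `rates` carries
#'   all rates).
#' @export
select_top_events <- function(table, min_rate = 0.70) {
  check_event_table(table)
  rates <- tapply(table$status, table$event, mean)
  sel <- sort(rates[rates > min_rate], decreasing = TRUE)
  structure(names(sel), rates = rates)
}

#' Specification for a synthetic neonatal-style cohort
#'
#' Describes a cohort on the 1-52 week grid with censoring sentinel 53:
#' an early-onset anchor event (emulating the dominant respiratory
#' diagnoses), dependent events that follow the anchor at positive
#' latencies, and independent events.  Onsets are rounded to whole weeks;
#' each event is censored independently with its own probability, in
#' which case the record gets week 53 and status 0.
#'
#' @param n_subjects Number of subjects.
#' @param anchor_label Label of the anchor event.
#' @param anchor_median Median onset week of the anchor.
#' @param anchor_censoring Censoring probability of the anchor.
#' @param dependent Named list: for each dependent event, a list with
#'   `offset` (median latency in weeks after the anchor), `spread`
#'   (geometric-like dispersion of the latency) and `censoring`.
#' @param independent Named list: for each independent event, a list with
#'   `median` (onset week) and `censoring`.
#' @param seed Integer seed used by [generate_cohort()].
#' @return A `cepa_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1000,
                        anchor_label = "RESP",
                        anchor_median = 5, anchor_censoring = 0.01,
                        dependent = list(
                          SKIN = list(offset = 3, spread = 2,
                                      censoring = 0.07),
                          DIGE = list(offset = 8, spread = 4,
                                      censoring = 0.18),
                          EAR = list(offset = 9, spread = 4,
                                     censoring = 0.19)),
                        independent = list(
                          INFE = list(median = 10, censoring = 0.05),
                          EYE = list(median = 20, censoring = 0.14),
                          INJU = list(median = 27, censoring = 0.24)),
                        seed = 20240502) {
  stopifnot(n_subjects >= 1, anchor_median >= 1, anchor_median <= 52,
            anchor_censoring >= 0, anchor_censoring <= 1)
  for (d in dependent) stopifnot(d$offset > 0, d$spread > 0,
                                 d$censoring >= 0, d$censoring <= 1)
  for (d in independent) stopifnot(d$median >= 1, d$median <= 52,
                                   d$censoring >= 0, d$censoring <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 anchor_label = anchor_label, anchor_median = anchor_median,
                 anchor_censoring = anchor_censoring, dependent = dependent,
                 independent = independent, seed = as.integer(seed)),
            class = "cepa_cohort_spec")
}

# onset draw with a given median on the week grid: exponential shifted to
# start at week 1, rate fixed by the median, rounded up to whole weeks
draw_onset <- function(n, median_week) {
  rate <- log(2) / max(median_week - 0.5, 0.5)
  pmin(ceiling(0.5 + rexp(n, rate)), 52L)
}

#' Generate a synthetic cohort
#'
#' Draws onsets per [cohort_spec()]: the anchor from a skewed early-onset
#' distribution, dependent events at `anchor + latency` (latency positive,
#' median `offset` weeks), independent events from their own onset
#' distributions.  Onset weeks are capped at 52; censored events get the
#' sentinel week 53 and status 0.  Fully deterministic given the spec's
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @return Long-format event table (one row per subject and event).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cepa_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    ids <- sprintf("S%05d", seq_len(n))
    anchor <- draw_onset(n, spec$anchor_median)
    rows <- list(data.frame(subject_id = ids, event = spec$anchor_label,
                            time = anchor, status = 1L))
    for (lab in names(spec$dependent)) {
      d <- spec$dependent[[lab]]
      # positive latency after the anchor: gamma with mean `offset` weeks
      # and sd `spread`, rounded up to whole weeks
      shape <- (d$offset / d$spread)^2
      rate <- d$offset / d$spread^2
      lat <- pmax(1L, ceiling(stats::rgamma(n, shape = shape, rate = rate)))
      rows[[length(rows) + 1]] <-
        data.frame(subject_id = ids, event = lab,
                   time = pmin(anchor + lat, 52L), status = 1L)
    }
    for (lab in names(spec$independent)) {
      d <- spec$independent[[lab]]
      rows[[length(rows) + 1]] <-
        data.frame(subject_id = ids, event = lab,
                   time = draw_onset(n, d$median), status = 1L)
    }
    out <- do.call(rbind, rows)
    # independent per-event censoring, sentinel week 53
    cens_prob <- c(setNames(spec$anchor_censoring, spec$anchor_label),
                   vapply(spec$dependent, `[[`, numeric(1), "censoring"),
                   vapply(spec$independent, `[[`, numeric(1), "censoring"))
    cens <- rbinom(nrow(out), 1, cens_prob[out$event]) == 1
    out$time[cens] <- 53
    out$status[cens] <- 0L
    out <- out[order(out$subject_id, out$event), ]
    rownames(out) <- NULL
    out
  })
}

#' End-to-end cohort precedence analysis
#'
#' Runs the full pipeline on a long-format event table: event summaries,
#' the all-pairs precedence matrix, sequence ranking, valid-sequence
#' selection, the precedence network, and (optionally) the diagnosis-gap
#' table for an anchor event.  The root region is the week grid
#' `[1, 54)` squared, covering weeks 1-52 plus the censoring sentinel bin.
#'
#' @param table Long-format event table (weeks 1-53 with sentinel 53 for
#'   censored events).
#' @param config An [opt_config()].
#' @param events Event labels to analyse; default [select_top_events()]
#'   with `min_rate = 0.70`.
#' @param anchor Anchor label for the diagnosis-gap table; default the
#'   most frequently observed event.
#' @param valid_threshold_pct Percent rule for valid sequences (default 2).
#' @param bidir_band No-priority band for network edges (default 0.05).
#' @param min_subjects Guard: smallest cohort the pipeline will accept.
#' @return A `cepa_report` list: `summary`, `precedence`, `ranking`,
#'   `valid`, `network`, `gaps`, `events`, `n_subjects`, `config`.
#' @export
run_cohort_analysis <- function(table, config = opt_config(), events = NULL,
                                anchor = NULL, valid_threshold_pct = 2,
                                bidir_band = 0.05, min_subjects = 50) {
  check_event_table(table)
  if (is.null(events)) events <- as.character(select_top_events(table))
  if (length(events) < 2)
    stop("at least two selected events are required")
  table <- table[table$event %in% events, , drop = FALSE]
  subjects <- unique(table$subject_id)
  if (length(subjects) < min_subjects)
    stop(sprintf("cohort has %d subjects; at least %d required",
                 length(subjects), min_subjects))
  wide <- events_wide(table, events)
  root <- region(1, 54, 1, 54)
  summary_tab <- summarize_events(table, t_max = 52)
  pm <- pairwise_matrix(wide$times, wide$status, root = root, config = config)
  ranking <- rank_sequences(pm)
  valid <- valid_sequences(ranking, valid_threshold_pct)
  network <- build_network(valid, pm, bidir_band)
  if (is.null(anchor)) {
    rates <- tapply(table$status, table$event, mean)
    anchor <- names(which.max(rates))
  }
  gaps <- lapply(setdiff(events, anchor), function(lab)
    diagnosis_gap(table, anchor, lab))
  names(gaps) <- setdiff(events, anchor)
  structure(list(summary = summary_tab, precedence = pm, ranking = ranking,
                 valid = valid, network = network, gaps = gaps,
                 anchor = anchor, events = events,
                 n_subjects = length(subjects), config = config),
            class = "cepa_report")
}

#' @export
print.cepa_report <- function(x, ...) {
  cat(sprintf("<cepa_report: %d subjects, %d events>\n", x$n_subjects,
              length(x$events)))
  cat("\nEvent summary:\n")
  print(x$summary)
  cat(sprintf("\nTop sequences (of %d ranked, %d valid):\n",
              nrow(x$ranking), nrow(x$valid)))
  print(head(x$ranking, 6))
  print(x$network)
  invisible(x)
}

#' Pivot a long event table to wide time/status matrices
#'
#' @param table Long-format event table.
#' @param events Labels to include (default all); every subject must have
#'   a record for each.
#' @return List of `times` and `status` matrices (subjects x events).
#' @export
events_wide <- function(table, events = NULL) {
  check_event_table(table)
  if (is.null(events)) events <- sort(unique(table$event))
  table <- table[table$event %in% events, , drop = FALSE]
  subjects <- sort(unique(table$subject_id))
  times <- matrix(NA_real_, length(subjects), length(events),
                  dimnames = list(subjects, events))
  status <- times
  times[cbind(match(table$subject_id, subjects),
              match(table$event, events))] <- table$time
  status[cbind(match(table$subject_id, subjects),
               match(table$event, events))] <- table$status
  if (anyNA(times))
    stop("every subject must have a record for every selected event")
  list(times = times, status = status)
}

#' Serialize a cohort report
#'
#' Writes the report tables as CSV (summary, precedence matrix, ranking,
#' valid sequences, per-event gap tables), the network as GraphML and DOT,
#' and a JSON index with run metadata.
#'
#' @param report A `cepa_report`.
#' @param dir Output directory (created if needed).
#' @export
write_cepa_report <- function(report, dir) {
  stopifnot(inherits(report, "cepa_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$summary, file.path(dir, "event_summary.csv"),
            row.names = FALSE)
  write_precedence_csv(report$precedence, file.path(dir, "precedence.csv"))
  write.csv(report$ranking, file.path(dir, "sequences.csv"),
            row.names = FALSE)
  write.csv(report$valid, file.path(dir, "valid_sequences.csv"),
            row.names = FALSE)
  write_network(report$network, file.path(dir, "network.graphml"), "graphml")
  write_network(report$network, file.path(dir, "network.dot"), "dot")
  for (lab in names(report$gaps))
    write.csv(report$gaps[[lab]],
              file.path(dir, sprintf("gap_%s.csv", lab)), row.names = FALSE)
  meta <- list(events = report$events, anchor = report$anchor,
               n_subjects = report$n_subjects,
               config = unclass(report$config),
               package_version = as.character(utils::packageVersion("cepa")))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
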