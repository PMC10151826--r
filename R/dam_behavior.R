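#' Score sleep architecture from a DAM record
#'
#' Sleep is the field-standard definition: a maximal run of consecutive
#' zero-count bins lasting at least `min_sleep_min` minutes (default 5).
#' Analysis starts at the first lights-on (ZT0) after the recording start and
#' covers `window_days` complete 24-h cycles. Sleep is split into day
#' (ZT0-12) and night (ZT12-24) at lights-off; a bout spanning the boundary
#' contributes minutes to each phase pro rata (per bin) by default, or
#' entirely to its onset phase with `boundary = "onset"`. Minute totals are
#' averaged per 24 h over the window. Bins flagged `NA` (bad monitor status)
#' are treated as waking bins with no counts.
#'
#' @param record An [activity_record()].
#' @param window_days Number of complete days to score; default all complete
#'   days available after ZT0. Errors if the record is shorter.
#' @param min_sleep_min Minimum inactivity run counted as sleep, minutes.
#' @param boundary `"prorate"` (default) or `"onset"` for phase assignment of
#'   boundary-spanning bouts.
#' @return One-row `data.frame` of class `sleep_summary`: `fly_id`,
#'   `total_sleep_min`, `day_sleep_min`, `night_sleep_min` (per 24 h),
#'   `bout_count_day`, `bout_count_night` (per 24 h, by onset phase),
#'   `mean_bout_len_min`, `waking_minutes` (total over window),
#'   `waking_activity` (counts per waking minute; `NA` if the fly never
#'   wakes), `window_days`.
#' @examples
#' rec <- simulate_activity(1, days = 2, seed = 3)[[1]]
#' score_sleep(rec)
#' @export
score_sleep <- function(record, window_days = NULL, min_sleep_min = 5,
                        boundary = c("prorate", "onset")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(record, "activity_record"), min_sleep_min > 0)
  bin_s <- record$bin_s
  bpd <- 86400 / bin_s
  bpm <- 60 / bin_s
  i0 <- zt0_index(record)
  avail <- floor((length(record$counts) - i0 + 1) / bpd)
  if (is.null(window_days)) window_days <- avail
  if (window_days < 1 || avail < window_days)
    mrdam_stop(sprintf("record spans %d complete day(s) after ZT0; %s requested",
                       avail, format(window_days)), "mrdam_validation_error")
  use <- record$counts[i0:(i0 + window_days * bpd - 1)]
  min_bins <- round(min_sleep_min * bpm)
  zero <- !is.na(use) & use == 0
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sleep_run <- r$values & r$lengths >= min_bins
  asleep <- logical(length(use))
  for (k in which(sleep_run)) asleep[starts[k]:ends[k]] <- TRUE
  zt_h <- (((seq_along(use) - 1L) %% bpd) * bin_s) / 3600
  is_day <- zt_h < record$day_h
  if (boundary == "prorate") {
    day_min <- sum(asleep & is_day) / bpm
    night_min <- sum(asleep & !is_day) / bpm
  } else {
    day_min <- night_min <- 0
    for (k in which(sleep_run)) {
      len_min <- r$lengths[k] / bpm
      if (is_day[starts[k]]) day_min <- day_min + len_min
      else night_min <- night_min + len_min
    }
  }
  n_bouts <- sum(sleep_run)
  onset_day <- sum(is_day[starts[sleep_run]])
  total_sleep <- sum(asleep) / bpm
  waking_min <- length(use) / bpm - total_sleep
  out <- data.frame(
    fly_id = record$fly_id,
    total_sleep_min = (day_min + night_min) / window_days,
    day_sleep_min = day_min / window_days,
    night_sleep_min = night_min / window_days,
    bout_count_day = onset_day / window_days,
    bout_count_night = (n_bouts - onset_day) / window_days,
    mean_bout_len_min = if (n_bouts > 0) total_sleep / n_bouts else NA_real_,
    waking_minutes = waking_min,
    waking_activity = if (waking_min > 0)
      sum(use, na.rm = TRUE) / waking_min else NA_real_,
    window_days = window_days,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sleep_summary", "data.frame")
  attr(out, "params") <- list(window_days = window_days,
                              min_sleep_min = min_sleep_min,
                              boundary = boundary)
  out
}

#' Waking activity of a scored fly
#'
#' Total beam-break counts divided by the number of minutes not scored as
#' sleep over the scoring window. Undefined (returned as `NA` with a
#' warning) for a fly that never wakes.
#'
#' @param record An [activity_record()].
#' @param summary Optional [score_sleep()] result for `record`; recomputed
#'   with defaults when omitted.
#' @return Counts per waking minute (scalar).
#' @export
waking_activity <- function(record, summary = NULL) {
  if (is.null(summary)) summary <- score_sleep(record)
  if (summary$waking_minutes <= 0) {
    warning("fly has no waking time; waking activity undefined")
    return(NA_real_)
  }
  summary$waking_activity
}

#' Circadian rhythmicity index with inclusion flag
#'
#' Autocorrelation-based rhythmicity statistic: activity is aggregated into
#' `agg_min`-minute bins, and the peak positive autocorrelation over lags
#' within `lag_window_h` (default 22-26 h, bracketing the 24-h circadian
#' period) is divided by a one-sided white-noise significance envelope,
#' Bonferroni-corrected across the lags examined (family-wise level
#' `alpha`). RI >= `threshold` (default 1) is then expected for white-noise
#' (arrhythmic) activity with probability at most `alpha`, while periodic
#' records score far above 1. Constant (all-zero or flat) records are
#' excluded with reason `"dead/flat"` before the statistic is computed.
#'
#' The score named by the upstream analysis convention (threshold 1) is not
#' publicly defined; this implementation is a documented interpretation with
#' the same decision rule, not a reproduction of any particular program.
#'
#' @param record An [activity_record()] spanning at least 3 days.
#' @param threshold Inclusion threshold on the index (default 1).
#' @param lag_window_h Length-2 numeric, lag window in hours.
#' @param agg_min Aggregation bin, minutes.
#' @param alpha Family-wise one-sided white-noise exceedance probability.
#' @return List: `ri`, `included`, `reason` (`NA` unless excluded).
#' @export
rhythmicity_index <- function(record, threshold = 1, lag_window_h = c(22, 26),
                              agg_min = 30, alpha = 0.01) {
  stopifnot(inherits(record, "activity_record"))
  bpd <- 86400 / record$bin_s
  if (length(record$counts) < 3 * bpd)
    mrdam_stop("rhythmicity requires >= 3 days of data", "mrdam_validation_error")
  x <- record$counts
  x[is.na(x)] <- 0L
  agg_bins <- agg_min * 60 / record$bin_s
  m <- floor(length(x) / agg_bins)
  xa <- colSums(matrix(x[seq_len(m * agg_bins)], nrow = agg_bins))
  if (stats::sd(xa) == 0)
    return(list(ri = NA_real_, included = FALSE, reason = "dead/flat"))
  lags <- seq(round(lag_window_h[1] * 60 / agg_min),
              round(lag_window_h[2] * 60 / agg_min))
  lags <- lags[lags < m - 2]
  ac <- stats::acf(xa, lag.max = max(lags), plot = FALSE)$acf[, 1, 1]
  r_peak <- max(ac[lags + 1L])
  envelope <- stats::qnorm(1 - alpha / length(lags)) / sqrt(m)
  ri <- r_peak / envelope
  list(ri = ri, included = ri >= threshold, reason = NA_character_)
}

#' Call death from a terminal run of inactivity
#'
#' A fly is called dead when its record ends with at least `flat_tail_hours`
#' of zero counts; the death time is the end of the last nonzero bin (the
#' last bout of waking activity). Mid-record inactivity followed by renewed
#' activity never triggers a call.
#'
#' @param record An [activity_record()].
#' @param flat_tail_hours Minimum terminal flat tail (default 12 h, the
#'   starvation-assay convention; use 24 for multi-day sleep assays).
#' @return Death time in hours from recording start, or `NA` if the fly is
#'   alive at the end (an all-zero record returns 0).
#' @export
detect_death <- function(record, flat_tail_hours = 12) {
  counts <- record$counts
  counts[is.na(counts)] <- 0L
  nz <- which(counts > 0)
  if (!length(nz)) return(0)
  last_nz <- max(nz)
  tail_h <- (length(counts) - last_nz) * record$bin_s / 3600
  if (tail_h >= flat_tail_hours) last_nz * record$bin_s / 3600 else NA_real_
}

#' Starvation survival table from activity records
#'
#' One row per fly: the detected death time (event = 1) or the record end
#' (event = 0, right-censored) for flies still active.
#'
#' @param records List of [activity_record()]s.
#' @param groups Optional group label per record (recycled if length 1).
#' @param flat_tail_hours Passed to [detect_death()].
#' @return `data.frame`: `subject_id`, `time` (hours), `event`, `group`.
#' @export
starvation_survival <- function(records, groups = "all", flat_tail_hours = 12) {
  groups <- rep_len(groups, length(records))
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    d <- detect_death(rec, flat_tail_hours)
    end_h <- length(rec$counts) * rec$bin_s / 3600
    data.frame(subject_id = rec$fly_id,
               time = if (is.na(d)) end_h else d,
               event = as.integer(!is.na(d)),
               group = groups[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full sleep-analysis pipeline with fixed exclusion order
#'
#' Applies the exclusion pipeline in the fixed, logged order: dead flies
#' (terminal flat tail of at least `dead_flat_tail_h`) first, then
#' arrhythmic flies (rhythmicity index below `ri_threshold`), then scores
#' sleep for the included flies.
#'
#' @param records List of [activity_record()]s.
#' @param window_days,min_sleep_min Passed to [score_sleep()].
#' @param ri_threshold Passed to [rhythmicity_index()].
#' @param dead_flat_tail_h Terminal flat tail declaring death (default 24 h
#'   for multi-day sleep assays).
#' @return List: `summaries` (rbound [score_sleep()] rows for included
#'   flies), `exclusions` (`data.frame` of `fly_id`, `reason`, in exclusion
#'   order).
#' @export
sleep_analysis <- function(records, window_days = NULL, min_sleep_min = 5,
                           ri_threshold = 1, dead_flat_tail_h = 24) {
  excl <- list()
  keep <- rep(TRUE, length(records))
  for (i in seq_along(records)) {          # stage 1: dead
    if (!is.na(detect_death(records[[i]], dead_flat_tail_h)) ||
        all(records[[i]]$counts == 0, na.rm = TRUE)) {
      keep[i] <- FALSE
      excl[[length(excl) + 1L]] <- data.frame(fly_id = records[[i]]$fly_id,
                                              reason = "dead")
    }
  }
  for (i in which(keep)) {                 # stage 2: arrhythmic
    ri <- rhythmicity_index(records[[i]], threshold = ri_threshold)
    if (!ri$included) {
      keep[i] <- FALSE
      excl[[length(excl) + 1L]] <- data.frame(
        fly_id = records[[i]]$fly_id,
        reason = if (!is.na(ri$reason)) ri$reason else "arrhythmic")
    }
  }
  summaries <- do.call(rbind, lapply(records[keep], score_sleep,
                                     window_days = window_days,
                                     min_sleep_min = min_sleep_min))
  list(summaries = summaries,
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(fly_id = character(), reason = character()))
}
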