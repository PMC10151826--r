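#' Sleep-architecture parameters for the activity simulator
#'
#' Describes the alternating wake/sleep bout process and the waking-activity
#' rates used by [simulate_activity()]. Defaults emulate a healthy adult male
#' fly under 12:12 LD at 25 degrees C: consolidated night sleep (~75% of the
#' dark phase, mean bout 30 min), a lighter daytime siesta (~25% of the light
#' phase, mean bout 10 min), and bimodal waking activity with morning and
#' evening peaks.
#'
#' Under the default `noisy = FALSE`, waking bins carry at least one count
#' (zero-truncated), so every run of zero bins is genuinely a generated sleep
#' bout and the recorded ground truth is recovered exactly by
#' [score_sleep()]. With `noisy = TRUE`, waking counts are plain Poisson and
#' may be zero, so scored sleep can exceed the ground truth slightly.
#'
#' @param wake_mean_min_day,wake_mean_min_night Mean wake-bout length (min).
#' @param sleep_mean_min_day,sleep_mean_min_night Mean sleep-bout length (min).
#' @param min_sleep_bout_min Minimum generated sleep-bout length (min); kept
#'   at the 5-min scoring convention so generated bouts are always scorable.
#' @param p_sleep_day,p_sleep_night Probability that a wake bout is followed
#'   by a sleep bout (0 disables sleep in that phase).
#' @param wake_rate_day,wake_rate_night Mean extra counts per waking 30-s bin.
#' @param bimodal_amp Amplitude of the morning/evening activity peaks
#'   (multiplier on the daytime rate).
#' @param noisy If `TRUE`, waking counts may be zero (Poisson, untruncated).
#' @return List of class `activity_profile`.
#' @export
activity_profile <- function(wake_mean_min_day = 30, wake_mean_min_night = 10,
                             sleep_mean_min_day = 10, sleep_mean_min_night = 30,
                             min_sleep_bout_min = 5,
                             p_sleep_day = 1, p_sleep_night = 1,
                             wake_rate_day = 2, wake_rate_night = 0.5,
                             bimodal_amp = 1.5, noisy = FALSE) {
  prof <- as.list(environment())
  stopifnot(all(unlist(prof[1:9]) >= 0), p_sleep_day <= 1, p_sleep_night <= 1)
  class(prof) <- "activity_profile"
  prof
}

#' Simulate DAM activity records with known ground truth
#'
#' Generates per-fly 30-s-binned beam-break counts under a 12:12 light/dark
#' cycle by alternating wake and sleep bouts (geometric bout lengths with a
#' phase-dependent mean), with bimodal waking activity and optional death
#' times. Counts are zero inside sleep bouts and after death. The generating
#' truth - per-fly sleep minutes per 24 h (total/day/night, from bout
#' construction, not from rescoring) and the observable death time (end of
#' the last nonzero bin) - is attached as attribute `"truth"`.
#'
#' @param n_flies Number of flies.
#' @param days Number of 24-h days to simulate (>= 1).
#' @param profile An [activity_profile()].
#' @param death_times Optional numeric vector (hours from recording start,
#'   `NA` for no death); counts are zeroed from the death time onward.
#' @param seed Integer seed; records are deterministic given the seed.
#' @param start `POSIXct` recording start (placed at lights-on, i.e. ZT0).
#' @return List of [activity_record()]s with attribute `"truth"` (a
#'   `data.frame`: `fly_id`, `total_sleep_min`, `day_sleep_min`,
#'   `night_sleep_min` per 24 h, `death_h`).
#' @examples
#' recs <- simulate_activity(2, days = 2, seed = 7)
#' attr(recs, "truth")
#' @export
simulate_activity <- function(n_flies, days, profile = activity_profile(),
                              death_times = NULL, seed = 1L,
                              start = as.POSIXct("2024-01-01 08:00:00",
                                                 tz = "UTC")) {
  stopifnot(n_flies >= 1, days >= 1, inherits(profile, "activity_profile"))
  if (!is.null(death_times) && length(death_times) != n_flies)
    mrdam_stop("death_times must have one entry per fly", "mrdam_validation_error")
  bin_s <- 30
  bpd <- 86400 / bin_s                   # bins per day
  bpm <- 60 / bin_s                      # bins per minute
  nbins <- as.integer(days * bpd)
  day_bins <- as.integer(12 * 3600 / bin_s)
  min_bout <- as.integer(round(profile$min_sleep_bout_min * bpm))
  zt_h <- (((seq_len(nbins) - 1L) %% bpd) * bin_s) / 3600
  is_day <- zt_h < 12
  # bimodal waking rate envelope: morning peak just after ZT0, evening peak
  # just before ZT12; flat low rate at night
  lambda <- ifelse(is_day,
                   profile$wake_rate_day *
                     (0.4 + profile$bimodal_amp *
                        (exp(-((zt_h - 0.75) / 1.25)^2) +
                         exp(-((zt_h - 11.25) / 1.25)^2))),
                   profile$wake_rate_night)

  geom_len <- function(mean_bins) {
    if (mean_bins <= 1) return(1L)
    stats::rgeom(1L, prob = 1 / mean_bins) + 1L
  }

  with_seed(seed, {
    records <- vector("list", n_flies)
    truth <- data.frame(fly_id = sprintf("fly%03d", seq_len(n_flies)),
                        total_sleep_min = 0, day_sleep_min = 0,
                        night_sleep_min = 0, death_h = NA_real_)
    for (f in seq_len(n_flies)) {
      asleep <- logical(nbins)
      pos <- 1L
      while (pos <= nbins) {
        day_now <- is_day[pos]
        wake_mean <- (if (day_now) profile$wake_mean_min_day
                      else profile$wake_mean_min_night) * bpm
        pos <- pos + geom_len(wake_mean)   # wake bout (bins stay FALSE)
        if (pos > nbins) break
        p_sleep <- if (is_day[pos]) profile$p_sleep_day else profile$p_sleep_night
        if (stats::runif(1L) >= p_sleep) next
        if (nbins - pos + 1L < min_bout) break  # tail too short: stay awake
        sleep_mean <- (if (is_day[pos]) profile$sleep_mean_min_day
                       else profile$sleep_mean_min_night) * bpm
        extra_mean <- max(sleep_mean - min_bout, 0)
        slen <- min_bout +
          (if (extra_mean > 0) stats::rgeom(1L, 1 / (extra_mean + 1)) else 0L)
        slen <- min(slen, nbins - pos + 1L)
        asleep[pos:(pos + slen - 1L)] <- TRUE
        pos <- pos + slen
      }
      counts <- integer(nbins)
      wake_idx <- which(!asleep)
      if (length(wake_idx)) {
        base <- stats::rpois(length(wake_idx), lambda[wake_idx])
        counts[wake_idx] <- if (profile$noisy) base else 1L + base
      }
      death_h <- if (is.null(death_times)) NA_real_ else death_times[f]
      if (!is.na(death_h)) {
        first_dead <- floor(death_h * 3600 / bin_s) + 1L
        if (first_dead <= nbins) {
          counts[first_dead:nbins] <- 0L
          asleep[first_dead:nbins] <- FALSE
        }
        last_nz <- if (any(counts > 0)) max(which(counts > 0)) else 0L
        truth$death_h[f] <- last_nz * bin_s / 3600
      }
      live <- if (!is.na(death_h)) seq_len(min(nbins, floor(death_h * 3600 / bin_s))) else seq_len(nbins)
      truth$total_sleep_min[f] <- sum(asleep[live]) / bpm / days
      truth$day_sleep_min[f] <- sum(asleep[live] & is_day[live]) / bpm / days
      truth$night_sleep_min[f] <- sum(asleep[live] & !is_day[live]) / bpm / days
      records[[f]] <- activity_record(truth$fly_id[f], counts, start = start,
                                      bin_s = bin_s,
                                      lights_on = format(start, "%H:%M:%S",
                                                         tz = "UTC"),
                                      channel = ((f - 1L) %% 32L) + 1L)
    }
    attr(records, "truth") <- truth
    records
  })
}
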