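#' A single fly's activity time series
#'
#' Container for one Drosophila Activity Monitor (DAM) channel: infrared
#' beam-break counts on a strictly regular 30-s grid, together with the
#' recording start time and the light schedule needed to convert clock time
#' to Zeitgeber time (ZT; hours since lights-on).
#'
#' @param fly_id Identifier for the fly.
#' @param counts Integer vector of non-negative beam-break counts per bin
#'   (`NA` marks bins from monitor rows with a non-valid status).
#' @param start `POSIXct` timestamp of the first bin.
#' @param bin_s Bin width in seconds (native DAM resolution is 30 s).
#' @param lights_on Clock time of lights-on, `"HH:MM:SS"`.
#' @param day_h Hours of light per cycle (12 under the standard 12:12 LD).
#' @param channel Monitor channel (1-32), if known.
#' @return An object of class `activity_record`.
#' @export
activity_record <- function(fly_id, counts,
                            start = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
                            bin_s = 30, lights_on = "08:00:00", day_h = 12,
                            channel = NA_integer_) {
  counts <- as.integer(counts)
  if (any(counts < 0, na.rm = TRUE))
    mrdam_stop("activity counts must be non-negative", "mrdam_validation_error")
  if (86400 %% bin_s != 0)
    mrdam_stop("bin width must divide 24 h", "mrdam_validation_error")
  if ((2 * day_h * 3600) %% 86400 != 0 && day_h != 12)
    mrdam_stop("light schedule period must divide 24 h", "mrdam_validation_error")
  structure(list(fly_id = as.character(fly_id), counts = counts,
                 start = start, bin_s = as.numeric(bin_s),
                 lights_on = lights_on, day_h = as.numeric(day_h),
                 channel = as.integer(channel)),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("<activity_record> fly %s: %d bins of %gs (%.1f days), starting %s\n",
              x$fly_id, length(x$counts), x$bin_s,
              length(x$counts) * x$bin_s / 86400, format(x$start)))
  invisible(x)
}

# seconds after midnight of a "HH:MM:SS" clock string
clock_seconds <- function(clock) {
  p <- as.numeric(strsplit(clock, ":", fixed = TRUE)[[1]])
  if (length(p) != 3L || any(is.na(p)))
    mrdam_stop("clock times must be HH:MM:SS", "mrdam_validation_error")
  p[1] * 3600 + p[2] * 60 + p[3]
}

# index of the first bin starting at lights-on (ZT0); error if the grid
# never hits lights-on exactly
zt0_index <- function(record) {
  start_sec <- as.numeric(record$start) %% 86400
  off <- (clock_seconds(record$lights_on) - start_sec) %% 86400
  if (off %% record$bin_s != 0)
    mrdam_stop("lights-on does not fall on the bin grid", "mrdam_validation_error")
  off / record$bin_s + 1L
}
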