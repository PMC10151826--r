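#' Write activity records as a TriKinetics-style monitor file
#'
#' Emits the tab-delimited DAM monitor dialect read back by
#' [read_dam_file()]: one row per 30-s reading with columns reading index,
#' date (`dd Mmm yy`), time (`HH:MM:SS`), a status code (1 = valid), and 32
#' channel counts. Channels beyond the supplied records are written as 0.
#'
#' @param records List of [activity_record()]s (at most 32) sharing the same
#'   start, bin width and length.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dam_file <- function(records, path) {
  if (inherits(records, "activity_record")) records <- list(records)
  if (length(records) < 1L || length(records) > 32L)
    mrdam_stop("a DAM monitor holds 1-32 channels", "mrdam_validation_error")
  n <- length(records[[1]]$counts)
  bin_s <- records[[1]]$bin_s
  start <- records[[1]]$start
  for (r in records)
    if (length(r$counts) != n || r$bin_s != bin_s || r$start != start)
      mrdam_stop("all records in one monitor file must share grid and start",
                 "mrdam_validation_error")
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (k in seq_along(records)) counts[, k] <- records[[k]]$counts
  stamps <- start + (seq_len(n) - 1) * bin_s
  old_lc <- Sys.getlocale("LC_TIME")
  on.exit(Sys.setlocale("LC_TIME", old_lc), add = TRUE)
  Sys.setlocale("LC_TIME", "C")
  lines <- paste(seq_len(n),
                 format(stamps, "%d %b %y", tz = "UTC"),
                 format(stamps, "%H:%M:%S", tz = "UTC"),
                 1L,
                 apply(counts, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TriKinetics-style DAM monitor file
#'
#' Parses the tab-delimited dialect written by [write_dam_file()] (reading
#' index, date, time, status, 32 channel counts). The timestamp grid must be
#' strictly regular and increasing; format problems raise errors naming the
#' offending row. Rows with a non-valid status (code other than 1) are
#' excluded: their counts become `NA` and the row numbers are logged in the
#' `"excluded_rows"` attribute of the result.
#'
#' @param path Monitor file path.
#' @param channels Which channels to return (default all 32).
#' @param lights_on Lights-on clock time annotation, `"HH:MM:SS"`.
#' @param day_h Hours of light per cycle.
#' @return List of [activity_record()]s (one per requested channel) with
#'   attribute `"excluded_rows"` (integer row numbers with bad status).
#' @export
read_dam_file <- function(path, channels = 1:32, lights_on = "08:00:00",
                          day_h = 12) {
  lines <- readLines(path)
  if (!length(lines))
    mrdam_stop("empty DAM file", "mrdam_format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 36L)
  if (length(bad))
    mrdam_stop(sprintf("DAM row %d has %d columns; expected 36 (index, date, time, status, 32 channels)",
                       bad[1], nf[bad[1]]), "mrdam_format_error")
  mat <- matrix(unlist(fields), nrow = length(lines), ncol = 36L, byrow = TRUE)
  old_lc <- Sys.getlocale("LC_TIME")
  on.exit(Sys.setlocale("LC_TIME", old_lc), add = TRUE)
  Sys.setlocale("LC_TIME", "C")
  stamps <- as.POSIXct(paste(mat[, 2], mat[, 3]),
                       format = "%d %b %y %H:%M:%S", tz = "UTC")
  if (anyNA(stamps))
    mrdam_stop(sprintf("unparseable date/time at DAM row %d",
                       which(is.na(stamps))[1]), "mrdam_format_error")
  if (nrow(mat) > 1L) {
    d <- diff(as.numeric(stamps))
    if (any(d <= 0))
      mrdam_stop(sprintf("non-monotone timestamps at DAM row %d",
                         which(d <= 0)[1] + 1L), "mrdam_format_error")
    if (any(d != d[1]))
      mrdam_stop(sprintf("irregular timestamp grid at DAM row %d",
                         which(d != d[1])[1] + 1L), "mrdam_format_error")
    bin_s <- d[1]
  } else bin_s <- 30
  status_ok <- mat[, 4] == "1"
  counts <- matrix(suppressWarnings(as.integer(mat[, 5:36])),
                   nrow = nrow(mat), ncol = 32L)
  if (anyNA(counts[status_ok, ]))
    mrdam_stop("non-integer channel counts in DAM file", "mrdam_format_error")
  counts[!status_ok, ] <- NA_integer_
  out <- lapply(channels, function(ch) {
    activity_record(sprintf("ch%02d", ch), counts[, ch], start = stamps[1],
                    bin_s = bin_s, lights_on = lights_on, day_h = day_h,
                    channel = ch)
  })
  attr(out, "excluded_rows") <- which(!status_ok)
  out
}

#' Read activity from the CSV fallback dialect
#'
#' Long-format CSV with columns `fly_id`, `timestamp`
#' (`YYYY-MM-DD HH:MM:SS`), `counts`; one record per distinct `fly_id`.
#'
#' @param path CSV path.
#' @inheritParams read_dam_file
#' @return List of [activity_record()]s.
#' @export
read_activity_csv <- function(path, lights_on = "08:00:00", day_h = 12) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "timestamp", "counts")
  if (!all(need %in% names(df)))
    mrdam_stop("activity CSV needs columns fly_id, timestamp, counts",
               "mrdam_format_error")
  lapply(split(df, df$fly_id), function(d) {
    ts <- as.POSIXct(d$timestamp, tz = "UTC")
    if (anyNA(ts)) mrdam_stop("unparseable timestamp in activity CSV",
                              "mrdam_format_error")
    o <- order(ts)
    d <- d[o, ]; ts <- ts[o]
    dd <- diff(as.numeric(ts))
    if (length(dd) && any(dd != dd[1]))
      mrdam_stop("irregular timestamp grid in activity CSV", "mrdam_format_error")
    activity_record(d$fly_id[1], d$counts, start = ts[1],
                    bin_s = if (length(dd)) dd[1] else 30,
                    lights_on = lights_on, day_h = day_h)
  })
}
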