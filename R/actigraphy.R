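# Actigraphy scoring: minute-epoch wrist counts to per-day and
# per-participant minutes of sleep, SB, LPA and MVPA.
#
# Scoring rules: awake epochs are classified by counts/min cutpoints
# (SB <= 178.50, LPA 178.51-562.49, MVPA >= 562.50); sleep within the
# nightly rest interval is scored as consecutive epochs < 20 counts/min,
# and awake epochs inside the interval (WASO) are excluded from sleep but
# kept in the day's awake budget via the intensity cutpoints, so each
# day's four parts sum exactly to its window length.

#' Intensity cutpoints for wrist counts/min
#'
#' Thresholds classifying awake minute epochs into sedentary behaviour
#' (`<= sb_max`), light activity (between the cutpoints) and MVPA
#' (`>= mvpa_min`), plus the sleep/wake threshold used inside rest
#' intervals (epochs `< sleep_wake` counts/min score as sleep).
#'
#' @param sb_max upper bound of SB, counts/min.
#' @param lpa_min,lpa_max nominal bounds of light activity.
#' @param mvpa_min lower bound of MVPA.
#' @param sleep_wake sleep/wake threshold within rest intervals.
#' @return an object of class `hac_cutpoints`.
#' @export
default_cutpoints <- function(sb_max = 178.50, lpa_min = 178.51,
                              lpa_max = 562.49, mvpa_min = 562.50,
                              sleep_wake = 20) {
  cp <- list(sb_max = sb_max, lpa_min = lpa_min, lpa_max = lpa_max,
             mvpa_min = mvpa_min, sleep_wake = sleep_wake)
  if (any(vapply(cp, function(v) !is.numeric(v) || length(v) != 1L || v <= 0, TRUE))) {
    .stopf("cutpoints must be single positive numbers")
  }
  if (!(cp$sb_max < cp$lpa_min && cp$lpa_min <= cp$lpa_max && cp$lpa_max < cp$mvpa_min)) {
    .stopf("cutpoints must satisfy sb_max < lpa_min <= lpa_max < mvpa_min")
  }
  structure(cp, class = "hac_cutpoints")
}

#' Classify awake epochs by intensity
#'
#' Total monotone partition of counts/min: SB iff `counts <= sb_max`,
#' MVPA iff `counts >= mvpa_min`, LPA otherwise.
#'
#' @param counts numeric vector of non-negative counts/min.
#' @param cutpoints an [default_cutpoints()] object.
#' @return factor with levels `SB`, `LPA`, `MVPA`.
#' @examples
#' classify_intensity(c(0, 178.50, 178.51, 562.49, 562.50))
#' @export
classify_intensity <- function(counts, cutpoints = default_cutpoints()) {
  if (!is.numeric(counts)) .stopf("counts must be numeric")
  if (any(!is.finite(counts)) || any(counts < 0)) .stopf("counts must be finite and non-negative")
  out <- ifelse(counts <= cutpoints$sb_max, "SB",
                ifelse(counts >= cutpoints$mvpa_min, "MVPA", "LPA"))
  factor(out, levels = c("SB", "LPA", "MVPA"))
}

#' Construct a minute-epoch actigraphy series
#'
#' @param timestamp `POSIXct` epoch start times, strictly increasing on a
#'   uniform grid (gaps, i.e. missing epochs, are allowed and handled
#'   downstream).
#' @param counts activity counts per minute, non-negative.
#' @param lux illuminance reading per epoch.
#' @param marker 0/1 event-marker flag (participant button press at
#'   bedtime and final wake).
#' @return data frame of class `hac_epochs`.
#' @export
epoch_series <- function(timestamp, counts, lux = 0, marker = 0L) {
  if (!inherits(timestamp, "POSIXct")) .stopf("timestamp must be POSIXct")
  n <- length(timestamp)
  if (n < 2L) .stopf("an epoch series needs at least 2 epochs")
  d <- as.numeric(diff(timestamp), units = "secs")
  if (any(d <= 0)) .stopf("timestamps must be strictly increasing")
  step <- min(d)
  if (any(abs(d / step - round(d / step)) > 1e-6)) {
    .stopf("timestamps must lie on a uniform grid (spacing a multiple of the epoch length)")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) .stopf("counts must be finite and non-negative")
  df <- data.frame(timestamp = timestamp,
                   counts = as.numeric(counts),
                   lux = rep_len(as.numeric(lux), n),
                   marker = rep_len(as.integer(marker), n))
  attr(df, "epoch_seconds") <- step
  class(df) <- c("hac_epochs", "data.frame")
  df
}

#' Read a minute-epoch CSV
#'
#' Expects columns `timestamp` (ISO-8601), `counts`, `lux`, `marker`.
#'
#' @param path file path.
#' @param tz time zone of the timestamps, default UTC.
#' @return an `hac_epochs` data frame.
#' @export
read_epoch_csv <- function(path, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "counts", "lux", "marker")
  if (!all(need %in% names(df))) {
    .stopf("epoch CSV %s must have columns: %s", path, paste(need, collapse = ", "))
  }
  ts <- as.POSIXct(df$timestamp, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(ts)) ts <- as.POSIXct(df$timestamp, tz = tz)
  epoch_series(ts, df$counts, df$lux, df$marker)
}

#' Write a minute-epoch CSV
#'
#' @param series an `hac_epochs` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S"),
    counts = series$counts, lux = series$lux, marker = series$marker)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect nightly rest intervals
#'
#' Paired event markers, when present, are authoritative: marker presses
#' are paired in time order as (bedtime, final wake), keeping pairs of
#' plausible overnight length. Without usable markers a heuristic is used:
#' maximal runs of epochs with low illuminance and low median-smoothed
#' counts, at least `min_rest_min` long, are taken as rest intervals;
#' shorter rest blocks are naps and are left to the sedentary budget.
#'
#' @param series an `hac_epochs` data frame.
#' @param cutpoints intensity cutpoints (the `sleep_wake` threshold feeds
#'   the heuristic).
#' @param lux_threshold maximum illuminance regarded as "dark".
#' @param min_rest_min minimum length (minutes) of a major rest interval.
#' @param max_rest_min maximum plausible rest length for a marker pair.
#' @param smooth_k window of the running median applied to counts before
#'   thresholding (odd integer, minutes); bridges brief awakenings.
#' @param use_markers set `FALSE` to force the heuristic.
#' @return data frame with `POSIXct` columns `start`, `end` (half-open
#'   `[start, end)`), one row per night, non-overlapping; errors if no
#'   rest interval is detectable.
#' @export
detect_rest_intervals <- function(series, cutpoints = default_cutpoints(),
                                  lux_threshold = 10, min_rest_min = 180,
                                  max_rest_min = 16 * 60, smooth_k = 15,
                                  use_markers = TRUE) {
  stopifnot(inherits(series, "hac_epochs"))
  step_min <- attr(series, "epoch_seconds") / 60
  if (use_markers && any(series$marker > 0)) {
    mt <- series$timestamp[series$marker > 0]
    if (length(mt) >= 2L) {
      k <- seq(1L, length(mt) - 1L, by = 2L)
      starts <- mt[k]; ends <- mt[k + 1L]
      len <- as.numeric(ends - starts, units = "mins")
      keep <- len >= min_rest_min & len <= max_rest_min
      if (any(keep)) {
        return(data.frame(start = starts[keep], end = ends[keep]))
      }
    }
  }
  # heuristic fallback: dark + quiet runs
  sm <- stats::runmed(series$counts, k = max(3L, smooth_k - (1 - smooth_k %% 2)))
  quiet <- series$lux < lux_threshold & sm < cutpoints$sleep_wake
  r <- rle(quiet)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  runs <- which(r$values & r$lengths * step_min >= min_rest_min)
  if (!length(runs)) {
    .stopf("no rest interval detectable (no markers and no sufficiently long dark, quiet block); participant should be excluded")
  }
  data.frame(
    start = series$timestamp[starts_idx[runs]],
    # end is exclusive: one epoch past the last quiet epoch
    end = series$timestamp[starts_idx[runs]] + r$lengths[runs] * step_min * 60
  )
}

#' Score sleep within a rest interval
#'
#' Inside `[start, end)` of the interval, epochs with counts strictly
#' below the sleep/wake threshold (20 counts/min) score as sleep; epochs
#' at or above it are wake after sleep onset (WASO) and are excluded from
#' sleep.
#'
#' @param series an `hac_epochs` data frame.
#' @param interval one-row data frame (or list) with `start` and `end`.
#' @param cutpoints intensity cutpoints.
#' @return named numeric vector `c(sleep = , wake = )` in minutes.
#' @export
score_sleep <- function(series, interval, cutpoints = default_cutpoints()) {
  stopifnot(inherits(series, "hac_epochs"))
  step_min <- attr(series, "epoch_seconds") / 60
  sel <- series$timestamp >= interval$start[1L] & series$timestamp < interval$end[1L]
  cts <- series$counts[sel]
  asleep <- cts < cutpoints$sleep_wake
  c(sleep = sum(asleep) * step_min, wake = sum(!asleep) * step_min)
}

#' Segment a recording into bedtime-to-bedtime days
#'
#' Day `n` spans `[bedtime_n, bedtime_{n+1})`: from going to bed one night
#' up to (excluding) the next night's bedtime, i.e. through the last
#' recorded awake minute of the following day. Data before the first
#' bedtime (the partial first recording day) are dropped. At least two
#' rest intervals are needed to form one complete day.
#'
#' @param series an `hac_epochs` data frame.
#' @param rest_intervals data frame from [detect_rest_intervals()].
#' @return data frame with columns `day`, `start`, `end`, `rest_start`,
#'   `rest_end` (the rest interval opening the day); zero rows when fewer
#'   than two nights are available.
#' @export
segment_days <- function(series, rest_intervals) {
  ri <- rest_intervals[order(rest_intervals$start), , drop = FALSE]
  if (nrow(ri) >= 2L && any(ri$end[-nrow(ri)] > ri$start[-1L])) {
    .stopf("rest intervals overlap")
  }
  if (nrow(ri) < 2L) {
    return(data.frame(day = integer(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      rest_start = as.POSIXct(character()),
                      rest_end = as.POSIXct(character())))
  }
  n <- nrow(ri) - 1L
  data.frame(day = seq_len(n),
             start = ri$start[seq_len(n)],
             end = ri$start[seq_len(n) + 1L],
             rest_start = ri$start[seq_len(n)],
             rest_end = ri$end[seq_len(n)])
}

#' Summarise one bedtime-to-bedtime day
#'
#' Sleep minutes come from [score_sleep()] on the rest interval opening
#' the window. All awake epochs in the window — daytime epochs, WASO
#' epochs inside the rest interval, and any nap epochs — are classified by
#' [classify_intensity()], so the four parts always sum to the number of
#' minutes covered. Epoch gaps up to `max_gap_min` are filled by carrying
#' the last classification forward; a longer gap marks the day invalid.
#'
#' @param series an `hac_epochs` data frame.
#' @param window one row of [segment_days()] output.
#' @param cutpoints intensity cutpoints.
#' @param max_gap_min largest epoch gap (minutes) repaired by
#'   last-observation carry-forward.
#' @return one-row data frame: `day`, `sleep`, `sb`, `lpa`, `mvpa`,
#'   `total_duration` (minutes), `valid`.
#' @export
summarize_day <- function(series, window, cutpoints = default_cutpoints(),
                          max_gap_min = 2) {
  stopifnot(inherits(series, "hac_epochs"))
  step_sec <- attr(series, "epoch_seconds")
  step_min <- step_sec / 60
  sel <- which(series$timestamp >= window$start[1L] & series$timestamp < window$end[1L])
  window_min <- as.numeric(window$end[1L] - window$start[1L], units = "mins")
  if (!length(sel)) {
    return(data.frame(day = window$day[1L], sleep = 0, sb = 0, lpa = 0, mvpa = 0,
                      total_duration = 0, valid = FALSE))
  }
  ts <- series$timestamp[sel]
  cts <- series$counts[sel]
  in_rest <- ts >= window$rest_start[1L] & ts < window$rest_end[1L]
  lab <- character(length(sel))
  asleep <- in_rest & cts < cutpoints$sleep_wake
  lab[asleep] <- "sleep"
  lab[!asleep] <- as.character(classify_intensity(cts[!asleep], cutpoints))
  # repair small gaps by carrying the previous epoch's class forward
  gaps <- as.numeric(diff(ts), units = "mins") - step_min
  valid <- TRUE
  extra <- setNames(numeric(4L), c("sleep", "SB", "LPA", "MVPA"))
  if (any(gaps > 1e-9)) {
    if (any(gaps > max_gap_min + 1e-9)) valid <- FALSE
    for (i in which(gaps > 1e-9 & gaps <= max_gap_min + 1e-9)) {
      cls <- if (lab[i] == "sleep") "sleep" else lab[i]
      extra[cls] <- extra[cls] + gaps[i]
    }
  }
  # epochs missing at the very edges of the window also count as gaps
  lead_gap <- as.numeric(ts[1L] - window$start[1L], units = "mins")
  tail_gap <- window_min - as.numeric(ts[length(ts)] - window$start[1L], units = "mins") - step_min
  for (g in c(lead_gap, tail_gap)) {
    if (g > max_gap_min + 1e-9) valid <- FALSE
  }
  if (lead_gap > 1e-9 && lead_gap <= max_gap_min + 1e-9) {
    extra[if (lab[1L] == "sleep") "sleep" else lab[1L]] <-
      extra[if (lab[1L] == "sleep") "sleep" else lab[1L]] + lead_gap
  }
  if (tail_gap > 1e-9 && tail_gap <= max_gap_min + 1e-9) {
    last <- lab[length(lab)]
    extra[if (last == "sleep") "sleep" else last] <-
      extra[if (last == "sleep") "sleep" else last] + tail_gap
  }
  mins <- step_min * c(sleep = sum(lab == "sleep"), SB = sum(lab == "SB"),
                       LPA = sum(lab == "LPA"), MVPA = sum(lab == "MVPA")) + extra
  data.frame(day = window$day[1L],
             sleep = unname(mins["sleep"]), sb = unname(mins["SB"]),
             lpa = unname(mins["LPA"]), mvpa = unname(mins["MVPA"]),
             total_duration = unname(sum(mins)), valid = valid)
}

#' Summarise every complete day of a recording
#'
#' Convenience wrapper: detects rest intervals (unless supplied), segments
#' the recording into bedtime-to-bedtime days and summarises each.
#'
#' @param series an `hac_epochs` data frame.
#' @param rest_intervals optional precomputed rest intervals.
#' @param cutpoints intensity cutpoints.
#' @param ... passed to [detect_rest_intervals()] and [summarize_day()].
#' @return data frame of day records (possibly zero rows).
#' @export
summarize_days <- function(series, rest_intervals = NULL,
                           cutpoints = default_cutpoints(), ...) {
  dots <- list(...)
  if (is.null(rest_intervals)) {
    det_args <- dots[names(dots) %in% names(formals(detect_rest_intervals))]
    rest_intervals <- do.call(detect_rest_intervals,
                              c(list(series = series, cutpoints = cutpoints), det_args))
  }
  windows <- segment_days(series, rest_intervals)
  if (!nrow(windows)) return(windows[, 0])
  sum_args <- dots[names(dots) %in% names(formals(summarize_day))]
  do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    do.call(summarize_day,
            c(list(series = series, window = windows[i, ], cutpoints = cutpoints),
              sum_args))
  }))
}

#' Average a participant's day records
#'
#' Applies the wear-time rule: a participant needs at least `min_days`
#' consecutive valid days (calendar-adjacent; the longest run is used).
#' Included participants get the arithmetic mean of each behaviour and of
#' the total day duration over that run.
#'
#' @param days data frame of day records from [summarize_days()].
#' @param min_days minimum consecutive valid days, default 5.
#' @return list with `included` (logical), `reason` (`NA` when included),
#'   `n_days` used, and `means` (named vector: sleep, sb, lpa, mvpa,
#'   total_duration) or `NULL` when excluded.
#' @export
average_participant <- function(days, min_days = 5) {
  if (is.null(days) || !nrow(days)) {
    return(list(included = FALSE, reason = "no complete days", n_days = 0L, means = NULL))
  }
  valid <- days$valid
  # longest run of consecutive valid days (day indices adjacent)
  best <- integer(0)
  cur <- integer(0)
  for (i in seq_len(nrow(days))) {
    if (valid[i] && (length(cur) == 0L || days$day[i] == days$day[cur[length(cur)]] + 1L)) {
      cur <- c(cur, i)
    } else {
      cur <- if (valid[i]) i else integer(0)
    }
    if (length(cur) > length(best)) best <- cur
  }
  if (length(best) < min_days) {
    return(list(included = FALSE,
                reason = sprintf("only %d consecutive valid days (< %d)", length(best), min_days),
                n_days = length(best), means = NULL))
  }
  cols <- c("sleep", "sb", "lpa", "mvpa", "total_duration")
  list(included = TRUE, reason = NA_character_, n_days = length(best),
       means = colMeans(days[best, cols]))
}
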