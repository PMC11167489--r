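test_that("intensity classification respects the cutpoint boundaries", {
  got <- classify_intensity(c(0, 178.50, 178.51, 562.49, 562.50, 5000))
  expect_equal(as.character(got), c("SB", "SB", "LPA", "LPA", "MVPA", "MVPA"))
  expect_error(classify_intensity(-1), "non-negative")
})

test_that("intensity classification is a total monotone partition of [0, Inf)", {
  counts <- sort(c(runif(500, 0, 1200), 178.50, 178.505, 178.51, 562.49, 562.495, 562.50))
  lab <- as.integer(classify_intensity(counts))
  expect_false(anyNA(lab))
  expect_true(all(diff(lab) >= 0))  # never steps down as counts increase
})

test_that("cutpoints are validated", {
  expect_error(default_cutpoints(sb_max = 600), "sb_max < lpa_min")
  expect_error(default_cutpoints(sleep_wake = -1), "positive")
})

test_that("paired event markers define the rest interval", {
  start <- utc("2026-03-02 20:00:00")
  s <- make_flat_series(start, minutes = 24 * 60, counts = 300, lux = 200,
                        marker_at = c(utc("2026-03-02 22:00:00"),
                                      utc("2026-03-03 06:00:00")))
  ri <- detect_rest_intervals(s)
  expect_equal(nrow(ri), 1L)
  expect_equal(ri$start, utc("2026-03-02 22:00:00"))
  expect_equal(ri$end, utc("2026-03-03 06:00:00"))
})

test_that("the lux/counts heuristic finds marker-free nights within 10 minutes", {
  es <- generate_epoch_series(c(sleep = 440, sb = 610, lpa = 270, mvpa = 60),
                              n_days = 3, seed = 31)
  truth <- attr(es, "truth")
  es$marker <- 0L  # strip the markers to force the heuristic
  ri <- detect_rest_intervals(es)
  expect_gte(nrow(ri), 3L)
  for (d in seq_len(3)) {
    j <- which.min(abs(as.numeric(ri$start - truth$rest_start[d], units = "mins")))
    expect_lt(abs(as.numeric(ri$start[j] - truth$rest_start[d], units = "mins")), 10)
    expect_lt(abs(as.numeric(ri$end[j] - truth$rest_end[d], units = "mins")), 10)
  }
})

test_that("a daytime-only recording has no detectable night", {
  s <- make_flat_series(utc("2026-03-02 08:00:00"), minutes = 600,
                        counts = 300, lux = 400)
  expect_error(detect_rest_intervals(s), "no rest interval")
})

test_that("sleep scoring counts only sub-threshold epochs as sleep", {
  start <- utc("2026-03-02 22:00:00")
  iv <- data.frame(start = start, end = start + 480 * 60)

  s_all <- make_flat_series(start, 480, counts = 5, lux = 0)
  expect_equal(score_sleep(s_all, iv), c(sleep = 480, wake = 0))

  s_20 <- make_flat_series(start, 480, counts = 20, lux = 0)  # exactly at threshold
  expect_equal(score_sleep(s_20, iv)[["sleep"]], 0)

  # 30 injected wake minutes inside a 480-min interval
  s <- make_flat_series(start, 480, counts = 5, lux = 0)
  s$counts[101:130] <- 50
  expect_equal(score_sleep(s, iv), c(sleep = 450, wake = 30))
})

test_that("day segmentation spans bedtime to bedtime", {
  ri <- data.frame(start = c(utc("2026-03-02 22:00:00"), utc("2026-03-03 23:00:00")),
                   end = c(utc("2026-03-03 06:00:00"), utc("2026-03-04 07:00:00")))
  w <- segment_days(NULL, ri)
  expect_equal(nrow(w), 1L)
  # bed 22:00, next bed 23:00: window holds 1500 minute epochs, the last
  # starting 24 h 59 min after bedtime
  expect_equal(as.numeric(w$end - w$start, units = "mins"), 1500)
  expect_equal(as.numeric((w$end - 60) - w$start, units = "mins"), 24 * 60 + 59)

  # identical bedtimes give exactly 1440 minutes
  ri2 <- data.frame(start = c(utc("2026-03-02 22:00:00"), utc("2026-03-03 22:00:00")),
                    end = c(utc("2026-03-03 06:00:00"), utc("2026-03-04 06:00:00")))
  expect_equal(as.numeric(segment_days(NULL, ri2)$end - segment_days(NULL, ri2)$start,
                          units = "mins"), 1440)

  # one night only: no complete day
  expect_equal(nrow(segment_days(NULL, ri[1, ])), 0L)

  # overlapping intervals are a data error
  bad <- data.frame(start = c(utc("2026-03-02 22:00:00"), utc("2026-03-03 01:00:00")),
                    end = c(utc("2026-03-03 06:00:00"), utc("2026-03-03 09:00:00")))
  expect_error(segment_days(NULL, bad), "overlap")
})

test_that("day summaries conserve the window and recover generator targets", {
  targets <- c(sleep = 450, sb = 600, lpa = 280, mvpa = 80)
  es <- generate_epoch_series(targets, n_days = 7, seed = 17)
  days <- summarize_days(es)
  expect_equal(nrow(days), 7L)
  expect_true(all(days$valid))
  # conservation: parts sum to the window length exactly
  expect_equal(days$sleep + days$sb + days$lpa + days$mvpa, days$total_duration)
  for (b in c("sleep", "sb", "lpa", "mvpa")) {
    expect_true(all(abs(days[[b]] - targets[[b]]) <= 2), label = paste(b, "within 2 min"))
  }
})

test_that("a window lying inside the rest interval scores as pure sleep", {
  start <- utc("2026-03-02 22:00:00")
  s <- make_flat_series(start, 600, counts = 5, lux = 0)
  w <- data.frame(day = 1L, start = start + 60 * 60, end = start + 180 * 60,
                  rest_start = start, rest_end = start + 600 * 60)
  rec <- summarize_day(s, w)
  expect_equal(rec$sleep, 120)
  expect_equal(rec$sb + rec$lpa + rec$mvpa, 0)
})

test_that("epoch gaps are carried forward up to the tolerance, else invalidate the day", {
  start <- utc("2026-03-02 22:00:00")
  s <- make_flat_series(start, 1440, counts = 100, lux = 200)
  w <- data.frame(day = 1L, start = start, end = start + 1440 * 60,
                  rest_start = start, rest_end = start)  # no rest: all awake
  # drop two interior minutes (2-min gap, repairable)
  s2 <- s[-c(200, 201), ]
  class(s2) <- class(s); attr(s2, "epoch_seconds") <- 60
  rec <- summarize_day(s2, w)
  expect_true(rec$valid)
  expect_equal(rec$total_duration, 1440)
  expect_equal(rec$sb, 1440)
  # a 5-min gap invalidates
  s3 <- s[-(300:304), ]
  class(s3) <- class(s); attr(s3, "epoch_seconds") <- 60
  expect_false(summarize_day(s3, w)$valid)
})

test_that("participant averaging enforces the consecutive-day wear rule", {
  day_rec <- function(day, sleep, valid = TRUE) {
    data.frame(day = day, sleep = sleep, sb = 600, lpa = 280, mvpa = 80,
               total_duration = sleep + 960, valid = valid)
  }
  four <- do.call(rbind, lapply(1:4, day_rec, sleep = 450))
  expect_false(average_participant(four)$included)

  five <- do.call(rbind, lapply(1:5, day_rec, sleep = 450))
  out <- average_participant(five)
  expect_true(out$included)
  expect_equal(out$means[["sleep"]], 450)

  # arithmetic mean across days
  six <- do.call(rbind, Map(day_rec, 1:5, c(440, 450, 460, 450, 450)))
  expect_equal(average_participant(six)$means[["sleep"]], 450)

  # an invalid day in the middle breaks the run
  broken <- do.call(rbind, lapply(1:9, day_rec, sleep = 450))
  broken$valid[5] <- FALSE
  expect_false(average_participant(broken)$included)
  expect_equal(average_participant(broken)$n_days, 4L)
  expect_true(average_participant(broken, min_days = 4)$included)
})

test_that("epoch CSV round-trips through read/write", {
  es <- generate_epoch_series(c(sleep = 400, sb = 500, lpa = 200, mvpa = 40),
                              n_days = 1, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_epoch_csv(es, f)
  back <- read_epoch_csv(f)
  expect_equal(back$counts, es$counts, tolerance = 1e-6)
  expect_equal(back$marker, es$marker)
  expect_equal(back$timestamp, es$timestamp)
  unlink(f)
})
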