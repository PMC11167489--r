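# shared fixtures built in code

# two clearly separated 3-d Gaussian clusters (for mixture sanity checks)
make_separated_clusters <- function(n_per = 40, gap = 8, seed = 421) {
  hac24:::.with_local_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 3), n_per, 3),
               matrix(rnorm(n_per * 3, mean = gap), n_per, 3))
    list(x = x, labels = rep(1:2, each = n_per))
  })
}

# hand-built epoch series: one value of counts per minute over a given span
make_flat_series <- function(start, minutes, counts, lux = 100, marker_at = NULL) {
  ts <- start + (seq_len(minutes) - 1L) * 60
  marker <- integer(minutes)
  if (!is.null(marker_at)) {
    idx <- vapply(marker_at, function(m) which.min(abs(as.numeric(ts - m))), 1L)
    marker[idx] <- 1L
  }
  epoch_series(ts, rep_len(counts, minutes), rep_len(lux, minutes), marker)
}

utc <- function(s) as.POSIXct(s, tz = "UTC")

# small reference cohort used by several tests (built once per run)
small_cohort <- local({
  cache <- NULL
  function(n = 253, seed = 11) {
    if (is.null(cache)) cache <<- generate_cohort(cohort_spec(n = n, seed = seed))
    cache
  }
})

ilr_cols <- function(cohort) as.matrix(cohort[, c("ilr1", "ilr2", "ilr3")])
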