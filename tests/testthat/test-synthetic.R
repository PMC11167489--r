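test_that("profile and cohort specifications validate their inputs", {
  expect_error(profile_spec("p", c(10, 20, 30, 45), c(1, 1, 1, 1)), "sum to ~100")
  expect_error(profile_spec("p", c(0, 50, 30, 20), c(1, 1, 1, 1)), "positive")
  expect_error(profile_spec("p", c(25, 25, 25, 25), c(-1, 1, 1, 1)), "non-negative")
  # explicit weights must sum to 1
  p1 <- profile_spec("a", c(25, 25, 25, 25), rep(1, 4), mixing_weight = 0.6)
  p2 <- profile_spec("b", c(40, 30, 20, 10), rep(1, 4), mixing_weight = 0.6)
  expect_error(cohort_spec(n = 10, profiles = list(p1, p2)), "sum to 1")
  expect_error(cohort_spec(n = -1), "count")

  # reference profiles: closed means, weights from class sizes
  spec <- cohort_spec(n = 10, seed = 1)
  expect_equal(sum(spec$weights), 1)
  expect_equal(spec$weights, c(103, 70, 54, 26) / 253)
  for (p in spec$profiles) expect_equal(sum(p$mean_composition), 100, tolerance = 1e-9)
})

test_that("an empty cohort is an empty, fully-typed table", {
  co <- generate_cohort(cohort_spec(n = 0, seed = 3))
  expect_equal(nrow(co), 0L)
  expect_true(all(c("profile", "sleep_pct", "cognition", "moca") %in% names(co)))
})

test_that("generated compositions are positive and closed", {
  co <- small_cohort()
  pct <- as.matrix(co[, c("sleep_pct", "sb_pct", "lpa_pct", "mvpa_pct")])
  expect_true(all(pct > 0))
  expect_equal(unname(rowSums(pct)), rep(100, nrow(co)), tolerance = 1e-9)
  expect_true(all(co$day_duration >= 1100 & co$day_duration <= 1550))
  expect_true(all(co$moca >= 11 & co$moca <= 25))
  expect_true(all(co$mmse >= 21 & co$mmse <= 30))
})

test_that("zero within-profile noise reproduces the profile means exactly", {
  profs <- lapply(mci_reference_profiles(), function(p) {
    profile_spec(p$label, p$mean_composition, c(0, 0, 0, 0), n = p$n)
  })
  co <- generate_cohort(cohort_spec(n = 40, profiles = profs, seed = 9))
  mu <- t(vapply(profs, function(p) ilr_transform(p$mean_composition), numeric(3)))
  for (i in seq_len(nrow(co))) {
    k <- as.integer(co$profile[i])
    expect_equal(unname(ilr_cols(co)[i, ]), unname(mu[k, ]), tolerance = 1e-9)
  }
})

test_that("the cohort is bit-identical under a fixed seed, including subsets", {
  s1 <- generate_cohort(cohort_spec(n = 25, seed = 77))
  s2 <- generate_cohort(cohort_spec(n = 25, seed = 77))
  expect_identical(s1, s2)
  # per-participant substreams: the first 10 of a larger cohort match
  s3 <- generate_cohort(cohort_spec(n = 10, seed = 77))
  expect_equal(s3, s1[1:10, ], ignore_attr = TRUE)
})

test_that("class draws follow the mixing weights", {
  counts <- table(small_cohort()$profile)
  expected <- c(103, 70, 54, 26)
  # each observed count within 4 SDs of its binomial expectation
  sds <- sqrt(expected * (1 - expected / 253))
  expect_true(all(abs(as.numeric(counts) - expected) < 4 * sds))
})

test_that("calibrated noise reproduces the percent-scale SDs approximately", {
  spec <- cohort_spec(n = 2000, seed = 303)
  co <- generate_cohort(spec)
  pct_cols <- c("sleep_pct", "sb_pct", "lpa_pct", "mvpa_pct")
  for (k in seq_along(spec$profiles)) {
    sub <- co[as.integer(co$profile) == k, pct_cols]
    achieved <- apply(sub, 2, sd)
    target <- spec$profiles[[k]]$within_sd
    # 3 ILR noise parameters against 4 percent-SD targets: the joint
    # least-squares fit cannot be exact; require rough agreement
    expect_true(all(abs(achieved / target - 1) < 0.25),
                label = sprintf("profile %d SDs within 25%% (got %s vs %s)", k,
                                paste(round(achieved, 2), collapse = "/"),
                                paste(target, collapse = "/")))
  }
})

test_that("cognition effects inject additively by profile", {
  co <- generate_cohort(cohort_spec(n = 200, seed = 55))
  expect_identical(inject_cognition_effect(co, c(0, 0, 0, 0)), co)
  up <- inject_cognition_effect(co, c(0, 0.5, 0, 0))
  k2 <- co$profile == levels(co$profile)[2]
  expect_equal(mean(up$cognition[k2]) - mean(co$cognition[k2]), 0.5)
  expect_equal(up$cognition[!k2], co$cognition[!k2])
  down <- inject_cognition_effect(co, c(0, -0.5, 0, 0))
  expect_equal(co$cognition[k2] - down$cognition[k2],
               up$cognition[k2] - co$cognition[k2])
  expect_error(inject_cognition_effect(co, c(0, 1)), "one delta per profile")
})

test_that("epoch fixtures respect their target bands", {
  es <- generate_epoch_series(c(sleep = 460, sb = 700, lpa = 250, mvpa = 0),
                              n_days = 2, seed = 13)
  expect_true(all(es$counts < 562.50))  # no MVPA epochs when the target is 0

  expect_error(generate_epoch_series(c(sleep = 0, sb = 1, lpa = 1, mvpa = 1)),
               "sleep target")
  expect_error(generate_epoch_series(c(sleep = 400, sb = 1, lpa = 1, mvpa = 1),
                                     epoch_len = 45), "divide 60")
})

test_that("a 7-day fixture passes the wear-validity rule end to end", {
  es <- generate_epoch_series(c(sleep = 430, sb = 640, lpa = 230, mvpa = 50),
                              n_days = 7, seed = 23)
  avg <- average_participant(summarize_days(es), min_days = 5)
  expect_true(avg$included)
  expect_equal(avg$n_days, 7L)
})

test_that("sub-minute epochs expand the grid without changing day totals", {
  tg <- c(sleep = 420, sb = 600, lpa = 300, mvpa = 60)
  es30 <- generate_epoch_series(tg, n_days = 2, epoch_len = 30, seed = 41)
  expect_equal(attr(es30, "epoch_seconds"), 30)
  days <- summarize_days(es30)
  expect_equal(nrow(days), 2L)
  for (b in c("sleep", "sb", "lpa", "mvpa")) {
    expect_true(all(abs(days[[b]] - tg[[b]]) <= 2))
  }
})
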