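# Synthetic cohort and epoch-series generators.
#
# The cohort generator draws participants from a finite mixture of
# logistic-normal compositions: each latent activity profile has a mean
# 24-HAC composition and a diagonal covariance in ILR space, calibrated so
# that the simulated percent-scale SDs match the profile's target SDs.
# Working in ILR space guarantees strictly positive, closed compositions.
# The epoch generator emits minute-level counts/lux/marker series whose
# day summaries recover known behaviour targets, for round-trip testing of
# the actigraphy module.

#' Specification of one latent activity profile
#'
#' @param label profile name.
#' @param mean_composition 4 positive percentages (sleep, sb, lpa, mvpa)
#'   summing to ~100; re-closed to exactly 100 internally.
#' @param within_sd 4 non-negative percent-scale SDs describing
#'   within-profile spread of each behaviour.
#' @param n nominal class size (used to derive mixing weights).
#' @param mixing_weight optional explicit weight in (0, 1]; derived from
#'   `n` at the cohort level when omitted.
#' @return an object of class `hac_profile_spec`.
#' @export
profile_spec <- function(label, mean_composition, within_sd, n = NULL,
                         mixing_weight = NULL) {
  m <- .as_part_matrix(mean_composition)[1L, ]
  if (any(m <= 0)) .stopf("profile '%s': mean composition parts must be strictly positive", label)
  if (abs(sum(m) - 100) > 1) {
    .stopf("profile '%s': mean composition should sum to ~100%%, got %.2f", label, sum(m))
  }
  m <- closure(m, kappa = 100)
  s <- rep_len(as.numeric(within_sd), 4L)
  if (any(s < 0) || any(!is.finite(s))) .stopf("profile '%s': within_sd must be non-negative", label)
  structure(list(label = label, mean_composition = m, within_sd = s,
                 n = n, mixing_weight = mixing_weight),
            class = "hac_profile_spec")
}

#' Reference latent activity profiles of older adults with MCI
#'
#' Four wrist-actigraphy activity profiles reported for community-dwelling
#' older adults with mild cognitive impairment, with their published
#' percent-of-day compositional means, SDs and class sizes (total n = 253):
#' an average-engagement profile, a low-activity/high-sedentary
#' "active chillers" profile, a highly active low-sedentary
#' "physical activity masters" profile, and a smallest, most sedentary
#' "sedentary savants" profile. These are the default generative
#' parameters of [cohort_spec()].
#'
#' @return list of four [profile_spec()] objects.
#' @export
mci_reference_profiles <- function() {
  list(
    profile_spec("Average 24-HAC",
                 c(sleep = 29.65, sb = 42.65, lpa = 21.19, mvpa = 6.51),
                 c(4.04, 3.78, 2.90, 2.83), n = 103),
    profile_spec("Active Chillers",
                 c(sleep = 30.64, sb = 48.94, lpa = 16.48, mvpa = 3.95),
                 c(3.54, 3.52, 1.66, 2.02), n = 70),
    profile_spec("Physical Activity Masters",
                 c(sleep = 29.08, sb = 31.99, lpa = 25.95, mvpa = 12.99),
                 c(3.19, 3.73, 3.37, 4.14), n = 54),
    profile_spec("Sedentary Savants",
                 c(sleep = 29.62, sb = 56.64, lpa = 11.55, mvpa = 2.19),
                 c(3.93, 2.93, 1.76, 1.45), n = 26)
  )
}

#' Default demographic distributions of the reference cohort
#'
#' Marginal distributions matching the reference MCI cohort: age 73.69
#' (5.41) years, 62.1% female, BMI 26.32 (4.58), MoCA 22.05 (2.85)
#' truncated to the eligible range 11-25, MMSE 27.73 (1.90) truncated to
#' 21-30, education categories (13.4% high school or less, 22.9% some
#' university, 9.9% trade school, 53.8% university degree) and three trial
#' cohorts of 88/89/76 participants.
#'
#' @return named list of distribution parameters.
#' @export
default_demographics <- function() {
  list(
    age_mean = 73.69, age_sd = 5.41, age_range = c(55, 95),
    female_prop = 0.621,
    bmi_mean = 26.32, bmi_sd = 4.58, bmi_range = c(15, 45),
    moca_mean = 22.05, moca_sd = 2.85, moca_range = c(11, 25),
    mmse_mean = 27.73, mmse_sd = 1.90, mmse_range = c(21, 30),
    education_probs = c(high_school_or_less = 0.134, some_university = 0.229,
                        trade_school = 0.099, university_degree = 0.538),
    education_years = c(high_school_or_less = 11, some_university = 14,
                        trade_school = 13, university_degree = 16),
    cohort_probs = c(RCT1 = 88, RCT2 = 89, RCT3 = 76) / 253
  )
}

# Calibrate diagonal ILR noise so simulated percent-scale SDs match the
# profile's target SDs. Least squares on log SD ratios with fixed
# common-random-number draws (deterministic, independent of the caller's
# RNG state). 3 free parameters cannot match 4 targets exactly; the fit is
# the best joint compromise.
.calibrate_ilr_sd <- function(mean_pct, sd_pct, sbp = default_sbp(),
                              n_mc = 4000L) {
  if (all(sd_pct == 0)) return(c(0, 0, 0))
  mu <- ilr_transform(mean_pct, sbp)
  Z <- .with_local_seed(8675309L, matrix(rnorm(3L * n_mc), ncol = 3L))
  targets <- pmax(sd_pct, 1e-6)
  achieved_sd <- function(sig) {
    X <- ilr_inverse(sweep(Z, 2L, sig, `*`) +
                       matrix(mu, n_mc, 3L, byrow = TRUE), sbp, kappa = 100)
    apply(X, 2L, sd)
  }
  obj <- function(ls) sum(log(pmax(achieved_sd(exp(ls)), 1e-9) / targets)^2)
  fit <- stats::optim(log(rep(0.2, 3L)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
  exp(fit$par)
}

#' Specification of a synthetic cohort
#'
#' Bundles the latent profile mixture, day-duration distribution,
#' cognition distribution (null between-profile effect by default),
#' demographic marginals and the master seed. ILR-space noise SDs are
#' calibrated at construction time (deterministically) from each
#' profile's percent-scale SDs.
#'
#' @param n cohort size (>= 0).
#' @param profiles list of [profile_spec()] objects; mixing weights are
#'   taken from explicit `mixing_weight`s, else derived from class sizes.
#' @param day_duration_mean,day_duration_sd minutes; bedtime-to-bedtime
#'   day totals are drawn from this normal, truncated to
#'   `day_duration_range`.
#' @param day_duration_range truncation bounds in minutes.
#' @param cognition_mean,cognition_sd global cognition score (ADAS-Cog-Plus
#'   scale; lower is better).
#' @param effect_deltas per-profile additive shift of the cognition mean;
#'   all zero by default (no true between-profile effect).
#' @param demographics list as from [default_demographics()].
#' @param seed master seed; per-participant substreams are derived from it
#'   so any subset reproduces identically.
#' @return an object of class `hac_cohort_spec`.
#' @export
cohort_spec <- function(n = 253, profiles = mci_reference_profiles(),
                        day_duration_mean = 1343.53, day_duration_sd = 44.11,
                        day_duration_range = c(1100, 1550),
                        cognition_mean = -0.31, cognition_sd = 0.62,
                        effect_deltas = NULL,
                        demographics = default_demographics(),
                        seed = 123L) {
  if (!is.numeric(n) || length(n) != 1L || n < 0) .stopf("n must be a count >= 0")
  if (!length(profiles) || !all(vapply(profiles, inherits, TRUE, "hac_profile_spec"))) {
    .stopf("profiles must be a non-empty list of profile_spec objects")
  }
  K <- length(profiles)
  w <- vapply(profiles, function(p) {
    if (!is.null(p$mixing_weight)) p$mixing_weight else as.numeric(p$n)
  }, numeric(1L))
  if (anyNA(w)) .stopf("each profile needs a class size n or an explicit mixing_weight")
  explicit <- all(vapply(profiles, function(p) !is.null(p$mixing_weight), TRUE))
  if (explicit && abs(sum(w) - 1) > 1e-8) {
    .stopf("explicit mixing weights must sum to 1 (got %.6f)", sum(w))
  }
  w <- w / sum(w)
  if (any(w <= 0)) .stopf("mixing weights must be positive")
  if (is.null(effect_deltas)) effect_deltas <- rep(0, K)
  if (length(effect_deltas) != K) .stopf("need one effect delta per profile (%d)", K)
  if (!is.numeric(cognition_sd) || cognition_sd < 0 || day_duration_sd < 0) {
    .stopf("standard deviations must be non-negative")
  }
  ilr_mean <- t(vapply(profiles, function(p) ilr_transform(p$mean_composition),
                       numeric(3L)))
  ilr_sd <- t(vapply(profiles, function(p) {
    .calibrate_ilr_sd(p$mean_composition, p$within_sd)
  }, numeric(3L)))
  structure(list(
    n = as.integer(n), profiles = profiles, weights = w,
    labels = vapply(profiles, `[[`, character(1L), "label"),
    ilr_mean = ilr_mean, ilr_sd = ilr_sd,
    day_duration_mean = day_duration_mean, day_duration_sd = day_duration_sd,
    day_duration_range = day_duration_range,
    cognition_mean = cognition_mean, cognition_sd = cognition_sd,
    effect_deltas = effect_deltas, demographics = demographics,
    seed = as.integer(seed)
  ), class = "hac_cohort_spec")
}

#' Generate a synthetic participant cohort
#'
#' Draws each participant's latent profile from the mixing weights, their
#' behaviour composition logistic-normally (diagonal Gaussian noise in ILR
#' space around the profile's ILR mean, mapped back through the inverse
#' ILR so parts are positive and closed), a bedtime-to-bedtime day
#' duration, demographics, and a cognition score
#' `Normal(cognition_mean + effect_delta[profile], cognition_sd)`.
#' Participant `i` uses a deterministic substream seeded from the master
#' seed, so any subset of participants is reproducible.
#'
#' @param spec an [cohort_spec()] object.
#' @return data frame of class `hac_cohort` with one row per participant:
#'   true profile label, behaviour percentages (`*_pct`, summing to 100),
#'   pre-closure minutes (`*_min`), `day_duration`, ILR coordinates,
#'   demographics and `cognition`. Zero rows when `spec$n == 0`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "hac_cohort_spec"))
  K <- length(spec$profiles)
  dem <- spec$demographics
  edu_levels <- names(dem$education_probs)
  rows <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    rows[[i]] <- .with_local_seed(.substream_seed(spec$seed, i), {
      k <- sample.int(K, 1L, prob = spec$weights)
      z <- spec$ilr_mean[k, ] + spec$ilr_sd[k, ] * rnorm(3L)
      pct <- ilr_inverse(z, kappa = 100)
      dur <- .rtruncnorm(1L, spec$day_duration_mean, spec$day_duration_sd,
                         spec$day_duration_range[1L], spec$day_duration_range[2L])
      edu <- sample(edu_levels, 1L, prob = dem$education_probs)
      data.frame(
        id = sprintf("P%04d", i),
        profile = spec$labels[k],
        sleep_pct = pct[["sleep"]], sb_pct = pct[["sb"]],
        lpa_pct = pct[["lpa"]], mvpa_pct = pct[["mvpa"]],
        sleep_min = pct[["sleep"]] / 100 * dur, sb_min = pct[["sb"]] / 100 * dur,
        lpa_min = pct[["lpa"]] / 100 * dur, mvpa_min = pct[["mvpa"]] / 100 * dur,
        day_duration = dur,
        ilr1 = z[1L], ilr2 = z[2L], ilr3 = z[3L],
        age = .rtruncnorm(1L, dem$age_mean, dem$age_sd, dem$age_range[1L], dem$age_range[2L]),
        sex = if (runif(1L) < dem$female_prop) "Female" else "Male",
        education = edu,
        education_years = unname(dem$education_years[edu]),
        bmi = .rtruncnorm(1L, dem$bmi_mean, dem$bmi_sd, dem$bmi_range[1L], dem$bmi_range[2L]),
        moca = round(.rtruncnorm(1L, dem$moca_mean, dem$moca_sd,
                                 dem$moca_range[1L], dem$moca_range[2L])),
        mmse = round(.rtruncnorm(1L, dem$mmse_mean, dem$mmse_sd,
                                 dem$mmse_range[1L], dem$mmse_range[2L])),
        cohort = sample(names(dem$cohort_probs), 1L, prob = dem$cohort_probs),
        cognition = rnorm(1L, spec$cognition_mean + spec$effect_deltas[k],
                          spec$cognition_sd),
        stringsAsFactors = FALSE
      )
    })
  }
  out <- if (spec$n > 0) do.call(rbind, rows) else {
    # typed empty table
    df <- generate_cohort(cohort_spec(n = 1, profiles = spec$profiles,
                                      seed = spec$seed))
    df[0L, ]
  }
  rownames(out) <- NULL
  out$profile <- factor(out$profile, levels = spec$labels)
  out$sex <- factor(out$sex, levels = c("Female", "Male"))
  out$education <- factor(out$education, levels = edu_levels)
  out$cohort <- factor(out$cohort, levels = names(dem$cohort_probs))
  attr(out, "spec") <- spec
  class(out) <- c("hac_cohort", "data.frame")
  out
}

#' Shift cognition by latent profile
#'
#' Adds `deltas[profile]` to each participant's cognition score, leaving
#' everything else unchanged. Useful for power and sanity checks against a
#' known injected effect.
#'
#' @param cohort an `hac_cohort` data frame.
#' @param deltas numeric vector, one value per profile level (optionally
#'   named by profile label).
#' @return the modified cohort.
#' @export
inject_cognition_effect <- function(cohort, deltas) {
  stopifnot(is.data.frame(cohort), "profile" %in% names(cohort))
  lev <- levels(cohort$profile)
  if (length(deltas) != length(lev)) {
    .stopf("need one delta per profile: %d profiles, %d deltas",
           length(lev), length(deltas))
  }
  if (!is.null(names(deltas))) deltas <- deltas[lev]
  cohort$cognition <- cohort$cognition + unname(deltas)[as.integer(cohort$profile)]
  cohort
}

#' Generate a synthetic minute-epoch actigraphy recording
#'
#' Builds `n_days` bedtime-to-bedtime days, each laid out as a nightly
#' rest interval (sleep epochs below the sleep/wake threshold plus a few
#' scattered WASO minutes in the sedentary counts band, low illuminance,
#' event markers at both ends) followed by an awake block of sedentary,
#' light and MVPA epochs with counts placed inside their cutpoint bands
#' and daytime illuminance. A closing night is appended so the final day
#' is complete. Day summaries computed by the actigraphy module recover
#' `day_targets` exactly by construction (WASO minutes are drawn from the
#' sedentary budget and scored back into it).
#'
#' @param day_targets named minutes per behaviour for one day:
#'   `sleep` (> 0), `sb`, `lpa`, `mvpa` (>= 0).
#' @param n_days number of complete days (>= 1).
#' @param epoch_len epoch length in seconds; must divide 60.
#' @param seed RNG seed.
#' @param start bedtime opening the first day (`POSIXct`).
#' @param waso_min target WASO minutes per night (capped at half the
#'   sedentary budget).
#' @return an `hac_epochs` data frame; attribute `truth` holds the per-day
#'   targets, bed/rise times and rest windows used to build it.
#' @export
generate_epoch_series <- function(day_targets, n_days = 7, epoch_len = 60,
                                  seed = 123L,
                                  start = as.POSIXct("2026-03-02 22:30:00", tz = "UTC"),
                                  waso_min = 20) {
  tg <- day_targets
  need <- c("sleep", "sb", "lpa", "mvpa")
  if (is.null(names(tg)) && length(tg) == 4L) names(tg) <- need
  if (!all(need %in% names(tg))) .stopf("day_targets needs named entries: %s", paste(need, collapse = ", "))
  tg <- round(as.numeric(tg[need])); names(tg) <- need
  if (tg["sleep"] <= 0 || any(tg < 0)) .stopf("sleep target must be positive and all targets non-negative")
  if (n_days < 1) .stopf("n_days must be >= 1")
  if (!is.numeric(epoch_len) || length(epoch_len) != 1L || epoch_len <= 0 ||
      60 %% epoch_len != 0) {
    .stopf("epoch_len must divide 60 seconds evenly")
  }
  per_min <- as.integer(60 / epoch_len)
  .with_local_seed(seed, {
    counts <- lux <- numeric(0)
    marker_min <- integer(0)  # minute indices (1-based) carrying a marker
    truth <- vector("list", n_days)
    minute_cursor <- 0L
    night <- function(sleep_m, waso) {
      # returns per-minute counts/lux for one rest interval
      n_rest <- sleep_m + waso
      c_night <- runif(n_rest, 0, 15)
      if (waso > 0) {
        # scattered interior WASO minutes, SB-band counts, still dark
        pos <- sort(sample(seq(10L, n_rest - 10L), waso))
        c_night[pos] <- runif(waso, 25, 170)
      }
      list(counts = c_night, lux = runif(n_rest, 0, 2))
    }
    waso_for_night <- function() {
      w <- min(waso_min, floor(tg["sb"] / 2))
      if (tg["sleep"] + w < 30) w <- 0  # night too short to intersperse WASO
      w
    }
    for (d in seq_len(n_days)) {
      waso <- waso_for_night()
      nt <- night(tg["sleep"], waso)
      day_sb <- tg["sb"] - waso
      lab <- sample(c(rep("SB", day_sb), rep("LPA", tg["lpa"]), rep("MVPA", tg["mvpa"])))
      c_day <- vapply(lab, function(l) switch(l,
        SB = runif(1L, 0, 178.5), LPA = runif(1L, 178.51, 562.49),
        MVPA = runif(1L, 562.5, 1800)), numeric(1L))
      rest_len <- tg["sleep"] + waso
      marker_min <- c(marker_min, minute_cursor + 1L, minute_cursor + rest_len + 1L)
      truth[[d]] <- data.frame(
        day = d, sleep = unname(tg["sleep"]), sb = unname(tg["sb"]),
        lpa = unname(tg["lpa"]), mvpa = unname(tg["mvpa"]),
        total = unname(sum(tg)), waso = waso,
        bed_minute = minute_cursor, rest_len = unname(rest_len))
      counts <- c(counts, nt$counts, c_day)
      lux <- c(lux, nt$lux, runif(length(c_day), 50, 500))
      minute_cursor <- minute_cursor + sum(tg)
    }
    # closing night so the final day has a terminating bedtime
    waso <- waso_for_night()
    nt <- night(tg["sleep"], waso)
    rest_len <- tg["sleep"] + waso
    marker_min <- c(marker_min, minute_cursor + 1L, minute_cursor + rest_len + 1L)
    counts <- c(counts, nt$counts, runif(5, 0, 178.5))
    lux <- c(lux, nt$lux, runif(5, 50, 500))
    n_min <- length(counts)
    marker <- integer(n_min)
    marker[marker_min] <- 1L
    # expand minutes to epochs of epoch_len seconds
    idx <- rep(seq_len(n_min), each = per_min)
    ts <- start + (seq_len(n_min * per_min) - 1L) * epoch_len
    series <- epoch_series(ts, counts[idx], lux[idx],
                           marker[idx] * rep(c(1L, integer(per_min - 1L)), n_min))
    truth <- do.call(rbind, truth)
    truth$bed_time <- start + truth$bed_minute * 60
    truth$rest_start <- truth$bed_time
    truth$rest_end <- truth$bed_time + truth$rest_len * 60
    attr(series, "truth") <- truth
    series
  })
}

#' Write a participant table to CSV
#'
#' @param cohort an `hac_cohort` (or plain) data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a participant table from CSV
#'
#' @param path CSV written by [write_cohort_csv()] (or matching its
#'   layout).
#' @return data frame with `profile`, `sex` and `education` as factors.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("profile", "sex", "education", "cohort")) {
    if (col %in% names(df)) df[[col]] <- factor(df[[col]])
  }
  df
}
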