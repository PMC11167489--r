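# End-to-end orchestration: simulate -> process -> profile -> compare,
# with CSV outputs, stage-level logging and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Nested list of every tunable of the analysis chain, suitable for
#' overriding from a YAML file ([read_config()]) or with named arguments
#' here. Thresholds: intensity cutpoints in counts/min, minimum 5
#' consecutive valid wear days, closure to 1440 min/day, latent profile
#' selection over K = 1..6 with 100 BLRT bootstrap replicates, IQR
#' winsorization on, and cognition ANCOVA adjusted for age, sex, BMI,
#' MoCA and trial cohort.
#'
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param ... named overrides of top-level entries, e.g.
#'   `simulate = list(n = 100)` (merged recursively).
#' @return configuration list of class `hac_config`.
#' @export
default_config <- function(seed = 123L, out_dir = file.path(tempdir(), "hac24"),
                           ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(enabled = TRUE, n = 253L, epochs = FALSE, n_days = 7L,
                    effect_deltas = NULL),
    input = list(participants_csv = NULL, epoch_dir = NULL),
    cutpoints = list(sb_max = 178.50, lpa_min = 178.51, lpa_max = 562.49,
                     mvpa_min = 562.50, sleep_wake = 20),
    min_days = 5L,
    kappa = 1440,
    winsorize = TRUE,
    profiles = list(K_range = 1:6, B = 100L, alpha = 0.05,
                    variance_structure = "equal-diagonal",
                    class_size_rule = "either",
                    n_restarts = 5L, boot_restarts = 3L,
                    max_iter = 500L, tol = 1e-8),
    covariates = c("age", "sex", "bmi", "moca", "cohort"),
    sensitivity_education = FALSE
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  class(cfg) <- c("hac_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of [default_config()];
#' everything else keeps its default.
#'
#' @param path YAML file.
#' @param seed optional seed override (takes precedence over the file).
#' @return configuration list of class `hac_config`.
#' @export
read_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(default_config, c(list(), y[setdiff(names(y), c("seed", "out_dir"))]))
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$out_dir)) cfg$out_dir <- y$out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- c("hac_config", "list")
  cfg
}

.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL  # hash the analytic configuration, not file locations
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the 24-HAC analysis pipeline
#'
#' Orchestrates up to four stages, each writing CSVs to `out_dir`:
#'
#' * `simulate` — generate the synthetic cohort (and, optionally,
#'   per-participant minute-epoch recordings) and write
#'   `participants.csv`.
#' * `process` — eligibility screening; then either score the epoch
#'   recordings through the actigraphy chain (rest intervals, day
#'   segmentation, wear-time rule) or take the participant table's
#'   per-day behaviour minutes as precomputed day averages; winsorize,
#'   close to `kappa`, compute ILR coordinates; write `compositions.csv`.
#' * `profile` — latent profile selection on the ILR coordinates; write
#'   `fit_statistics.csv` and `assignments.csv`.
#' * `compare` — descriptive tests by assigned profile (ANOVA /
#'   chi-square) and the cognition ANCOVA with estimated marginal means;
#'   write `comparisons.csv` and `emmeans.csv`.
#'
#' A `manifest.json` with the config hash, package version, seed and
#' stage row counts is written at the end. Given the same configuration
#' and seed the outputs are reproducible.
#'
#' @param config configuration from [default_config()] or [read_config()].
#' @param stages which stages to run (in order).
#' @param verbose emit stage-level messages with row counts.
#' @return result bundle (list) invisibly: `cohort`, `compositions`,
#'   `exclusions`, `selection`, `profile_description`, `comparisons`,
#'   `ancova`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "process", "profile", "compare"),
                         verbose = TRUE) {
  stages <- match.arg(stages, c("simulate", "process", "profile", "compare"),
                      several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cp <- do.call(default_cutpoints, config$cutpoints)
  bundle <- list(manifest = list(
    package_version = as.character(utils::packageVersion("hac24")),
    seed = config$seed, config_hash = .config_hash(config), counts = list()))

  cohort <- NULL
  if ("simulate" %in% stages && isTRUE(config$simulate$enabled)) {
    cohort <- .run_stage("simulate", {
      spec <- cohort_spec(n = config$simulate$n,
                          effect_deltas = config$simulate$effect_deltas,
                          seed = config$seed)
      co <- generate_cohort(spec)
      write_cohort_csv(co, file.path(config$out_dir, "participants.csv"))
      if (isTRUE(config$simulate$epochs)) {
        epdir <- file.path(config$out_dir, "epochs")
        dir.create(epdir, showWarnings = FALSE)
        for (i in seq_len(nrow(co))) {
          tg <- c(sleep = co$sleep_min[i], sb = co$sb_min[i],
                  lpa = co$lpa_min[i], mvpa = co$mvpa_min[i])
          es <- generate_epoch_series(tg, n_days = config$simulate$n_days,
                                      seed = .substream_seed(config$seed, 100000L + i))
          write_epoch_csv(es, file.path(epdir, paste0(co$id[i], ".csv")))
        }
      }
      co
    })
    .stage_log(verbose, "simulate: %d participants generated", nrow(cohort))
    bundle$manifest$counts$simulated <- nrow(cohort)
  }
  if (is.null(cohort) && !is.null(config$input$participants_csv)) {
    cohort <- read_cohort_csv(config$input$participants_csv)
  }

  if ("process" %in% stages) {
    if (is.null(cohort)) .stopf("stage 'process' failed: no participant table available")
    res <- .run_stage("process", {
      scr <- apply_eligibility(cohort)
      kept <- scr$included
      exclusions <- scr$exclusions
      epdir <- config$input$epoch_dir
      if (is.null(epdir) && isTRUE(config$simulate$epochs)) {
        epdir <- file.path(config$out_dir, "epochs")
      }
      if (!is.null(epdir)) {
        # full actigraphy chain on the epoch recordings
        mins <- matrix(NA_real_, nrow(kept), 5,
                       dimnames = list(NULL, c("sleep", "sb", "lpa", "mvpa", "total_duration")))
        wear_ok <- logical(nrow(kept))
        for (i in seq_len(nrow(kept))) {
          f <- file.path(epdir, paste0(kept$id[i], ".csv"))
          avg <- if (file.exists(f)) {
            series <- read_epoch_csv(f)
            days <- tryCatch(summarize_days(series, cutpoints = cp),
                             error = function(e) NULL)
            average_participant(days, min_days = config$min_days)
          } else list(included = FALSE, reason = "no epoch file")
          wear_ok[i] <- avg$included
          if (avg$included) mins[i, ] <- avg$means
          else exclusions <- rbind(exclusions,
                                   data.frame(id = as.character(kept$id[i]),
                                              reason = avg$reason))
        }
        kept <- kept[wear_ok, , drop = FALSE]
        mins <- mins[wear_ok, , drop = FALSE]
        behav <- mins[, c("sleep", "sb", "lpa", "mvpa"), drop = FALSE]
        day_dur <- mins[, "total_duration"]
      } else {
        # participant table already carries averaged per-day minutes
        behav <- as.matrix(kept[, c("sleep_min", "sb_min", "lpa_min", "mvpa_min")])
        colnames(behav) <- hac_behaviors()
        day_dur <- kept$day_duration
      }
      if (isTRUE(config$winsorize) && nrow(behav) >= 4) {
        behav <- apply(behav, 2L, winsorize)
      }
      closed <- closure(behav, kappa = config$kappa)
      ilr <- ilr_transform(closed)
      if (isTRUE(config$winsorize) && nrow(ilr) >= 4) {
        ilr <- apply(ilr, 2L, winsorize)
        colnames(ilr) <- c("ilr1", "ilr2", "ilr3")
      }
      pct <- closed / config$kappa * 100
      comp <- data.frame(id = kept$id,
                         sleep_min = closed[, "sleep"], sb_min = closed[, "sb"],
                         lpa_min = closed[, "lpa"], mvpa_min = closed[, "mvpa"],
                         sleep_pct = pct[, "sleep"], sb_pct = pct[, "sb"],
                         lpa_pct = pct[, "lpa"], mvpa_pct = pct[, "mvpa"],
                         day_duration = day_dur,
                         ilr1 = ilr[, 1L], ilr2 = ilr[, 2L], ilr3 = ilr[, 3L])
      write.csv(comp, file.path(config$out_dir, "compositions.csv"), row.names = FALSE)
      list(kept = kept, comp = comp, exclusions = exclusions)
    })
    cohort_kept <- res$kept
    compositions <- res$comp
    bundle$exclusions <- res$exclusions
    .stage_log(verbose, "process: %d included, %d excluded",
               nrow(compositions), nrow(res$exclusions))
    bundle$manifest$counts$included <- nrow(compositions)
    bundle$manifest$counts$excluded <- nrow(res$exclusions)
  }

  if ("profile" %in% stages) {
    if (!exists("compositions", inherits = FALSE)) {
      .stopf("stage 'profile' failed: run the 'process' stage first")
    }
    sel <- .run_stage("profile", {
      pr <- config$profiles
      s <- select_profiles(as.matrix(compositions[, c("ilr1", "ilr2", "ilr3")]),
                           K_range = pr$K_range, B = pr$B, alpha = pr$alpha,
                           class_size_rule = pr$class_size_rule,
                           variance_structure = pr$variance_structure,
                           n_restarts = pr$n_restarts,
                           boot_restarts = pr$boot_restarts,
                           max_iter = pr$max_iter, tol = pr$tol,
                           seed = .substream_seed(config$seed, 777L))
      write.csv(s$fit_table, file.path(config$out_dir, "fit_statistics.csv"),
                row.names = FALSE)
      write.csv(data.frame(id = compositions$id, profile = s$chosen$assignment),
                file.path(config$out_dir, "assignments.csv"), row.names = FALSE)
      s
    })
    bundle$selection <- sel
    bundle$profile_description <- describe_profiles(sel$chosen)
    .stage_log(verbose, "profile: chose K = %d (criteria met: %s)",
               sel$chosen_K, sel$criteria_met)
    bundle$manifest$counts$chosen_K <- sel$chosen_K
  }

  if ("compare" %in% stages) {
    if (!exists("cohort_kept", inherits = FALSE) || is.null(bundle$selection)) {
      .stopf("stage 'compare' failed: needs the 'process' and 'profile' stages")
    }
    cmp <- .run_stage("compare", {
      d <- cohort_kept
      d$assigned <- factor(bundle$selection$chosen$assignment)
      for (col in c("sleep_pct", "sb_pct", "lpa_pct", "mvpa_pct")) {
        d[[col]] <- compositions[[col]]
      }
      d$day_duration <- compositions$day_duration
      if (isTRUE(config$winsorize) && nrow(d) >= 4) {
        d$cognition <- as.numeric(winsorize(d$cognition))
      }
      cont <- c("age", "bmi", "moca", "mmse", "day_duration",
                "sleep_pct", "sb_pct", "lpa_pct", "mvpa_pct")
      rows <- lapply(cont, function(v) {
        a <- oneway_anova(d[[v]], d$assigned)
        data.frame(variable = v, test = "anova", statistic = a$statistic,
                   df1 = a$df[1L], df2 = a$df[2L], p = a$p)
      })
      for (v in c("sex", "education")) {
        tab <- table(d[[v]], d$assigned)
        tab <- tab[rowSums(tab) > 0, , drop = FALSE]  # unused categories
        if (nrow(tab) < 2L) next
        x2 <- chi_square(tab)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, test = "chi-square", statistic = x2$statistic,
          df1 = x2$df, df2 = NA, p = x2$p)
      }
      covs <- config$covariates
      if (isTRUE(config$sensitivity_education)) {
        covs <- c(setdiff(covs, "moca"), "education_years")
      }
      anc <- ancova_emm(d, outcome = "cognition", factor_name = "assigned",
                        covariates = covs)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = "cognition", test = "ancova", statistic = anc$statistic,
        df1 = anc$df[1L], df2 = anc$df[2L], p = anc$p)
      tab <- do.call(rbind, rows)
      write.csv(tab, file.path(config$out_dir, "comparisons.csv"), row.names = FALSE)
      write.csv(anc$emmeans, file.path(config$out_dir, "emmeans.csv"), row.names = FALSE)
      list(table = tab, ancova = anc)
    })
    bundle$comparisons <- cmp$table
    bundle$ancova <- cmp$ancova
    .stage_log(verbose, "compare: cognition ANCOVA F(%d, %d) = %.3f, p = %.3f",
               cmp$ancova$df[1L], cmp$ancova$df[2L], cmp$ancova$statistic,
               cmp$ancova$p)
  }

  if (exists("cohort", inherits = FALSE)) bundle$cohort <- cohort
  if (exists("compositions", inherits = FALSE)) bundle$compositions <- compositions
  jsonlite::write_json(bundle$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(bundle)
}
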