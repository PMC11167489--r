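# Between-profile comparisons: one-way ANOVA (raw and from printed
# summary statistics), Pearson chi-square, and ANCOVA on cognition with
# estimated marginal means. Pairwise contrasts are unadjusted by default,
# matching an exploratory analysis with no multiplicity correction.

#' One-way analysis of variance
#'
#' Classical between/within decomposition: `F = MSB / MSW` on
#' `(K-1, n-K)` degrees of freedom, computed via [stats::lm()].
#'
#' @param y numeric outcome vector.
#' @param groups group labels (coerced to factor), at least 2 groups with
#'   at least 2 observations each.
#' @return an object of class `hac_comparison` with `statistic` (F), `df`,
#'   `p`, a per-group `means` table, and the underlying model.
#' @export
oneway_anova <- function(y, groups) {
  groups <- factor(groups)
  if (length(y) != length(groups)) .stopf("y and groups differ in length")
  keep <- complete.cases(y, groups)
  y <- y[keep]; groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (nlevels(groups) < 2L) .stopf("need at least 2 groups")
  if (any(sizes < 2L)) {
    .stopf("every group needs n >= 2 (got %s)", paste(sizes, collapse = ", "))
  }
  fit <- lm(y ~ groups)
  a <- anova(fit)
  means <- data.frame(group = levels(groups),
                      n = as.integer(sizes),
                      mean = tapply(y, groups, mean),
                      sd = tapply(y, groups, sd), row.names = NULL)
  structure(list(method = "oneway-anova",
                 statistic = a$`F value`[1L],
                 df = c(a$Df[1L], a$Df[2L]),
                 p = a$`Pr(>F)`[1L],
                 means = means, model = fit),
            class = "hac_comparison")
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the F-test from per-group n, mean and SD (as printed in a
#' descriptive table): `SSB = sum n_i (m_i - grand mean)^2`,
#' `SSW = sum (n_i - 1) s_i^2`. Agrees exactly with [oneway_anova()] when
#' the summaries come from the raw data.
#'
#' @param n,mean,sd numeric vectors of per-group size, mean and SD (same
#'   length, >= 2 groups, all `n >= 2`).
#' @return an `hac_comparison` with `statistic`, `df`, `p`, `grand_mean`
#'   and the `means` table.
#' @export
anova_from_summary <- function(n, mean, sd) {
  if (length(unique(c(length(n), length(mean), length(sd)))) != 1L) {
    .stopf("n, mean, sd must have equal length")
  }
  if (length(n) < 2L) .stopf("need at least 2 groups")
  if (any(n < 2L)) .stopf("every group needs n >= 2")
  N <- sum(n); K <- length(n)
  grand <- sum(n * mean) / N
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- K - 1L; df2 <- N - K
  Fstat <- (ssb / df1) / (ssw / df2)
  structure(list(method = "anova-from-summary",
                 statistic = Fstat, df = c(df1, df2),
                 p = pf(Fstat, df1, df2, lower.tail = FALSE),
                 grand_mean = grand,
                 means = data.frame(group = seq_len(K), n = n, mean = mean, sd = sd)),
            class = "hac_comparison")
}

#' Pearson chi-square test on a contingency table
#'
#' Wraps [stats::chisq.test()] with no continuity correction, after
#' validating that all margins are positive.
#'
#' @param contingency r x c matrix of non-negative counts.
#' @return an `hac_comparison` with `statistic` (X-squared), `df`, `p`,
#'   `expected` counts and the observed table.
#' @export
chi_square <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) .stopf("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    .stopf("contingency table has a zero margin")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  structure(list(method = "chi-square",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 expected = ct$expected, observed = m),
            class = "hac_comparison")
}

#' ANCOVA with estimated marginal means
#'
#' Fits `outcome ~ factor + covariates` (no interactions: homogeneous
#' slopes assumed), tests the factor marginally (Type III, i.e. adjusted
#' for all covariates; sum-to-zero contrasts) and computes estimated
#' marginal means per factor level — model predictions at the covariate
#' means, averaging categorical covariates over their observed
#' proportions — with standard errors via \pkg{emmeans}.
#'
#' @param data data frame of complete cases.
#' @param outcome outcome column name (e.g. a global cognition score).
#' @param factor_name grouping column (e.g. the latent activity profile).
#' @param covariates character vector of covariate column names (may be
#'   empty, reducing to a one-way ANOVA).
#' @return an `hac_comparison` with `statistic` (factor F), `df`, `p`,
#'   `emmeans` table (`group`, `emmean`, `SE`, `df`), overall model F
#'   (`model_f`, `model_df`), and the fitted model.
#' @export
ancova_emm <- function(data, outcome, factor_name = "profile",
                       covariates = c("age", "sex", "bmi", "moca", "cohort")) {
  cols <- c(outcome, factor_name, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) .stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  d <- data[, cols, drop = FALSE]
  if (any(!complete.cases(d))) .stopf("ancova_emm requires complete cases")
  d[[factor_name]] <- droplevels(factor(d[[factor_name]]))
  if (nlevels(d[[factor_name]]) < 2L) .stopf("factor needs >= 2 levels")
  for (cv in covariates) if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  rhs <- paste(c(factor_name, covariates), collapse = " + ")
  fml <- as.formula(paste(outcome, "~", rhs))
  # sum-to-zero contrasts so the Type III marginal test is well defined
  fac_cols <- names(d)[vapply(d, is.factor, TRUE)]
  contr <- setNames(rep(list("contr.sum"), length(fac_cols)), fac_cols)
  fit <- lm(fml, data = d, contrasts = contr)
  X <- model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    ali <- attr(stats::alias(fit)$Complete, "dimnames")[[1]]
    .stopf("rank-deficient model; collinear term(s): %s",
           paste(unique(ali), collapse = ", "))
  }
  a3 <- car::Anova(fit, type = "III")
  ridx <- which(rownames(a3) == factor_name)
  emm <- emmeans::emmeans(fit, specs = factor_name, weights = "proportional")
  emm_df <- as.data.frame(emm)
  names(emm_df)[1L] <- "group"
  fstat <- summary(fit)$fstatistic
  structure(list(method = "ancova-emm",
                 statistic = a3$`F value`[ridx],
                 df = c(a3$Df[ridx], a3$Df[rownames(a3) == "Residuals"]),
                 p = a3$`Pr(>F)`[ridx],
                 emmeans = emm_df,
                 model_f = unname(fstat[1L]),
                 model_df = unname(fstat[2:3]),
                 emm_object = emm,
                 model = fit, factor_name = factor_name,
                 covariates = covariates),
            class = "hac_comparison")
}

#' Pairwise group contrasts
#'
#' All pairwise differences between group (or covariate-adjusted marginal)
#' means with unadjusted p-values by default; other adjustment methods can
#' be switched on but are off to match an exploratory protocol.
#'
#' @param result an `hac_comparison` from [oneway_anova()] or
#'   [ancova_emm()].
#' @param adjust multiplicity adjustment passed to \pkg{emmeans}
#'   (`"none"`, `"tukey"`, `"bonferroni"`, ...).
#' @return data frame with `contrast`, `estimate`, `SE`, `df`, `t`, `p`.
#' @export
pairwise_contrasts <- function(result, adjust = "none") {
  stopifnot(inherits(result, "hac_comparison"))
  emm <- if (result$method == "ancova-emm") {
    result$emm_object
  } else if (result$method == "oneway-anova") {
    emmeans::emmeans(result$model, specs = "groups")
  } else {
    .stopf("pairwise contrasts need a fitted oneway_anova or ancova_emm result")
  }
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  data.frame(contrast = ctr$contrast, estimate = ctr$estimate, SE = ctr$SE,
             df = ctr$df, t = ctr$t.ratio, p = ctr$p.value)
}

#' @export
print.hac_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ", "), x$p))
  if (!is.null(x$emmeans)) {
    cat("estimated marginal means:\n")
    print(x$emmeans, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
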