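# Latent profile analysis: Gaussian finite mixtures on ILR coordinates.
#
# A K-class latent profile model treats each participant's 3 ILR
# coordinates as drawn from one of K multivariate normal components with
# diagonal covariance (variances shared across classes by default, the
# simplest common LPA model; optionally free per class). Fitting is by
# expectation-maximisation with a k-means start plus random restarts.
# Model selection follows the published protocol: AIC, BIC, entropy,
# a parametric bootstrapped likelihood-ratio test of K vs K-1, and a
# minimum class-size rule.

.mixture_loglik_matrix <- function(x, means, vars, weights, x2 = x * x) {
  # n x K matrix of log(w_k) + log N(x | mu_k, diag(sigma2_k)).
  # For diagonal Gaussians the density splits into three matrix products,
  # so the whole E-step is a couple of GEMMs:
  #   log f_k(x) = -x^2 . 1/(2v_k) + x . (mu_k / v_k)
  #                - [mu_k^2 . 1/(2v_k) + 0.5 sum log(2 pi v_k)]
  K <- nrow(means)
  Vk <- if (nrow(vars) > 1L) vars else vars[rep(1L, K), , drop = FALSE]
  quad <- x2 %*% t(1 / (2 * Vk))
  lin <- x %*% t(means / Vk)
  const <- rowSums(means^2 / (2 * Vk)) + 0.5 * rowSums(log(2 * pi * Vk))
  lin - quad + rep(log(weights) - const, each = nrow(x))
}

.em_once <- function(x, K, structure, max_iter, tol, floor_vec, init) {
  n <- nrow(x); d <- ncol(x)
  x2 <- x * x
  sum_x2 <- colSums(x2)
  means <- init$means
  vars <- init$vars     # 1 x d (equal) or K x d (free)
  weights <- init$weights
  ll_trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  post <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lpm <- .mixture_loglik_matrix(x, means, vars, weights, x2)
    mx <- lpm[, 1L]
    if (K > 1L) for (k in 2L:K) mx <- pmax(mx, lpm[, k])
    lse <- mx + log(rowSums(exp(lpm - mx)))
    ll <- sum(lse)
    if (!is.finite(ll)) return(NULL)
    ll_trace[iter] <- ll
    post <- exp(lpm - lse)
    if (iter > 1L && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    nk <- colSums(post)
    if (any(nk < 1e-8)) return(NULL)  # empty class: degenerate restart
    weights <- nk / n
    S <- crossprod(post, x)           # K x d weighted sums
    means <- S / nk
    if (structure == "equal-diagonal") {
      # pooled within-class sum of squares: sum_j x^2 - sum_k S^2 / nk
      s2 <- (sum_x2 - colSums(S * S / nk)) / n
      vars <- matrix(pmax(s2, floor_vec), nrow = 1L)
    } else {
      T2 <- crossprod(post, x2)
      vars <- pmax(T2 / nk - means^2, rep(floor_vec, each = K))
    }
  }
  list(means = means, vars = vars, weights = weights, loglik = ll_trace[iter],
       loglik_trace = ll_trace[seq_len(iter)], posterior = post,
       converged = converged)
}

.random_init <- function(x, K, structure) {
  n <- nrow(x); d <- ncol(x)
  centers <- x[sample.int(n, K, replace = n < K), , drop = FALSE] +
    matrix(rnorm(K * d, sd = 0.1 * apply(x, 2L, sd)), K, d, byrow = TRUE)
  v <- matrix(apply(x, 2L, var), nrow = 1L)
  list(means = centers,
       vars = if (structure == "equal-diagonal") v else v[rep(1L, K), , drop = FALSE],
       weights = rep(1 / K, K))
}

.kmeans_init <- function(x, K, structure) {
  if (K == 1L) {
    return(list(means = matrix(colMeans(x), 1L),
                vars = matrix(apply(x, 2L, var), nrow = 1L),
                weights = 1))
  }
  km <- tryCatch(kmeans(x, centers = K, nstart = 5L, iter.max = 50L),
                 error = function(e) NULL)
  if (is.null(km)) return(.random_init(x, K, structure))
  v <- matrix(apply(x, 2L, var), nrow = 1L)
  list(means = km$centers,
       vars = if (structure == "equal-diagonal") v else v[rep(1L, K), , drop = FALSE],
       weights = pmax(tabulate(km$cluster, K), 1) / nrow(x))
}

#' Fit a K-class Gaussian latent profile model
#'
#' Expectation-maximisation for a finite mixture of diagonal-covariance
#' normals on continuous indicators (here, ILR coordinates). The first
#' start is k-means-based; `n_restarts - 1` further runs use random
#' initialisations, and the best log-likelihood is kept. Variances are
#' floored at `variance_floor` times each coordinate's total variance to
#' prevent degenerate spikes; a restart that collapses a class is
#' discarded and an error is raised only if every restart degenerates.
#'
#' @param x numeric matrix, observations in rows (no missing values);
#'   `nrow(x)` must exceed `K`.
#' @param K number of latent classes (>= 1).
#' @param variance_structure `"equal-diagonal"` (variances shared across
#'   classes, zero covariances; default) or `"free-diagonal"`.
#' @param n_restarts number of EM starts.
#' @param max_iter maximum EM iterations per start.
#' @param tol relative log-likelihood change declaring convergence.
#' @param variance_floor variance floor as a fraction of each coordinate's
#'   total variance.
#' @param seed optional seed for the restart RNG (local; the caller's RNG
#'   state is preserved).
#' @return an object of class `hac_lpa`: class means, variances, mixing
#'   weights, log-likelihood (and its nondecreasing trace), posterior
#'   class-membership matrix, modal assignments and parameter count.
#' @export
fit_mixture <- function(x, K, variance_structure = c("equal-diagonal", "free-diagonal"),
                        n_restarts = 5, max_iter = 500, tol = 1e-8,
                        variance_floor = 1e-6, seed = NULL) {
  variance_structure <- match.arg(variance_structure)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) .stopf("fit_mixture requires complete data")
  n <- nrow(x); d <- ncol(x)
  if (K < 1L) .stopf("K must be >= 1")
  if (n <= K) .stopf("need more observations (%d) than classes (%d)", n, K)
  floor_vec <- pmax(variance_floor * apply(x, 2L, var), 1e-12)
  run <- function() {
    best <- NULL
    for (r in seq_len(max(1L, n_restarts))) {
      init <- if (r == 1L) .kmeans_init(x, K, variance_structure)
              else .random_init(x, K, variance_structure)
      fit <- .em_once(x, K, variance_structure, max_iter, tol, floor_vec, init)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
    }
    best
  }
  best <- .with_local_seed(seed, run())
  if (is.null(best)) .stopf("all EM restarts degenerated; cannot fit K = %d", K)
  p <- if (variance_structure == "equal-diagonal") K * d + d + (K - 1L)
       else 2L * K * d + (K - 1L)
  assignment <- max.col(best$posterior, ties.method = "first")
  structure(list(
    K = as.integer(K), d = d, n = n,
    means = best$means, variances = best$vars, weights = best$weights,
    loglik = best$loglik, loglik_trace = best$loglik_trace,
    posterior = best$posterior, assignment = assignment,
    n_parameters = p, variance_structure = variance_structure,
    converged = best$converged
  ), class = "hac_lpa")
}

#' @export
print.hac_lpa <- function(x, ...) {
  cat(sprintf("Latent profile model: K = %d (%s), n = %d\n",
              x$K, x$variance_structure, x$n))
  cat(sprintf("  log-likelihood %.3f, %d parameters, converged: %s\n",
              x$loglik, x$n_parameters, x$converged))
  cat("  class sizes:", paste(tabulate(x$assignment, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Fit statistics of a latent profile solution
#'
#' AIC (`-2 ll + 2 p`), BIC (`-2 ll + p log n`), normalised entropy
#' `1 - sum(-p_ik log p_ik) / (n log K)` (1 for a one-class model and for
#' perfectly crisp posteriors, 0 for uniform posteriors), and the smallest
#' modal class (count and fraction).
#'
#' @param fit an `hac_lpa` object.
#' @return list with `AIC`, `BIC`, `entropy`, `min_class_n`,
#'   `min_class_frac`.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "hac_lpa"))
  n <- fit$n; K <- fit$K; p <- fit$posterior
  entropy <- if (K == 1L) 1 else {
    plogp <- p * log(pmax(p, 1e-300))
    1 - sum(-plogp) / (n * log(K))
  }
  sizes <- tabulate(fit$assignment, K)
  list(AIC = -2 * fit$loglik + 2 * fit$n_parameters,
       BIC = -2 * fit$loglik + fit$n_parameters * log(n),
       entropy = entropy,
       min_class_n = min(sizes),
       min_class_frac = min(sizes) / n)
}

# draw n observations from a fitted mixture (parametric bootstrap)
.simulate_mixture <- function(fit, n) {
  k <- sample.int(fit$K, n, replace = TRUE, prob = fit$weights)
  sds <- sqrt(if (nrow(fit$variances) > 1L) fit$variances else
              fit$variances[rep(1L, fit$K), , drop = FALSE])
  fit$means[k, , drop = FALSE] +
    matrix(rnorm(n * fit$d), n, fit$d) * sds[k, , drop = FALSE]
}

#' Bootstrapped likelihood-ratio test of K vs K-1 classes
#'
#' Parametric bootstrap: the observed statistic is
#' `2 (ll_K - ll_{K-1})`; `B` datasets are simulated from the fitted
#' (K-1)-class model and refitted under both class counts (with a reduced
#' restart budget for speed), and the p-value uses the add-one estimator
#' `(1 + #{LR_b >= LR_obs}) / (B + 1)`, so it is always in (0, 1]. A
#' bootstrap replicate whose refit fails is redrawn up to 3 times, then
#' dropped with a warning.
#'
#' @param x data matrix.
#' @param K number of classes of the larger model (>= 2).
#' @param B bootstrap replicates.
#' @param n_restarts restarts for the observed-data fits.
#' @param boot_restarts restarts inside the bootstrap.
#' @param max_iter,tol,variance_structure passed to [fit_mixture()].
#' @param seed optional local seed.
#' @param fit_k,fit_km1 optional precomputed fits of K and K-1 classes.
#' @return list with `p`, `lr_obs`, `lr_boot`, `B_effective`.
#' @export
blrt <- function(x, K, B = 100, n_restarts = 5, boot_restarts = 3,
                 max_iter = 500, tol = 1e-8,
                 variance_structure = "equal-diagonal", seed = NULL,
                 fit_k = NULL, fit_km1 = NULL) {
  if (K < 2L) .stopf("BLRT needs K >= 2")
  x <- as.matrix(x)
  .with_local_seed(seed, {
    if (is.null(fit_km1)) {
      fit_km1 <- fit_mixture(x, K - 1L, variance_structure, n_restarts, max_iter, tol)
    }
    if (is.null(fit_k)) {
      fit_k <- fit_mixture(x, K, variance_structure, n_restarts, max_iter, tol)
    }
    lr_obs <- 2 * (fit_k$loglik - fit_km1$loglik)
    lr_boot <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      for (try in 1:3) {
        xb <- .simulate_mixture(fit_km1, nrow(x))
        lr <- tryCatch({
          f0 <- fit_mixture(xb, K - 1L, variance_structure, boot_restarts, max_iter, tol)
          f1 <- fit_mixture(xb, K, variance_structure, boot_restarts, max_iter, tol)
          2 * (f1$loglik - f0$loglik)
        }, error = function(e) NA_real_)
        if (!is.na(lr)) break
      }
      lr_boot[b] <- lr
    }
    if (anyNA(lr_boot)) {
      warning(sprintf("%d of %d bootstrap replicates failed and were dropped",
                      sum(is.na(lr_boot)), B))
      lr_boot <- lr_boot[!is.na(lr_boot)]
    }
    Beff <- length(lr_boot)
    list(p = (1 + sum(lr_boot >= lr_obs)) / (Beff + 1),
         lr_obs = lr_obs, lr_boot = lr_boot, B_effective = Beff)
  })
}

#' Select the number of latent activity profiles
#'
#' Fits every class count in `K_range`, tabulates AIC, BIC, entropy,
#' BLRT p-value (K vs K-1) and smallest class, then applies the selection
#' protocol: a class count is *eligible* when its BLRT improves
#' significantly on K-1 (`p < alpha`; not applicable to the smallest K in
#' the range) and every class satisfies the class-size rule. Among
#' eligible counts the lowest BIC wins, ties going to the smaller K. If no
#' count is eligible the best-BIC solution is returned flagged
#' `criteria_met = FALSE`.
#'
#' The class-size rule defaults to the disjunctive published form — a
#' class passes with at least `min_class_n` members *or* more than
#' `min_class_frac` of the sample — under which the fraction arm is the
#' binding one at moderate n. `"n25"` enforces the absolute arm alone and
#' `"frac1"` the fraction arm alone.
#'
#' @param x data matrix (participants x ILR coordinates).
#' @param K_range contiguous class counts to consider.
#' @param B bootstrap replicates for each BLRT.
#' @param alpha BLRT significance level.
#' @param class_size_rule `"either"`, `"n25"` or `"frac1"`.
#' @param min_class_n,min_class_frac class-size thresholds.
#' @param variance_structure,n_restarts,boot_restarts,max_iter,tol passed
#'   to the fitting routines.
#' @param seed optional local seed covering all fits and bootstraps.
#' @return an object of class `hac_lpa_selection`: `fit_table` (one row
#'   per K), `chosen` (`hac_lpa`), `chosen_K`, `criteria_met`, `fits`.
#' @export
select_profiles <- function(x, K_range = 1:6, B = 100, alpha = 0.05,
                            class_size_rule = c("either", "n25", "frac1"),
                            min_class_n = 25, min_class_frac = 0.01,
                            variance_structure = "equal-diagonal",
                            n_restarts = 5, boot_restarts = 3,
                            max_iter = 500, tol = 1e-8, seed = NULL) {
  class_size_rule <- match.arg(class_size_rule)
  if (!length(K_range)) .stopf("K_range must be non-empty")
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) > 1L && any(diff(K_range) != 1L)) {
    .stopf("K_range must be contiguous (BLRT compares K with K-1)")
  }
  x <- as.matrix(x)
  n <- nrow(x)
  .with_local_seed(seed, {
    fits <- list()
    rows <- vector("list", length(K_range))
    for (j in seq_along(K_range)) {
      K <- K_range[j]
      fits[[j]] <- fit_mixture(x, K, variance_structure, n_restarts, max_iter, tol)
      fs <- fit_statistics(fits[[j]])
      p_blrt <- NA_real_
      if (j > 1L) {
        p_blrt <- blrt(x, K, B = B, n_restarts = n_restarts,
                       boot_restarts = boot_restarts, max_iter = max_iter,
                       tol = tol, variance_structure = variance_structure,
                       fit_k = fits[[j]], fit_km1 = fits[[j - 1L]])$p
      }
      size_ok <- switch(class_size_rule,
        either = fs$min_class_n >= min_class_n || fs$min_class_frac > min_class_frac,
        n25 = fs$min_class_n >= min_class_n,
        frac1 = fs$min_class_frac > min_class_frac)
      rows[[j]] <- data.frame(
        K = K, loglik = fits[[j]]$loglik, n_parameters = fits[[j]]$n_parameters,
        AIC = fs$AIC, BIC = fs$BIC, entropy = fs$entropy,
        blrt_p = p_blrt, min_class_n = fs$min_class_n,
        min_class_frac = fs$min_class_frac,
        eligible = size_ok && (j == 1L || p_blrt < alpha))
    }
    tab <- do.call(rbind, rows)
    if (any(tab$eligible)) {
      elig <- which(tab$eligible)
      pick <- elig[which.min(tab$BIC[elig])]  # which.min ties -> lower K
      met <- TRUE
    } else {
      pick <- which.min(tab$BIC)
      met <- FALSE
    }
    structure(list(fit_table = tab, chosen = fits[[pick]],
                   chosen_K = K_range[pick], criteria_met = met,
                   fits = fits, class_size_rule = class_size_rule,
                   alpha = alpha, B = B, n = n),
              class = "hac_lpa_selection")
  })
}

#' @export
print.hac_lpa_selection <- function(x, ...) {
  cat(sprintf("Latent profile selection over K = %s (n = %d)\n",
              paste(range(x$fit_table$K), collapse = ".."), x$n))
  print(x$fit_table, row.names = FALSE, digits = 4)
  cat(sprintf("Chosen K = %d%s\n", x$chosen_K,
              if (x$criteria_met) "" else "  [no model met criteria; best BIC returned]"))
  invisible(x)
}

#' Describe latent profiles as behaviour compositions
#'
#' Maps each class's ILR mean back to a percent-of-day composition and
#' labels every behaviour `above`, `below` or `average` relative to the
#' whole-sample compositional mean (the mixing-weighted centre), using a
#' tolerance in percentage points. Labels are invariant to the closure
#' constant.
#'
#' @param fit an `hac_lpa` object fitted on ILR coordinates.
#' @param kappa closure constant for reporting (100 for %/day, 1440 for
#'   min/day).
#' @param sbp sequential binary partition used for the coordinates.
#' @param tol_pct half-width (percentage points, on the 100 scale) of the
#'   "average" band.
#' @return list with `class_means` (K x 4, closed to `kappa`), `overall`
#'   (the weighted compositional centre), `labels` (K x 4 character
#'   matrix), `class_n` (modal counts) and `weights`.
#' @export
describe_profiles <- function(fit, kappa = 100, sbp = default_sbp(),
                              tol_pct = 0.5) {
  stopifnot(inherits(fit, "hac_lpa"))
  if (fit$d != 3L) .stopf("describe_profiles expects 3 ILR coordinates")
  comp <- ilr_inverse(fit$means, sbp = sbp, kappa = kappa)
  overall <- ilr_inverse(colSums(fit$weights * fit$means), sbp = sbp, kappa = kappa)
  scale <- kappa / 100
  lab <- comp
  lab[] <- "average"
  lab[comp > rep(overall, each = fit$K) + tol_pct * scale] <- "above"
  lab[comp < rep(overall, each = fit$K) - tol_pct * scale] <- "below"
  rownames(comp) <- rownames(lab) <- paste0("profile", seq_len(fit$K))
  list(class_means = comp, overall = overall, labels = lab,
       class_n = tabulate(fit$assignment, fit$K), weights = fit$weights)
}

#' Match estimated class means to reference means
#'
#' Finds the class permutation minimising the mean Euclidean distance
#' between estimated and reference mean vectors (exhaustive search;
#' label switching makes raw class indices meaningless).
#'
#' @param est_means,ref_means K x d matrices.
#' @return list with `perm` (est row order matching ref rows),
#'   `mean_error` and `max_error` (Euclidean, after matching).
#' @export
match_class_means <- function(est_means, ref_means) {
  est_means <- as.matrix(est_means); ref_means <- as.matrix(ref_means)
  K <- nrow(ref_means)
  if (nrow(est_means) != K) .stopf("mean matrices must have the same number of rows")
  perms <- .permutations(K)
  best <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    d <- sqrt(rowSums((est_means[p, , drop = FALSE] - ref_means)^2))
    if (is.null(best) || mean(d) < best$mean_error) {
      best <- list(perm = p, mean_error = mean(d), max_error = max(d))
    }
  }
  best
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 1L
  for (pos in seq_len(k)) {
    for (j in seq_len(nrow(sub))) {
      rest <- setdiff(seq_len(k), pos)[sub[j, ]]
      out[row, ] <- c(pos, rest)
      row <- row + 1L
    }
  }
  out
}
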