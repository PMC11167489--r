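test_that("a one-class model is the closed-form normal MLE", {
  set.seed(10)
  x <- matrix(rnorm(30, sd = 2), 10, 3)
  f <- fit_mixture(x, K = 1)
  expect_equal(unname(f$means[1, ]), unname(colMeans(x)))
  # MLE variance (divide by n)
  expect_equal(unname(f$variances[1, ]),
               unname(apply(x, 2, function(v) mean((v - mean(v))^2))),
               tolerance = 1e-8)
  expect_equal(f$weights, 1)
  # closed-form log-likelihood and the BIC hand formula with p = 6
  ll <- sum(vapply(1:3, function(j) {
    sum(dnorm(x[, j], mean(x[, j]), sqrt(mean((x[, j] - mean(x[, j]))^2)), log = TRUE))
  }, numeric(1)))
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  expect_equal(f$n_parameters, 6L)
  expect_equal(fit_statistics(f)$BIC, -2 * ll + 6 * log(10), tolerance = 1e-6)
})

test_that("well-separated clusters are recovered perfectly", {
  d <- make_separated_clusters()
  f <- fit_mixture(d$x, K = 2, seed = 1)
  expect_equal(adjusted_rand_index(f$assignment, d$labels), 1)
  expect_equal(sum(f$weights), 1)
  expect_equal(unname(rowSums(f$posterior)), rep(1, nrow(d$x)), tolerance = 1e-9)
})

test_that("EM log-likelihood is nondecreasing on every run", {
  co <- small_cohort()
  x <- ilr_cols(co)
  for (K in 1:5) {
    f <- fit_mixture(x, K, seed = K)
    expect_true(all(diff(f$loglik_trace) >= -1e-7 * abs(f$loglik)),
                label = sprintf("monotone trace at K=%d", K))
  }
  # free-diagonal structure too
  f <- fit_mixture(x, 3, variance_structure = "free-diagonal", seed = 2)
  expect_true(all(diff(f$loglik_trace) >= -1e-7 * abs(f$loglik)))
  expect_equal(f$n_parameters, 3 * 3 + 3 * 3 + 2)
})

test_that("the fitted model agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  x <- ilr_cols(small_cohort())
  f <- fit_mixture(x, 4, seed = 3)
  m <- mclust::Mclust(x, G = 4, modelNames = "EEI", verbose = FALSE)
  # same model family: log-likelihoods should agree to ~1e-3 and the
  # partitions should coincide
  expect_equal(f$loglik, m$loglik, tolerance = 2e-4)
  expect_equal(adjusted_rand_index(f$assignment, m$classification), 1)
  expect_equal(mclust::adjustedRandIndex(f$assignment, m$classification),
               adjusted_rand_index(f$assignment, m$classification))
})

test_that("fit statistics follow their definitions", {
  fake <- function(post, ll = -50, p = 10) {
    n <- nrow(post); K <- ncol(post)
    structure(list(K = K, d = 3L, n = n, posterior = post,
                   assignment = max.col(post, ties.method = "first"),
                   loglik = ll, n_parameters = p), class = "hac_lpa")
  }
  onehot <- fake(cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(fit_statistics(onehot)$entropy, 1)
  uniform <- fake(matrix(0.5, 4, 2))
  expect_equal(fit_statistics(uniform)$entropy, 0)
  fs <- fit_statistics(onehot)
  expect_equal(fs$AIC, -2 * -50 + 2 * 10)
  expect_equal(fs$min_class_n, 2L)
  expect_equal(fs$min_class_frac, 0.5)
})

test_that("the bootstrapped LRT behaves at the extremes", {
  d <- make_separated_clusters(n_per = 30)
  b <- blrt(d$x, 2, B = 19, seed = 4, boot_restarts = 2)
  expect_equal(b$p, 1 / 20)  # separation forces the observed LR extreme
  expect_gt(b$p, 0); expect_lte(b$p, 1)
  expect_error(blrt(d$x, 1), "K >= 2")
})

test_that("single-cluster data select one profile", {
  set.seed(6)
  x <- matrix(rnorm(150 * 3), 150, 3)
  sel <- select_profiles(x, K_range = 1:3, B = 19, seed = 6)
  expect_equal(sel$chosen_K, 1L)
  expect_equal(nrow(sel$fit_table), 3L)
  expect_true(sel$criteria_met)
  expect_true(is.na(sel$fit_table$blrt_p[1]))
  expect_true(all(sel$fit_table$entropy >= 0 & sel$fit_table$entropy <= 1))
})

test_that("two separated clusters select two profiles", {
  d <- make_separated_clusters(n_per = 50)
  # B = 39 so the smallest attainable BLRT p (1/40) clears alpha = 0.05
  sel <- select_profiles(d$x, K_range = 1:3, B = 39, seed = 8)
  expect_equal(sel$chosen_K, 2L)
  expect_equal(adjusted_rand_index(sel$chosen$assignment, d$labels), 1)
})

test_that("the strict class-size arm can veto an otherwise eligible model", {
  # 2 clusters, one tiny: eligible under the disjunctive rule but not n25
  hac24:::.with_local_seed(12, {
    x <- rbind(matrix(rnorm(90 * 3), 90, 3),
               matrix(rnorm(10 * 3, mean = 9), 10, 3))
  })
  sel_either <- select_profiles(x, K_range = 1:2, B = 39, seed = 5,
                                class_size_rule = "either")
  sel_strict <- select_profiles(x, K_range = 1:2, B = 39, seed = 5,
                                class_size_rule = "n25")
  expect_equal(sel_either$chosen_K, 2L)
  expect_equal(sel_strict$chosen_K, 1L)
})

test_that("profiles are described as compositions against the overall centre", {
  co <- small_cohort()
  f <- fit_mixture(ilr_cols(co), 4, seed = 9)
  de <- describe_profiles(f)
  expect_equal(unname(rowSums(de$class_means)), rep(100, 4), tolerance = 1e-9)
  expect_equal(sum(de$class_n), nrow(co))
  # labels are invariant to the closure constant
  de_min <- describe_profiles(f, kappa = 1440)
  expect_identical(de$labels, de_min$labels)
  # a one-class model sits at the centre: all labels "average"
  f1 <- fit_mixture(ilr_cols(co), 1)
  expect_true(all(describe_profiles(f1)$labels == "average"))
})

test_that("class matching is permutation invariant", {
  mu <- matrix(c(0, 0, 0, 5, 5, 5, -5, 2, 1), 3, byrow = TRUE)
  shuffled <- mu[c(3, 1, 2), ]
  m <- match_class_means(shuffled, mu)
  expect_equal(m$mean_error, 0)
  expect_equal(shuffled[m$perm, ], mu)
})
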