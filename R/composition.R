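# Compositional data analysis for the four-part 24-HAC time budget.
#
# A day's time use (sleep, SB, LPA, MVPA) is a composition: only the
# relative sizes of the parts are informative, and the parts are closed to
# a constant total (1440 min, or 100%). Standard statistics are applied in
# isometric log-ratio (ILR) coordinates, an orthonormal log-ratio basis
# built from a sequential binary partition of the parts.

#' Behaviour part names of the 24-hour activity cycle
#'
#' Canonical order of the four behaviour parts used throughout the package:
#' sleep, sedentary behaviour (`sb`), light physical activity (`lpa`), and
#' moderate-to-vigorous physical activity (`mvpa`).
#'
#' @return character vector of length 4.
#' @export
hac_behaviors <- function() c("sleep", "sb", "lpa", "mvpa")

.as_part_matrix <- function(x) {
  parts <- hac_behaviors()
  if (is.data.frame(x)) x <- as.matrix(x[, intersect(colnames(x), parts), drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  if (ncol(x) != 4L) .stopf("expected 4 behaviour parts, got %d columns", ncol(x))
  if (!is.null(colnames(x)) && all(parts %in% colnames(x))) {
    x <- x[, parts, drop = FALSE]
  } else {
    colnames(x) <- parts
  }
  storage.mode(x) <- "double"
  x
}

#' Close a behaviour vector to a constant sum
#'
#' Multiplies each part by `kappa / sum(parts)` so the output sums exactly
#' to the closure constant `kappa` (1440 min for a day, or 100 for
#' percentages). Closure discards the absolute total — which varies from
#' day to day because a bedtime-to-bedtime "day" is not exactly 24 h — and
#' keeps only the relative information the compositional analysis uses.
#'
#' @param x numeric vector of 4 positive parts (ordered as
#'   [hac_behaviors()], or named), or a matrix/data frame with one
#'   composition per row.
#' @param kappa closure constant; default 1440 (minutes in a day).
#' @return numeric vector or matrix of the same shape, rows summing to
#'   `kappa`.
#' @examples
#' closure(c(sleep = 420, sb = 600, lpa = 240, mvpa = 60))
#' @export
closure <- function(x, kappa = 1440) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    .stopf("kappa must be a single positive number")
  }
  vec <- is.null(dim(x)) && !is.data.frame(x)
  m <- .as_part_matrix(x)
  if (any(!is.finite(m)) || any(m <= 0)) {
    .stopf("all behaviour parts must be finite and strictly positive; zero parts are not supported")
  }
  out <- m * (kappa / rowSums(m))
  if (vec) out[1L, ] else out
}

#' Default sequential binary partition for the 24-HAC
#'
#' The 3 x 4 sign-code matrix defining the ILR balances used for the
#' activity-profile analysis: first MVPA against the geometric mean of SB,
#' LPA and sleep; then SB against LPA and sleep; finally LPA against sleep.
#' Each row contrasts the `+1` parts with the `-1` parts; a part already
#' partitioned out is coded 0.
#'
#' @return integer matrix with rows `ilr1..ilr3` and columns
#'   [hac_behaviors()].
#' @seealso [sbp_basis()], [ilr_transform()]
#' @export
default_sbp <- function() {
  sbp <- rbind(
    ilr1 = c(sleep = -1L, sb = -1L, lpa = -1L, mvpa = 1L),
    ilr2 = c(sleep = -1L, sb = 1L, lpa = -1L, mvpa = 0L),
    ilr3 = c(sleep = -1L, sb = 0L, lpa = 1L, mvpa = 0L)
  )
  sbp
}

.validate_sbp <- function(sbp) {
  if (!is.matrix(sbp) || nrow(sbp) != 3L || ncol(sbp) != 4L) {
    .stopf("sbp must be a 3 x 4 matrix over {-1, 0, +1}")
  }
  if (!all(sbp %in% c(-1L, 0L, 1L))) .stopf("sbp codes must be -1, 0 or +1")
  if (any(rowSums(sbp == 1L) < 1L) || any(rowSums(sbp == -1L) < 1L)) {
    .stopf("every sbp row needs at least one +1 and one -1 code")
  }
  invisible(sbp)
}

#' Orthonormal balance basis of a sequential binary partition
#'
#' Converts a sign-code matrix into the 4 x 3 contrast matrix `V` such
#' that `ilr = t(V) %*% log(x)`. A row contrasting `a` parts (+1) against
#' `b` parts (-1) gets coefficients `+sqrt(b / (a (a + b)))` and
#' `-sqrt(a / (b (a + b)))`, which yields the normalising constants
#' sqrt(3/4), sqrt(2/3) and sqrt(1/2) for the default partition.
#'
#' @param sbp sign-code matrix as returned by [default_sbp()].
#' @return 4 x 3 numeric matrix with orthonormal columns.
#' @export
sbp_basis <- function(sbp = default_sbp()) {
  .validate_sbp(sbp)
  V <- matrix(0, nrow = 4L, ncol = 3L,
              dimnames = list(colnames(sbp), rownames(sbp)))
  for (r in seq_len(3L)) {
    plus <- sbp[r, ] == 1L
    minus <- sbp[r, ] == -1L
    a <- sum(plus); b <- sum(minus)
    V[plus, r] <- sqrt(b / (a * (a + b)))
    V[minus, r] <- -sqrt(a / (b * (a + b)))
  }
  V
}

#' Isometric log-ratio transform of behaviour compositions
#'
#' Maps a 4-part composition to 3 real balance coordinates. With the
#' default partition: `ilr1 = sqrt(3/4) * ln(MVPA / (SB*LPA*sleep)^(1/3))`,
#' `ilr2 = sqrt(2/3) * ln(SB / (LPA*sleep)^(1/2))`,
#' `ilr3 = sqrt(1/2) * ln(LPA / sleep)`. The transform is scale invariant,
#' so closing to minutes or percent gives identical coordinates.
#'
#' @param x composition vector, or matrix/data frame of compositions (one
#'   per row); all parts strictly positive.
#' @param sbp sequential binary partition code matrix.
#' @return numeric vector of length 3, or an `n x 3` matrix, with columns
#'   `ilr1`, `ilr2`, `ilr3`.
#' @examples
#' ilr_transform(c(sleep = 29.80, sb = 43.55, lpa = 19.91, mvpa = 6.74))
#' @export
ilr_transform <- function(x, sbp = default_sbp()) {
  vec <- is.null(dim(x)) && !is.data.frame(x)
  m <- .as_part_matrix(x)
  if (any(!is.finite(m)) || any(m <= 0)) {
    .stopf("ilr_transform requires strictly positive parts")
  }
  V <- sbp_basis(sbp)
  z <- log(m) %*% V
  if (vec) z[1L, ] else z
}

#' Inverse isometric log-ratio transform
#'
#' Recovers the unique composition with the given balance coordinates,
#' closed to `kappa`. `ilr_inverse(ilr_transform(x), kappa = sum(x))`
#' returns `x` for any valid composition.
#'
#' @param z numeric vector of 3 coordinates or an `n x 3` matrix.
#' @param sbp sequential binary partition code matrix.
#' @param kappa closure constant of the output composition.
#' @return composition vector or matrix with columns [hac_behaviors()].
#' @export
ilr_inverse <- function(z, sbp = default_sbp(), kappa = 1440) {
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, nrow = 1L)
  if (ncol(z) != 3L) .stopf("expected 3 ilr coordinates, got %d", ncol(z))
  if (any(!is.finite(z))) .stopf("ilr coordinates must be finite")
  V <- sbp_basis(sbp)
  x <- exp(z %*% t(V))
  colnames(x) <- hac_behaviors()
  out <- closure(x, kappa = kappa)
  if (vec) out[1L, ] else out
}

#' Compositional (geometric) mean of behaviour compositions
#'
#' The centre of a compositional sample: the part-wise geometric mean,
#' re-closed to `kappa`. Equivalent to mapping the arithmetic mean of the
#' ILR coordinates back through [ilr_inverse()].
#'
#' @param x matrix or data frame of compositions, one per row.
#' @param kappa closure constant of the result.
#' @return named numeric vector of 4 parts summing to `kappa`.
#' @export
compositional_mean <- function(x, kappa = 1440) {
  m <- .as_part_matrix(x)
  if (nrow(m) < 1L) .stopf("need at least one composition")
  if (any(!is.finite(m)) || any(m <= 0)) {
    .stopf("compositional_mean requires strictly positive parts")
  }
  g <- exp(colMeans(log(m)))
  closure(g, kappa = kappa)
}

#' Winsorize a variable at Tukey IQR fences
#'
#' Screens one variable across participants: values below
#' `Q1 - 1.5 * IQR` are replaced by the 5th percentile of the input and
#' values above `Q3 + 1.5 * IQR` by the 95th percentile. Fences and
#' replacement percentiles are computed once from the original input
#' (single pass), with linear-interpolation quantiles (type 7) by default.
#'
#' @param x numeric vector, length at least 4.
#' @param probs replacement percentiles, default `c(0.05, 0.95)`.
#' @param fence_mult IQR multiplier for the fences, default 1.5.
#' @param type quantile type passed to [stats::quantile()].
#' @return numeric vector of the same length; the number of replaced
#'   values is attached as attribute `n_modified`.
#' @export
winsorize <- function(x, probs = c(0.05, 0.95), fence_mult = 1.5, type = 7) {
  if (!is.numeric(x) || length(x) < 4L) .stopf("winsorize needs a numeric vector of length >= 4")
  if (any(!is.finite(x))) .stopf("winsorize requires finite values")
  q <- quantile(x, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2L] - q[1L]
  lower <- q[1L] - fence_mult * iqr
  upper <- q[2L] + fence_mult * iqr
  repl <- quantile(x, probs, type = type, names = FALSE)
  out <- x
  out[x < lower] <- repl[1L]
  out[x > upper] <- repl[2L]
  structure(out, n_modified = sum(x < lower | x > upper))
}
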