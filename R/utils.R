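# internal helpers shared across modules

# log(sum(exp(x))) along rows of a matrix, guarding against underflow
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# deterministic per-unit substream seed derived from a master seed; keeps
# values inside the 32-bit integer range R requires
.substream_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 + i * 48271) %% 2147483647)
}

# run `expr` under a local RNG state: seeds with `seed` if non-NULL and
# restores the caller's .Random.seed afterwards
.with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# truncated normal draw by rejection; bounds are loose in all uses so
# rejection is cheap
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant agreement between two labelings of the same
#' observations; 1 means identical partitions (up to relabeling), 0 is the
#' expected value under independent random partitions. Used for parameter
#' recovery checks against known simulation labels.
#'
#' @param a,b vectors of class labels of equal length.
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) .stopf("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
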