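# Cohort reliability and correlation statistics: absolute-agreement
# average-measures intraclass correlation from the two-way ANOVA mean
# squares, Spearman rank correlation with an exact permutation p-value,
# test-retest coefficient of variation, and printed-table style summaries.

#' Intraclass correlation, two-way absolute agreement, average measures
#'
#' ICC(A,k) in the McGraw & Wong convention: with rows as targets and
#' columns as raters, the two-way mean squares for rows (MSR), columns
#' (MSC) and error (MSE) give
#' `ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#' where `n` is the number of targets. This is the appropriate coefficient
#' for inter-observer agreement of averaged measurements when rater means
#' are not interchangeable.
#'
#' @param ratings Numeric matrix (or data frame) with >= 2 rows (targets)
#'   and >= 2 columns (raters), no missing cells.
#' @return ICC(A,k), a scalar in `[-1, 1]` up to sampling noise.
#' @export
#' @examples
#' m <- cbind(r1 = c(9, 10, 11, 14), r2 = c(9.5, 10.5, 10.8, 13.6))
#' icc_absolute_average(m)
icc_absolute_average <- function(ratings) {
  m <- as.matrix(ratings)
  if (!is.numeric(m) || nrow(m) < 2 || ncol(m) < 2 || any(!is.finite(m))) {
    abort("`ratings` must be a complete numeric matrix with >= 2 rows and >= 2 columns.")
  }
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  sst <- sum((m - gm)^2)
  if (sst < 1e-24) {
    abort("all ratings are identical: total variance is zero, ICC undefined.",
          class = "cervseq_zero_variance")
  }
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# all permutations of 1:n, one per row, by iterative insertion
permutations_all <- function(n) {
  p <- matrix(1L, 1, 1)
  for (m in 2:n) {
    old <- p
    p <- matrix(0L, nrow(old) * m, m)
    r <- 0L
    for (i in seq_len(nrow(old))) {
      for (pos in seq_len(m)) {
        r <- r + 1L
        p[r, ] <- append(old[i, ], m, after = pos - 1L)
      }
    }
  }
  p
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' the permutation probability of `|rho|` at least as extreme as observed:
#' computed by full enumeration of all `n!` permutations for `n <= 8`, and
#' by Monte-Carlo permutation (`n_mc` draws, seeded, add-one estimator) for
#' `8 < n <= 30`. Larger samples are out of scope for this study's cohort
#' sizes.
#'
#' @param x,y Numeric vectors of equal length >= 3. Constant vectors have no
#'   defined rank correlation and raise an error.
#' @param n_mc Number of Monte-Carlo permutations when enumeration is not
#'   used (>= 99999).
#' @param seed Seed for the Monte-Carlo branch.
#' @return Tibble `(rho, p_value, n, method)`.
#' @export
#' @examples
#' spearman_exact(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
spearman_exact <- function(x, y, n_mc = 99999L, seed = 1L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  if (n > 30) abort("n > 30 is out of scope for the exact permutation test.")
  if (n_mc < 99999) abort("`n_mc` must be at least 99999.")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    abort("rank correlation undefined for a constant vector.",
          class = "cervseq_constant_vector")
  }
  rho_of <- function(ryp) {
    sum((rx - mean(rx)) * (ryp - mean(ryp))) /
      ((n - 1) * sd(rx) * sd(ryp))
  }
  rho <- rho_of(ry)
  eps <- 1e-12
  if (n <= 8) {
    perms <- permutations_all(n)
    # rho for permuted y-ranks differs only through sum(rx * ry_perm)
    sums <- as.numeric(matrix(ry[perms], nrow = nrow(perms)) %*% rx)
    mean_term <- n * mean(rx) * mean(ry)
    denom <- (n - 1) * sd(rx) * sd(ry)
    rhos <- (sums - mean_term) / denom
    p <- mean(abs(rhos) >= abs(rho) - eps)
    method <- "exact enumeration"
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_mc)) {
      if (abs(rho_of(ry[sample.int(n)])) >= abs(rho) - eps) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_mc + 1)
    method <- sprintf("Monte-Carlo permutation (%d draws)", n_mc)
  }
  tibble(rho = rho, p_value = p, n = n, method = method)
}

#' Test-retest coefficient of variation and intra-individual SD
#'
#' For each individual's pair of repeated measurements (sessions T1 and T2),
#' the intra-individual standard deviation (of the two values, denominator
#' `n - 1 = 1`, i.e. `|T1 - T2| / sqrt(2)`) and the coefficient of variation
#' `SD / mean`.
#'
#' @param t1,t2 Paired numeric vectors.
#' @return Tibble `(t1, t2, mean, sd, cv)`.
#' @export
#' @examples
#' cv_and_intraindividual_sd(c(20, 12), c(10, 12))
cv_and_intraindividual_sd <- function(t1, t2) {
  if (length(t1) != length(t2)) abort("`t1` and `t2` must be paired.")
  if (any(!is.finite(t1)) || any(!is.finite(t2))) {
    abort("values must be finite.")
  }
  m <- (t1 + t2) / 2
  s <- abs(t1 - t2) / sqrt(2)
  if (any(m == 0)) {
    abort("coefficient of variation undefined: a pair has mean zero.",
          class = "cervseq_zero_mean")
  }
  tibble(t1 = t1, t2 = t2, mean = m, sd = s, cv = s / m)
}

# half-away-from-zero decimal rounding (printed-table convention); a small
# relative epsilon guards binary representation of exact halves
round_half_away <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Summarise a column the way the cohort tables print it
#'
#' Full-precision mean, minimum, maximum and count, together with the
#' rounded mean (half-away-from-zero to `digits`) and the table-style
#' `"mean [min;max]"` string. Rounding is applied only to the printed
#' representations, never to the stored values.
#'
#' @param values Numeric vector with >= 1 finite value.
#' @param digits Decimal places for the printed mean.
#' @return One-row tibble `(mean, mean_printed, min, max, n, formatted)`.
#' @export
#' @examples
#' summarize_column(c(58, 55, 67, 67, 64, 63, 60, 57, 59, 61), digits = 0)
summarize_column <- function(values, digits = 1) {
  if (length(values) == 0 || any(!is.finite(values))) {
    abort("`values` must be a non-empty finite numeric vector.")
  }
  mp <- round_half_away(mean(values), digits)
  lo <- round_half_away(min(values), digits)
  hi <- round_half_away(max(values), digits)
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  tibble(
    mean = mean(values), mean_printed = mp,
    min = min(values), max = max(values), n = length(values),
    formatted = sprintf("%s [%s;%s]", fmt(mp), fmt(lo), fmt(hi))
  )
}
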