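new_test_result <- function(statistic, p_value, effect, method,
                            exact = FALSE, degenerate = FALSE, ...) {
  out <- list(statistic = unname(statistic), p_value = unname(p_value),
              effect = unname(effect), method = method, exact = exact,
              degenerate = degenerate, ...)
  class(out) <- "t21_test"
  out
}

#' @export
print.t21_test <- function(x, ...) {
  cat(x$method, if (x$exact) "(exact)" else "(asymptotic)", "\n")
  cat("  statistic =", format(x$statistic), "  p =", format(x$p_value),
      "  effect =", format(x$effect), "\n")
  invisible(x)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided exact test of association in a 2x2 table (rows = group,
#' columns = positive/negative), used for autoantibody over-representation
#' screens. The p-value sums hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (with a small relative slack for floating-point ties).
#' The effect is the sample odds ratio `a*d / (b*c)`; when any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to every cell so the
#' odds ratio stays finite.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a`,`b` = group-1
#'   positive/negative, `c`,`d` = group-2 positive/negative.
#' @return A test-result list with `statistic` (the observed `a` cell),
#'   `p_value`, `effect` (odds ratio) and `exact = TRUE`.
#' @examples
#' fisher_exact(5, 5, 5, 5)$p_value   # symmetric table, p = 1
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (length(cells) != 4 || anyNA(cells) || any(cells < 0) ||
      any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0) stop("table total must be positive", call. = FALSE)

  r1 <- a + b; r2 <- c + d; k <- a + c
  lo <- max(0L, k - r2); hi <- min(k, r1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, k)
  p_obs <- stats::dhyper(a, r1, r2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  if (any(cells == 0)) {
    or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
    corrected <- TRUE
  } else {
    or <- (a * d) / (b * c)
    corrected <- FALSE
  }
  new_test_result(statistic = a, p_value = p, effect = or,
                  method = "Fisher's exact test", exact = TRUE,
                  haldane_corrected = corrected)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: for sorted p-values,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and restored to the
#' input order. Missing entries are excluded from the family (they do not
#' count toward `m`) and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, possibly with `NA`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(q)
  pv <- p[ok]
  o <- order(pv)
  q_sorted <- pmin(1, rev(cummin(rev(m * pv[o] / seq_len(m)))))
  qq <- numeric(m)
  qq[o] <- q_sorted
  q[ok] <- qq
  q
}

# Midranks with tie bookkeeping; returns ranks and tie sizes.
.midranks <- function(x) {
  r <- rank(x, ties.method = "average")
  list(ranks = r, ties = as.integer(table(x)))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. The statistic is
#' `U = #\{x_i > y_j\} + 0.5 * #\{x_i = y_j\}`. When `n_x * n_y <= 400`
#' and there are no ties the two-sided p-value is exact (from the null
#' distribution of U); otherwise a normal approximation with tie and
#' continuity corrections is used. The effect reported is the difference
#' of group medians, the convention used for unpaired median differences.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Largest `n_x * n_y` for which the exact branch runs.
#' @return Test-result list with `statistic` (U), `p_value`, `effect`
#'   (median of `x` minus median of `y`).
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  md <- stats::median(x) - stats::median(y)

  if (!has_ties && n * m <= exact_limit) {
    p_le <- stats::pwilcox(U, n, m)
    p_ge <- 1 - stats::pwilcox(U - 1, n, m)
    p <- min(1, 2 * min(p_le, p_ge))
    return(new_test_result(U, p, md, "Mann-Whitney U test", exact = TRUE))
  }
  N <- n + m
  tie_sizes <- as.integer(table(c(x, y)))
  mu <- n * m / 2
  sigma2 <- n * m / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
  if (sigma2 <= 0)  # all values tied
    return(new_test_result(U, 1, md, "Mann-Whitney U test",
                           exact = FALSE, degenerate = TRUE))
  cc <- sign(U - mu) * 0.5
  z <- (U - mu - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result(U, p, md, "Mann-Whitney U test", exact = FALSE)
}

#' Wilcoxon signed-rank test for paired samples (two-sided)
#'
#' Paired location test used for trial visit-versus-baseline endpoints.
#' Differences `after - before` equal to zero are dropped (the common
#' signed-rank convention; flagged in the result). With `n <= 25`
#' non-zero differences and no tied absolute differences the two-sided
#' p-value is exact (enumeration of sign assignments via the signed-rank
#' null distribution); otherwise midranks and a normal approximation with
#' tie and continuity corrections are used. The effect is the median of
#' the paired differences.
#'
#' @param before,after Equal-length paired numeric vectors.
#' @param exact_limit Largest number of non-zero differences for which
#'   the exact branch runs.
#' @return Test-result list with `statistic` (V = positive-rank sum),
#'   `p_value`, `effect` (median paired difference), `n_used`, and
#'   `zeros_dropped`.
#' @export
wilcoxon_signed_rank <- function(before, after, exact_limit = 25) {
  if (length(before) != length(after))
    stop("paired samples must have equal length", call. = FALSE)
  keep <- !(is.na(before) | is.na(after))
  before <- before[keep]; after <- after[keep]
  if (length(before) < 2)
    stop("need at least 2 complete pairs", call. = FALSE)
  d <- after - before
  md <- stats::median(d)
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(new_test_result(0, 1, 0, "Wilcoxon signed-rank test",
                           exact = TRUE, degenerate = TRUE,
                           n_used = 0L, zeros_dropped = zeros))
  ad <- abs(d)
  r <- rank(ad, ties.method = "average")
  V <- sum(r[d > 0])
  tied <- anyDuplicated(ad) > 0

  if (!tied && n <= exact_limit) {
    p_le <- stats::psignrank(V, n)
    p_ge <- 1 - stats::psignrank(V - 1, n)
    p <- min(1, 2 * min(p_le, p_ge))
    return(new_test_result(V, p, md, "Wilcoxon signed-rank test",
                           exact = TRUE, n_used = n, zeros_dropped = zeros))
  }
  mu <- n * (n + 1) / 4
  tie_sizes <- as.integer(table(ad))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_sizes^3 - tie_sizes) / 48
  if (sigma2 <= 0)
    return(new_test_result(V, 1, md, "Wilcoxon signed-rank test",
                           exact = FALSE, degenerate = TRUE,
                           n_used = n, zeros_dropped = zeros))
  cc <- sign(V - mu) * 0.5
  z <- (V - mu - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result(V, p, md, "Wilcoxon signed-rank test",
                  exact = FALSE, n_used = n, zeros_dropped = zeros)
}

#' First and third quartiles by linear interpolation
#'
#' Quantiles under the convention where the quantile index is
#' `p * (n - 1)` (linear interpolation between order statistics; type 7).
#' Fixed package-wide so the extreme-outlier fences are reproducible.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Named numeric vector `c(q1 = ..., q3 = ...)`.
#' @export
quartiles <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("need at least one finite value", call. = FALSE)
  q <- stats::quantile(v, probs = c(0.25, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], q3 = q[2])
}

#' Extreme-outlier mask (3 x IQR fences)
#'
#' Flags measurements strictly more than three interquartile ranges below
#' the first quartile or above the third quartile
#' (`value < Q1 - 3*IQR` or `value > Q3 + 3*IQR`). Values exactly on a
#' fence are retained. With fewer than `min_n` finite values no exclusions
#' are made; non-finite entries are never flagged.
#'
#' @param values Numeric vector.
#' @param min_n Minimum number of finite values needed to compute fences.
#' @return Logical vector, `TRUE` where the value is an extreme outlier.
#' @export
extreme_outlier_mask <- function(values, min_n = 4) {
  mask <- rep(FALSE, length(values))
  fin <- is.finite(values)
  if (sum(fin) < min_n) return(mask)
  q <- quartiles(values)
  iqr <- q["q3"] - q["q1"]
  lower <- q["q1"] - 3 * iqr
  upper <- q["q3"] + 3 * iqr
  mask[fin] <- values[fin] < lower | values[fin] > upper
  mask
}
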