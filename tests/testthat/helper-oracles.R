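# Brute-force oracles, independent of the package implementation.

# Fisher two-sided p by direct hypergeometric enumeration with choose().
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  lo <- max(0, k - r2); hi <- min(k, r1)
  prob <- function(x) choose(r1, x) * choose(r2, k - x) / choose(N, k)
  p_obs <- prob(a)
  support <- lo:hi
  sum(vapply(support, prob, numeric(1))[
    vapply(support, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# Definitional BH step-up: q_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(n))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Linear-interpolation quantile (index = p * (n - 1)), written from the
# definition rather than via stats::quantile.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- p * (length(s) - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

tiny_participants <- function(n_t21 = 6, n_d21 = 4, seed = 42) {
  simulate_participants(cohort_spec(n_t21, n_d21, seed = seed))
}
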