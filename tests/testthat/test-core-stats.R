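test_that("fisher_exact matches enumeration and reports the sample OR", {
  sym <- fisher_exact(5, 5, 5, 5)
  expect_equal(sym$effect, 1)
  expect_equal(sym$p_value, 1)

  t1 <- fisher_exact(3, 7, 1, 9)
  expect_equal(t1$effect, 27 / 7)
  expect_equal(t1$p_value, oracle_fisher_p(3, 7, 1, 9), tolerance = 1e-10)

  t0 <- fisher_exact(0, 10, 5, 5)
  expect_equal(t0$effect, 0.5 * 5.5 / (10.5 * 5.5))
  expect_true(t0$haldane_corrected)
  expect_equal(t0$p_value, oracle_fisher_p(0, 10, 5, 5), tolerance = 1e-10)

  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact(0, 0, 0, 0), "positive")
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    mine <- fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- fisher.test(tab)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-7)
  }
})

test_that("benjamini_hochberg implements the step-up rule with NA handling", {
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  # missing entries leave the family and return NA
  q <- benjamini_hochberg(c(0.01, NA, 0.02, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], c(0.03, 0.03, 0.04))

  # cross-check against p.adjust on complete vectors
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"))
  }

  # sorted q non-decreasing in sorted p
  p <- runif(40)
  q <- benjamini_hochberg(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("mann_whitney_u: exact branch matches enumeration", {
  t1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_value, 1 / 3)
  expect_true(t1$exact)

  x <- c(5, 5, 6); y <- c(5, 6, 7)  # identical values force ties
  tt <- mann_whitney_u(x, x)
  expect_equal(tt$statistic, length(x)^2 / 2)
  expect_equal(tt$p_value, 1)

  set.seed(3)
  for (i in 1:15) {
    x <- round(rnorm(sample(2:6, 1)), 6)
    y <- round(rnorm(sample(2:6, 1)) + 0.5, 6)
    mine <- mann_whitney_u(x, y)
    expect_equal(mine$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney_u exact and normal branches agree near boundary", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15) + runif(1, -1, 1)
    p_exact <- mann_whitney_u(x, y)$p_value
    p_norm <- mann_whitney_u(x, y, exact_limit = 0)$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("wilcoxon_signed_rank: exact enumeration, zeros, degenerate", {
  z <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)

  pos <- wilcoxon_signed_rank(rep(0, 5), c(1, 2, 3, 4, 5))
  expect_equal(pos$p_value, 2 / 32)
  expect_true(pos$exact)

  neg <- wilcoxon_signed_rank(seq(10, 100, 10), seq(10, 100, 10) - (1:10))
  expect_equal(neg$p_value, 2 / 1024)
  expect_lt(neg$effect, 0)

  set.seed(9)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    before <- rnorm(n)
    after <- before + round(rnorm(n), 5)
    mine <- wilcoxon_signed_rank(before, after)
    expect_equal(mine$p_value, oracle_wsr_p(after - before),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("wilcoxon exact and normal branches agree near boundary", {
  set.seed(13)
  for (i in 1:10) {
    before <- rnorm(20)
    after <- before + rnorm(20, 0.3)
    p_exact <- wilcoxon_signed_rank(before, after)$p_value
    p_norm <- wilcoxon_signed_rank(before, after, exact_limit = 0)$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("quartiles use linear interpolation (index = p*(n-1))", {
  q <- quartiles(c(1:9, 100))
  expect_equal(unname(q), c(3.25, 7.75))
  expect_equal(unname(quartiles(rep(4, 6))), c(4, 4))
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(sample(4:40, 1))
    expect_equal(unname(quartiles(x)),
                 c(oracle_quantile(x, 0.25), oracle_quantile(x, 0.75)))
  }
  expect_error(quartiles(numeric(0)), "finite")
})

test_that("extreme_outlier_mask uses strict 3xIQR fences", {
  x <- c(1:9, 100)  # Q3 + 3*IQR = 7.75 + 13.5 = 21.25
  expect_equal(which(extreme_outlier_mask(x)), 10L)
  expect_false(any(extreme_outlier_mask(rep(2, 10))))

  # a value exactly on the fence is retained ("more than" is strict):
  # for c(0 x10, 4 x10, v) the quartiles are 0 and 4, upper fence 16
  expect_false(any(extreme_outlier_mask(c(rep(0, 10), rep(4, 10), 16))))
  expect_true(any(extreme_outlier_mask(c(rep(0, 10), rep(4, 10), 16.001))))
  # too few values: no exclusions
  expect_false(any(extreme_outlier_mask(c(0, 1e6))))
})

test_that("extreme_outlier_mask is invariant under positive affine maps", {
  set.seed(21)
  for (i in 1:10) {
    x <- c(rnorm(20), rnorm(2, 0, 25))
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 10)
    expect_identical(extreme_outlier_mask(x),
                     extreme_outlier_mask(a + b * x))
  }
})
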