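test_that("regression with SEE matches a direct normal-equation solve", {
  set.seed(11)
  x <- runif(25, 50, 200)
  y <- 0.6 * x - 12 + rnorm(25, 0, 8)
  fit <- linreg_see(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)  # independent oracle
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  res <- y - X %*% beta
  expect_equal(fit$see, sqrt(sum(res^2) / (25 - 2)), tolerance = 1e-10)
  expect_equal(fit$r, cor(x, y))

  # collinear points: perfect fit
  fc <- linreg_see(1:10, 3 * (1:10) + 2)
  expect_equal(fc$r, 1)
  expect_equal(fc$see, 0, tolerance = 1e-10)

  # degenerate constant y is flagged, not NaN
  fd <- linreg_see(1:10, rep(5, 10))
  expect_true(fd$degenerate)
  expect_equal(fd$r, 0)
  expect_equal(fd$slope, 0, tolerance = 1e-12)
  expect_error(linreg_see(rep(1, 10), 1:10), "zero variance in x")
  expect_error(linreg_see(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman summaries match brute-force computation", {
  set.seed(12)
  a <- runif(30, 40, 160); b <- a + rnorm(30, -5, 10)
  ba <- bland_altman(a, b, "absolute")
  d <- a - b
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d), tolerance = 1e-12)

  bp <- bland_altman(a, b, "percent")
  dp <- (a - b) / ((a + b) / 2) * 100
  expect_equal(bp$bias, mean(dp), tolerance = 1e-12)
  expect_equal(bp$loa_low, mean(dp) - 1.96 * sd(dp), tolerance = 1e-12)

  # identical pairs
  b0 <- bland_altman(a, a)
  expect_equal(b0$bias, 0)
  expect_equal(b0$sd, 0)

  # halving: percent difference of (50, 100) pairs is -66.67 with zero sd
  bh <- bland_altman(c(50, 50), c(100, 100), "percent")
  expect_equal(bh$bias, -200 / 3, tolerance = 1e-10)
  expect_equal(bh$sd, 0)

  # percent bias is antisymmetric under swapping methods
  expect_equal(bland_altman(b, a, "percent")$bias, -bp$bias, tolerance = 1e-12)
  expect_error(bland_altman(c(1, -1), c(-1, 1), "percent"), "zero-average")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("weighted kappa agrees with the disagreement-form identity", {
  set.seed(13)
  for (rep in 1:20) {
    m <- matrix(rpois(25, 4), 5, 5)
    m[1, 1] <- m[1, 1] + rpois(1, 50)  # realistic diagonal dominance
    k1 <- weighted_kappa(m)$kappa
    # independent form: 1 - sum(o * d) / sum(e * d), d = (i - j)^2
    n <- sum(m)
    d <- outer(1:5, 1:5, `-`)^2
    e <- outer(rowSums(m), colSums(m)) / n
    k2 <- 1 - sum(m * d) / sum(e * d)
    expect_equal(k1, k2, tolerance = 1e-12)
  }
  # purely diagonal table: perfect agreement
  expect_equal(weighted_kappa(diag(c(5, 3, 2, 4, 1)))$kappa, 1)
  # all mass in one cell: expected agreement 1, kappa undefined
  one <- matrix(0, 5, 5); one[1, 1] <- 10
  expect_error(weighted_kappa(one), "undefined kappa")
  expect_error(weighted_kappa(matrix(0, 5, 5)), "empty")
})

test_that("variance-ratio test doubles the correct F tail", {
  set.seed(14)
  d1 <- rnorm(44, sd = 2); d2 <- rnorm(44, sd = 1)
  vr <- variance_ratio_test(d1, d2)
  expect_gte(vr$f, 1)
  expect_equal(vr$f, max(var(d1), var(d2)) / min(var(d1), var(d2)))
  expect_equal(vr$p, min(1, 2 * pf(vr$f, 43, 43, lower.tail = FALSE)))
  # equal samples: F = 1, two-sided p = 1
  ve <- variance_ratio_test(d1, d1)
  expect_equal(ve$f, 1)
  expect_equal(ve$p, 1)
  # exact 4:1 variance scaling
  expect_equal(variance_ratio_test(2 * d2, d2)$f, 4, tolerance = 1e-12)
  expect_error(variance_ratio_test(rep(1, 5), rep(2, 5)), "zero variance")

  # Monte-Carlo oracle for the null distribution of the statistic; equal
  # group sizes, where the larger-over-smaller ratio's tail equals the
  # doubled F tail exactly
  set.seed(15)
  n <- 12
  x1 <- rnorm(n); x2 <- rnorm(n)
  obs <- variance_ratio_test(x1, x2)
  nsim <- 2e5
  f1 <- rchisq(nsim, n - 1) / (n - 1)
  f2 <- rchisq(nsim, n - 1) / (n - 1)
  fsim <- pmax(f1 / f2, f2 / f1)
  p_mc <- mean(fsim >= obs$f)
  se <- sqrt(p_mc * (1 - p_mc) / nsim)
  expect_lt(abs(p_mc - obs$p), 3 * se + 1e-3)
})

test_that("rank tests delegate correctly and Dunn matches hand computation", {
  # three identical repeated columns: Friedman statistic 0 (degenerate
  # ties-only input is warned about, not NaN)
  m <- matrix(rnorm(10), 10, 3)
  expect_warning(fr <- rank_tests(m, kind = "friedman"), "ties-only")
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)

  # Wilcoxon with all a > b, n = 8, no ties: two-sided p = 2 / 2^8
  set.seed(16)
  dpos <- sort(runif(8, 0.5, 8))
  a <- 10 + dpos; b <- rep(10, 8)
  w <- rank_tests(a, b, kind = "wilcoxon_signed_rank")
  expect_equal(w$p_value, 2 / 2^8, tolerance = 1e-12)

  # Kruskal-Wallis on two groups equals the squared rank-sum z statistic
  set.seed(17)
  x <- c(rnorm(7), rnorm(6, 1)); g <- rep(1:2, c(7, 6))
  kw <- rank_tests(x, groups = g, kind = "kruskal_wallis")
  rk <- rank(x); W <- sum(rk[g == 1]); n1 <- 7; n2 <- 6; N <- 13
  z <- (W - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw$statistic, z^2, tolerance = 1e-10)

  # Dunn on 1..9 in three ordered groups: z_AB = -3 / sqrt(5)
  dn <- rank_tests(1:9, groups = rep(c("A", "B", "C"), each = 3),
                   kind = "dunn")
  cmp <- dn$comparisons
  ab <- cmp[cmp$group1 == "A" & cmp$group2 == "B", ]
  expect_equal(ab$z, -3 / sqrt(5), tolerance = 1e-10)
  expect_equal(ab$p_adjusted, min(1, 3 * 2 * pnorm(-3 / sqrt(5))),
               tolerance = 1e-10)
  expect_equal(nrow(cmp), 3)
  expect_error(rank_tests(1:5, kind = "dunn"), "groups")
})
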