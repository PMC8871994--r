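# hand datasets used for the worked-formula checks
hx <- c(4.1, 5.2, 6.3, 3.8, 5.0)
hy <- c(7.4, 6.9, 8.1, 7.7, 7.0)

test_that("the variance F test matches the textbook formula", {
  f <- f_variance_test(hx, hy)
  s2x <- sum((hx - mean(hx))^2) / 4
  s2y <- sum((hy - mean(hy))^2) / 4
  Fstat <- s2x / s2y
  p <- 2 * min(pf(Fstat, 4, 4), 1 - pf(Fstat, 4, 4))
  expect_lt(abs(f$statistic - Fstat), 1e-10)
  expect_lt(abs(f$p_value - p), 1e-10)
  # identical samples: F = 1
  expect_equal(f_variance_test(hx, hx)$statistic, 1)
  # scaling one sample by 2 scales the ratio by 4
  expect_equal(f_variance_test(hx, 2 * hy)$statistic, Fstat / 4,
               tolerance = 1e-12)
  # doubly degenerate input routes to Welch downstream
  expect_true(is.na(f_variance_test(rep(1, 3), rep(2, 3))$p_value))
})

test_that("Student and Welch t match hand-computed formulas to 1e-10", {
  x <- c(1.2, 2.4, 3.1, 4.5)
  y <- c(2.2, 2.9, 4.4, 5.1)
  nx <- 4; ny <- 4
  s2x <- var(x); s2y <- var(y)
  # pooled (Student)
  sp2 <- ((nx - 1) * s2x + (ny - 1) * s2y) / (nx + ny - 2)
  t_st <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p_st <- 2 * pt(-abs(t_st), nx + ny - 2)
  st <- student_t(x, y)
  expect_lt(abs(st$statistic - t_st), 1e-10)
  expect_lt(abs(st$p_value - p_st), 1e-10)
  expect_identical(st$df, 6)
  # Welch with Welch-Satterthwaite df
  se2 <- s2x / nx + s2y / ny
  t_w <- (mean(x) - mean(y)) / sqrt(se2)
  df_w <- se2^2 / ((s2x / nx)^2 / (nx - 1) + (s2y / ny)^2 / (ny - 1))
  p_w <- 2 * pt(-abs(t_w), df_w)
  w <- welch_t(x, y)
  expect_lt(abs(w$statistic - t_w), 1e-10)
  expect_lt(abs(w$df - df_w), 1e-10)
  expect_lt(abs(w$p_value - p_w), 1e-10)
})

test_that("two-sample tests are antisymmetric and handle degeneracy", {
  w1 <- welch_t(hx, hy)
  w2 <- welch_t(hy, hx)
  expect_equal(w1$statistic, -w2$statistic)
  expect_equal(w1$p_value, w2$p_value)
  d <- welch_t(rep(2, 5), rep(2, 5))
  expect_identical(d$statistic, 0)
  expect_identical(d$p_value, 1)
  idp <- welch_t(hx, hx)
  expect_equal(idp$statistic, 0)
  expect_equal(idp$p_value, 1)
})

test_that("the Fisher test routes between Student and Welch", {
  set.seed(61)
  a <- rnorm(50, sd = 1)
  b <- rnorm(50, sd = 6)
  expect_identical(two_sample_test(a, b)$test, "welch_t")
  c2 <- rnorm(50, sd = 1)
  expect_identical(two_sample_test(a, c2)$test, "student_t")
  expect_identical(two_sample_test(rep(1, 4), rep(1, 4))$test, "welch_t")
})

test_that("Kruskal-Wallis matches a hand-computed tied example", {
  g <- list(c(1, 3, 5), c(2, 4, 6), c(7, 8, 5))
  pooled <- unlist(g)
  r <- rank(pooled)
  n <- length(pooled)
  groups <- rep(seq_along(g), lengths(g))
  Rbar <- tapply(r, groups, mean)
  H <- (12 / (n * (n + 1))) * sum(lengths(g) * (Rbar - (n + 1) / 2)^2)
  ties <- table(pooled)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  k <- kruskal_wallis(g)
  expect_lt(abs(k$statistic - H), 1e-10)
  expect_lt(abs(k$p_value - (1 - pchisq(H, 2))), 1e-10)
  expect_identical(kruskal_wallis(list(c(1, 1), c(1, 1)))$statistic, 0)
})

test_that("OLS is exact on collinear input and shift-invariant", {
  x <- 0:5
  fit <- ols_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_lt(fit$residual_variance, 1e-20)
  y <- c(0.3, 1.1, 2.2, 2.7, 4.4, 5.1)
  f1 <- ols_fit(x, y)
  f2 <- ols_fit(x, y + 10)
  expect_equal(f1$slope, f2$slope)
  expect_equal(f2$intercept, f1$intercept + 10)
  expect_error(ols_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("p-values are uniform under the null (KS check)", {
  set.seed(67)
  p_w <- replicate(2000, welch_t(rnorm(12), rnorm(12))$p_value)
  expect_gt(ks.test(p_w, "punif")$p.value, 0.01)
  p_k <- replicate(1000,
                   kruskal_wallis(list(rnorm(12), rnorm(12),
                                       rnorm(12)))$p_value)
  # rank tests are discrete at this n; check the tail mass instead
  expect_lt(abs(mean(p_k < 0.1) - 0.1), 0.03)
})
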