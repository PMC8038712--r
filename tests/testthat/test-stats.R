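test_that("Kruskal-Wallis matches the hand-computed rank formula", {
  # ranks 1..9 in three blocks: Rbar = 2, 5, 8 -> H = 7.2
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(r$p_value, 0.0273, tolerance = 1e-3)

  same <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(kruskal_wallis(list(c(5, 5, 5), c(5, 5, 5))),
               class = "ftirfp_degenerate_error")
  expect_error(kruskal_wallis(list(1:3)), class = "ftirfp_validation_error")
})

test_that("many-to-one rank post hoc reproduces the closed-form z", {
  res <- manytoone_rank_posthoc(list(a = c(1, 2, 3), ctrl = c(4, 5, 6),
                                     b = c(7, 8, 9)), control_index = 2)
  expect_length(res, 2)
  expect_equal(res$a$statistic, -3 / sqrt(5), tolerance = 1e-12)
  expect_equal(res$b$statistic, 3 / sqrt(5), tolerance = 1e-12)
  p_un <- 2 * pnorm(-3 / sqrt(5))
  expect_equal(p_un, 0.1797, tolerance = 1e-3)
  expect_equal(res$a$p_value, min(1, 2 * p_un), tolerance = 1e-10)
  expect_equal(res$a$p_value, 0.3594, tolerance = 1e-3)

  # treatment identical to control
  res2 <- manytoone_rank_posthoc(list(ctrl = c(1, 3), t = c(1, 3)),
                                 control_index = 1)
  expect_equal(res2$t$statistic, 0)
  expect_equal(res2$t$p_value, 1)

  # adjustment "none" leaves p unadjusted
  res3 <- manytoone_rank_posthoc(list(a = c(1, 2, 3), ctrl = c(4, 5, 6),
                                      b = c(7, 8, 9)), control_index = 2,
                                 adjustment = "none")
  expect_equal(res3$a$p_value, p_un, tolerance = 1e-10)
  expect_false(res3$a$adjusted)

  expect_error(manytoone_rank_posthoc(list(numeric(0), 1:3), 1),
               class = "ftirfp_validation_error")
})

test_that("exact Mann-Whitney p matches full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)

  mid <- mann_whitney_u(c(1, 4), c(2, 3))
  expect_equal(mid$statistic, 2)
  expect_equal(mid$p_value, 1)

  same <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3), method = "normal")
  expect_equal(same$p_value, 1)

  # exact requested with ties: falls back with a recorded notice
  tied <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4), method = "exact")
  expect_match(tied$note, "ties")

  # property: exact p equals the enumeration oracle on random tie-free input
  set.seed(31)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2)          # distinct values, no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y, method = "exact")$p_value,
                 mw_exact_p_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis with two groups equals the squared normal MW z", {
  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v <- sample(10000, n1 + n2)
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    H <- kruskal_wallis(list(x, y))$statistic
    r <- rank(c(x, y))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    expect_equal(H, z^2, tolerance = 1e-9)
  }
})

test_that("Welch's t matches the closed form and is scale invariant", {
  r <- welch_t(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(r$statistic, -3 / sqrt(2.5 / 5 + 10 / 5), tolerance = 1e-12)
  expect_equal(r$statistic, -1.8974, tolerance = 1e-4)
  expect_equal(r$df, 2.5^2 / (0.5^2 / 4 + 2^2 / 4), tolerance = 1e-10)
  expect_equal(r$df, 5.88, tolerance = 1e-2)
  expect_equal(r$p_value, 0.107, tolerance = 1e-2)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  r2 <- welch_t(7 * c(1, 2, 3, 4, 5), 7 * c(2, 4, 6, 8, 10))
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-10)

  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)),
               class = "ftirfp_degenerate_error")
  expect_error(welch_t(1, c(1, 2)), class = "ftirfp_validation_error")
})

test_that("normality screen reproduces the K-squared reference values", {
  # frozen reference values computed independently with the standard
  # D'Agostino (1970) / Anscombe-Glynn (1983) transforms
  r1 <- normality_screen((1:20)^1.5)
  expect_equal(r1$statistic, 2.8797112813, tolerance = 1e-8)
  expect_equal(r1$p_value, 0.2369619639, tolerance = 1e-8)
  expect_equal(r1$recommendation, "parametric")

  r2 <- normality_screen(log(1:15))
  expect_equal(r2$statistic, 4.5927961165, tolerance = 1e-8)
  expect_equal(r2$p_value, 0.1006206214, tolerance = 1e-8)

  r3 <- normality_screen(c(2.1, -0.8, 0.5, 1.7, -1.2, 0.3, 0.9, -0.4, 1.1,
                           -2.0, 0.6, 0.2))
  expect_equal(r3$statistic, 0.3469005021, tolerance = 1e-8)

  small <- normality_screen(1:5)
  expect_true(is.na(small$p_value))
  expect_true(is.na(small$recommendation))
  expect_match(small$note, "insufficient")
})

test_that("normality screen separates normal from skewed samples", {
  set.seed(23)
  null_ok <- 0; alt_ok <- 0
  for (i in 1:100) {
    null_ok <- null_ok + (normality_screen(rnorm(500))$p_value > 0.05)
    alt_ok <- alt_ok + (normality_screen(rexp(500))$p_value < 0.05)
  }
  expect_gte(null_ok, 90)
  expect_gte(alt_ok, 95)
})

test_that("rank tests are invariant to within-group permutation and group order", {
  set.seed(41)
  g1 <- rnorm(7); g2 <- rnorm(5); g3 <- rnorm(6)
  h <- kruskal_wallis(list(g1, g2, g3))$statistic
  expect_equal(kruskal_wallis(list(sample(g1), sample(g3), sample(g2)))$statistic,
               h, tolerance = 1e-12)
  u <- mann_whitney_u(g1, g2)
  u2 <- mann_whitney_u(sample(g1), sample(g2))
  expect_equal(u2$statistic, u$statistic)
  expect_equal(u2$p_value, u$p_value, tolerance = 1e-12)
})

test_that("Kruskal-Wallis holds its nominal level on iid groups", {
  set.seed(57)
  rej <- 0; n <- 5000
  for (i in 1:n) {
    p <- kruskal_wallis(list(rnorm(10), rnorm(10), rnorm(10)))$p_value
    rej <- rej + (p <= 0.05)
  }
  expect_gte(rej / n, 0.04)
  expect_lte(rej / n, 0.06)
})
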