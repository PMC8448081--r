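test_that("paired_rm_anova equals the squared paired t (oracle)", {
  set.seed(31)
  for (i in 1:5) {
    pre <- rnorm(10, 20, 4)
    post <- pre + rnorm(10, -1, 2)
    a <- paired_rm_anova(pre, post)
    o <- paired_t_oracle(pre, post)
    expect_equal(a$f_stat, o$t^2)
    expect_equal(a$p_value, o$p)
    expect_equal(a$df_den, o$df)
    expect_equal(a$partial_eta_sq, a$f_stat / (a$f_stat + length(pre) - 1))
  }
  same <- rnorm(8)
  a0 <- paired_rm_anova(same, same)
  expect_equal(a0$f_stat, 0)
  expect_equal(a0$partial_eta_sq, 0)
  expect_error(paired_rm_anova(c(1, 2, 3), c(2, 3, 4)),
               class = "dualchange_degenerate_error")  # constant nonzero diffs
})

test_that("one_sample_manova: T2/lambda/F identities and p=1 reduction", {
  # p = 1 reduces exactly to the paired design
  set.seed(32)
  d <- rnorm(20, 1, 2)
  m <- one_sample_manova(matrix(d, ncol = 1))
  a <- paired_rm_anova(d, rep(0, 20))
  expect_equal(m$f_stat, a$f_stat)
  expect_equal(m$p_value, a$p_value)
  expect_equal(c(m$df_num, m$df_den), c(1L, 19L))

  # all-zero differences
  z <- one_sample_manova(matrix(0, 10, 3))
  expect_equal(z$wilks_lambda, 1)
  expect_equal(z$f_stat, 0)
  expect_equal(z$partial_eta_sq, 0)

  # df convention of the full design
  set.seed(33)
  D <- matrix(rnorm(89 * 6), 89, 6)
  m6 <- one_sample_manova(D)
  expect_equal(c(m6$df_num, m6$df_den), c(6L, 83L))
  # eta identity to machine precision against the F-based formula at (p, n-p)
  expect_equal(m6$partial_eta_sq, 1 - m6$wilks_lambda)
  expect_equal(m6$wilks_lambda, 1 / (1 + m6$hotelling_t2 / 88))

  expect_error(one_sample_manova(matrix(rnorm(12), 4, 6)),
               class = "dualchange_input_error")          # n <= p
  expect_error(one_sample_manova(cbind(d, d)),
               class = "dualchange_degenerate_error")     # singular covariance
})

test_that("two_group_manova: df convention and p=1 pooled-t reduction", {
  set.seed(34)
  x <- rnorm(12, 0, 1); y <- rnorm(9, 1, 1)
  m <- two_group_manova(matrix(c(x, y), ncol = 1), rep(c("a", "b"), c(12, 9)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(m$f_stat, unname(tt$statistic)^2)
  expect_equal(m$p_value, tt$p.value)

  X <- matrix(rnorm(89 * 6), 89, 6)
  g <- rep(c("student", "general"), c(32, 57))
  m6 <- two_group_manova(X, g)
  expect_equal(c(m6$df_num, m6$df_den), c(6L, 82L))
  expect_equal(m6$wilks_lambda, 1 / (1 + m6$hotelling_t2 / 87))
  expect_equal(m6$partial_eta_sq, 1 - m6$wilks_lambda)

  expect_error(two_group_manova(X, rep("a", 89)), class = "dualchange_input_error")
  expect_error(two_group_manova(X[1:8, ], rep(c("a", "b"), c(1, 7))),
               class = "dualchange_input_error")
})

test_that("effect-size conversions", {
  expect_equal(partial_eta_from_f(0, 1, 88), 0)
  expect_equal(partial_eta_from_f(25.29, 1, 88), 25.29 / (25.29 + 88))
  expect_equal(eta_from_lambda(1), 0)
  expect_error(eta_from_lambda(0), class = "dualchange_input_error")
  expect_error(eta_from_lambda(1.1), class = "dualchange_input_error")
})

test_that("baseline_stratified_change_test: t, df and pooled-SD d", {
  set.seed(35)
  pre <- rnorm(89, 20, 5)
  post <- pre + rnorm(89, 2, 4)
  flag <- rep(c(TRUE, FALSE), c(51, 38))
  s <- baseline_stratified_change_test(pre, post, flag, outcome = "wb")
  expect_lte(s$df, 87)                          # df <= n1 + n2 - 2
  ch <- post - pre
  tt <- t.test(ch[flag], ch[!flag])
  expect_equal(s$t_stat, unname(tt$statistic))
  expect_equal(s$p_value, tt$p.value)
  sp <- sqrt((50 * var(ch[flag]) + 37 * var(ch[!flag])) / 87)
  expect_equal(s$cohen_d, (mean(ch[flag]) - mean(ch[!flag])) / sp)
  # pooled mode has integer df n1 + n2 - 2
  s2 <- baseline_stratified_change_test(pre, post, flag, welch = FALSE)
  expect_equal(s2$df, 87)
  expect_error(baseline_stratified_change_test(pre, post, rep(c(TRUE, FALSE), c(1, 88)),
                                               outcome = "wb"),
               regexp = "wb", class = "dualchange_input_error")
})

test_that("mann_whitney_check matches exhaustive enumeration on separation", {
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  got <- mann_whitney_check(c(x, y), rep(c("a", "b"), each = 3))
  oracle <- mw_enumerate(x, y)
  expect_equal(got$u_stat, oracle$u)   # complete separation: U = 0
  expect_true(got$u_stat %in% c(0, 9))
  expect_equal(got$p_value, oracle$p)  # 2/20 = 0.1
  # identical multisets -> p ~ 1
  same <- mann_whitney_check(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gt(same$p_value, 0.99)
  expect_error(mann_whitney_check(rep(5, 6), rep(c("a", "b"), each = 3)),
               class = "dualchange_degenerate_error")
  # large-n shift alternative detected
  set.seed(36)
  shift <- mann_whitney_check(c(rnorm(200), rnorm(200, 1)),
                              rep(c("a", "b"), each = 200))
  expect_lt(shift$p_value, 0.05)
})

test_that("outcome_correlations: symmetry, unit diagonal, limits", {
  set.seed(37)
  co <- generate_cohort(simulation_config(n_participants = 600, seed = 37))
  r <- outcome_correlations(co, timepoint = "pre")
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 6))
  # independent outcomes -> r ~ 0
  ind <- data.frame(a = rnorm(2000), b = rnorm(2000))
  r2 <- outcome_correlations(ind, outcomes = c("a", "b"))
  expect_lt(abs(r2["a", "b"]), 0.08)
  # constant outcome flagged as NA with warning
  const <- data.frame(a = rnorm(10), b = rep(1, 10))
  expect_warning(r3 <- outcome_correlations(const, outcomes = c("a", "b")),
                 "constant")
  expect_true(is.na(r3["a", "b"]))
})

test_that("flag_univariate_outliers flags by |z| with configurable threshold", {
  set.seed(38)
  x <- c(rnorm(49, 0, 1), 10)   # last value ~10 SDs out
  flags <- flag_univariate_outliers(x)
  z <- (x - mean(x)) / sd(x)
  expect_identical(flags, abs(z) > 3.29)
  expect_true(flags[50])
  expect_equal(sum(flags), 1L)
  expect_false(any(flag_univariate_outliers(x, threshold = Inf)))
  expect_warning(f0 <- flag_univariate_outliers(cbind(rep(2, 5))), "zero SD")
  expect_false(any(f0))
})

test_that("statistics are invariant to participant ordering", {
  set.seed(39)
  X <- matrix(rnorm(40 * 3), 40, 3)
  g <- rep(c("a", "b"), 20)
  perm <- sample.int(40)
  m1 <- one_sample_manova(X); m2 <- one_sample_manova(X[perm, ])
  expect_equal(m1$f_stat, m2$f_stat)
  t1 <- two_group_manova(X, g); t2 <- two_group_manova(X[perm, ], g[perm])
  expect_equal(t1$f_stat, t2$f_stat)
  a1 <- paired_rm_anova(X[, 1], X[, 2])
  a2 <- paired_rm_anova(X[perm, 1], X[perm, 2])
  expect_equal(a1$f_stat, a2$f_stat)
})

test_that("rank_inverse_normal preserves order and normalises", {
  x <- c(3, 1, 2, NA, 5)
  y <- rank_inverse_normal(x)
  expect_true(is.na(y[4]))
  expect_equal(order(y[-4]), order(x[-4]))
  expect_equal(mean(y, na.rm = TRUE), 0, tolerance = 1e-10)
})
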