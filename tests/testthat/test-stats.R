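test_that("the gate selects the t-branch for normal data and records every gate outcome", {
  set.seed(123)
  a <- rnorm(50); b <- rnorm(50, 0.2)
  r <- gated_two_sample_test(a, b)
  expect_true(all(r$shapiro_p > 0.05))
  expect_true(r$normal)
  expect_false(is.na(r$levene_p))
  expect_match(r$test_used, "^t_")
  # branch is a pure function of the recorded gate p-values
  expect_identical(r$test_used,
                   if (r$levene_p > r$alpha) "t_equal_var" else "t_unequal_var")
  # agreement with the corresponding base test
  tt <- t.test(a, b, var.equal = r$test_used == "t_equal_var")
  expect_equal(r$p_value, tt$p.value)
})

test_that("a non-normal group routes the comparison to the Mann-Whitney branch", {
  set.seed(102)
  a <- rnorm(50)^2                      # heavily skewed
  b <- rnorm(50)
  r <- gated_two_sample_test(a, b)
  expect_true(any(r$shapiro_p <= 0.05))
  expect_identical(r$test_used, "mann_whitney")
  expect_true(is.na(r$levene_p))
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("identical samples give a p-value near 1", {
  set.seed(103)
  a <- rnorm(30)
  r <- gated_two_sample_test(a, a)
  expect_gte(r$p_value, 0.9)
})

test_that("zero-variance groups produce a degenerate report without a p-value", {
  r <- gated_two_sample_test(rep(1, 5), rnorm(5))
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  expect_true(is.na(r$test_used))
  expect_error(gated_two_sample_test(1:2, rnorm(5)), "at least 3")
})

test_that("the Mann-Whitney implementation matches base wilcox.test on both branches", {
  set.seed(104)
  # exact enumeration branch (n <= 8, no ties)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    ours <- mwu_test(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_identical(ours$method, "exact")
  }
  # normal approximation with continuity (and tie) correction
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(25, 0.3)
    ours <- mwu_test(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # ties
  a <- c(1, 2, 2, 3, 4, 4, 4, 6, 7, 8); b <- c(2, 3, 3, 5, 5, 6, 7, 7, 9, 9)
  expect_equal(mwu_test(a, b)$p_value,
               suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))$p.value,
               tolerance = 1e-12)
})

test_that("Monte-Carlo Mann-Whitney power is reproducible and calibrated", {
  p1 <- mwu_power_mc(0.5, 20, reps = 500, seed = 7)
  p2 <- mwu_power_mc(0.5, 20, reps = 500, seed = 7)
  expect_identical(p1, p2)              # same seed, bit-identical
  # null rejection rate near the nominal level
  p0 <- mwu_power_mc(0, 50, reps = 4000, seed = 8)
  expect_lt(abs(p0 - 0.05), 0.02)
  # separated distributions are always detected
  expect_gte(mwu_power_mc(3, 50, reps = 1000, seed = 9), 0.999)
  # monotone in effect and in n (within Monte-Carlo error)
  pw <- vapply(c(0.2, 0.5, 0.9), mwu_power_mc, numeric(1),
               n_per_group = 40, reps = 1500, seed = 10)
  expect_true(all(diff(pw) > 0))
  pn <- vapply(c(10, 30, 80), function(n)
    mwu_power_mc(0.5, n, reps = 1500, seed = 11), numeric(1))
  expect_true(all(diff(pn) > 0))
  expect_error(mwu_power_mc(0.5, 2, reps = 500, seed = 1), ">= 3")
  expect_error(mwu_power_mc(0.5, 10, reps = 50, seed = 1), ">= 100")
})

test_that("bootstrap power mode resamples the observed samples", {
  set.seed(12)
  x <- rnorm(40); y <- rnorm(40, 1.2)
  pb <- mwu_power_mc(n_per_group = 40, reps = 500, seed = 13,
                     method = "bootstrap", x = x, y = y)
  expect_gt(pb, 0.9)
  expect_error(mwu_power_mc(n_per_group = 40, reps = 500, seed = 13,
                            method = "bootstrap"), "observed samples")
})

test_that("noncentral-t power matches a quadrature oracle and is monotone", {
  expect_equal(t_test_power(0, 20), 0.05, tolerance = 1e-12)
  # oracle: integrate P(reject | chi-square scale) over the chi-square density
  power_quad <- function(d, n, alpha = 0.05) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    crit <- qt(1 - alpha / 2, df)
    f <- function(v)
      (pnorm(-crit * sqrt(v / df) - ncp) +
       pnorm(crit * sqrt(v / df) - ncp, lower.tail = FALSE)) * dchisq(v, df)
    integrate(f, qchisq(1e-12, df), qchisq(1 - 1e-12, df),
              rel.tol = 1e-10)$value
  }
  expect_equal(t_test_power(0.8, 26), power_quad(0.8, 26), tolerance = 1e-3)
  expect_equal(t_test_power(0.3, 100), power_quad(0.3, 100), tolerance = 1e-3)
  d_grid <- seq(0.1, 1.2, by = 0.1)
  expect_true(all(diff(vapply(d_grid, t_test_power, numeric(1),
                              n_per_group = 25)) > 0))
  n_grid <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(vapply(n_grid, function(n)
    t_test_power(0.5, n), numeric(1))) > 0))
  expect_error(t_test_power(0.5, 1), ">= 2")
})

test_that("gated test reports export cleanly to a data frame", {
  set.seed(105)
  r <- gated_two_sample_test(rnorm(20), rnorm(20), group_names = c("c", "i"))
  df <- as.data.frame(r)
  expect_identical(df$group_a, "c")
  expect_true(is.finite(df$p_value))
  expect_identical(names(df)[1:2], c("group_a", "group_b"))
})
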