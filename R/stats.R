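#' Gated two-sample test (Shapiro-Wilk, Levene, t-test / Mann-Whitney U)
#'
#' Executes the decision tree used throughout the analyses: Shapiro-Wilk
#' normality on each group at level `alpha`; if both pass, a Levene test for
#' equality of variances (Brown-Forsythe form, centering on the median)
#' chooses between the equal-variance and Welch t-test; if at least one group
#' is non-normal, a two-sided Mann-Whitney U test is used instead. Every gate
#' outcome is recorded in the report.
#'
#' Zero-variance (constant) groups make Shapiro-Wilk undefined; the report is
#' then flagged degenerate and carries no p-value. Shapiro-Wilk is calibrated
#' for 3 <= n <= 5000; larger groups are tested on their first 5000 values
#' with a warning.
#'
#' @param a,b numeric samples, each of length >= 3, finite.
#' @param alpha significance level for gates and test (default 0.05).
#' @param group_names length-2 character labels for the report.
#' @return an object of class `gated_test`: list with `shapiro_p` (one per
#'   group), `normal`, `levene_p` (NA when the Mann-Whitney branch is taken),
#'   `test_used` (`"t_equal_var"`, `"t_unequal_var"`, `"mann_whitney"`, or NA
#'   when degenerate), `statistic`, `p_value`, `alpha`, `n`, `medians`,
#'   `degenerate`.
#' @export
gated_two_sample_test <- function(a, b, alpha = 0.05,
                                  group_names = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each sample needs at least 3 observations")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite")
  base <- list(alpha = alpha, n = c(length(a), length(b)),
               group_names = group_names,
               medians = c(stats::median(a), stats::median(b)),
               means = c(mean(a), mean(b)),
               sds = c(stats::sd(a), stats::sd(b)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rep <- c(base, list(shapiro_p = c(NA_real_, NA_real_), normal = NA,
                        levene_p = NA_real_, test_used = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        degenerate = TRUE))
    return(structure(rep, class = "gated_test"))
  }
  sp <- c(shapiro_capped(a), shapiro_capped(b))
  normal <- all(sp > alpha)
  if (normal) {
    g <- factor(rep(group_names, c(length(a), length(b))))
    lev <- car::leveneTest(c(a, b) ~ g, center = stats::median)
    levene_p <- lev[["Pr(>F)"]][1L]
    tt <- stats::t.test(a, b, var.equal = levene_p > alpha)
    rep <- c(base, list(
      shapiro_p = sp, normal = TRUE, levene_p = levene_p,
      test_used = if (levene_p > alpha) "t_equal_var" else "t_unequal_var",
      statistic = unname(tt$statistic), p_value = tt$p.value,
      degenerate = FALSE))
  } else {
    mw <- mwu_test(a, b)
    rep <- c(base, list(
      shapiro_p = sp, normal = FALSE, levene_p = NA_real_,
      test_used = "mann_whitney", statistic = mw$U, p_value = mw$p_value,
      degenerate = FALSE))
  }
  structure(rep, class = "gated_test")
}

shapiro_capped <- function(x) {
  if (length(x) > 5000L) {
    warning("Shapiro-Wilk is calibrated for n <= 5000; using the first 5000 values")
    x <- x[seq_len(5000L)]
  }
  stats::shapiro.test(x)$p.value
}

#' @export
print.gated_test <- function(x, ...) {
  cat(sprintf("Gated two-sample test: %s (n=%d) vs %s (n=%d)\n",
              x$group_names[1], x$n[1], x$group_names[2], x$n[2]))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate: a group has zero variance; no test performed\n")
    return(invisible(x))
  }
  cat(sprintf("  Shapiro-Wilk p: %.4g / %.4g  ->  %s\n", x$shapiro_p[1],
              x$shapiro_p[2], if (x$normal) "normal" else "non-normal"))
  if (x$normal)
    cat(sprintf("  Levene p: %.4g\n", x$levene_p))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g (alpha = %g)\n",
              x$test_used, x$statistic, x$p_value, x$alpha))
  invisible(x)
}

#' @export
as.data.frame.gated_test <- function(x, ...) {
  data.frame(group_a = x$group_names[1], group_b = x$group_names[2],
             n_a = x$n[1], n_b = x$n[2],
             shapiro_p_a = x$shapiro_p[1], shapiro_p_b = x$shapiro_p[2],
             levene_p = x$levene_p,
             test_used = if (is.na(x$test_used)) "degenerate" else x$test_used,
             statistic = x$statistic, p_value = x$p_value,
             median_a = x$medians[1], median_b = x$medians[2],
             alpha = x$alpha, stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney U test
#'
#' U statistic of the first sample with a two-sided p-value: exact
#' enumeration of the U distribution when both groups have at most 8
#' observations and there are no ties, otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @return list with `U` (statistic of the first sample), `p_value`,
#'   `method`.
#' @export
mwu_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (n1 <= 8 && n2 <= 8 && !has_ties) {
    mu <- n1 * n2 / 2
    p <- if (U > mu) 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
         else 2 * stats::pwilcox(U, n1, n2)
    list(U = U, p_value = min(p, 1), method = "exact")
  } else {
    list(U = U, p_value = mwu_normal_p(U, n1, n2, ties), method = "normal")
  }
}

# normal approximation with tie and continuity corrections
mwu_normal_p <- function(U, n1, n2, ties) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  if (sigma == 0) return(NA_real_)
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Monte-Carlo power of the two-sided Mann-Whitney U test
#'
#' Estimates power by simulation: in each repetition two samples of size
#' `n_per_group` are drawn from unit-variance normal distributions whose
#' means differ by `effect` (a location shift in SD units), a two-sided
#' Mann-Whitney U test is applied, and power is the fraction of repetitions
#' rejecting at level `alpha`. Reproducible under a fixed seed.
#'
#' With `method = "bootstrap"`, samples are instead drawn with replacement
#' from two observed samples `x` and `y`, estimating power at the observed
#' effect and distributional shape.
#'
#' @param effect location shift in SD units (normal method).
#' @param n_per_group sample size per group, >= 3.
#' @param alpha significance level (default 0.05).
#' @param reps Monte-Carlo repetitions, >= 100 (default 10000).
#' @param seed integer seed (required: every stochastic step is seeded).
#' @param method `"normal"` (default) or `"bootstrap"`.
#' @param x,y observed samples for the bootstrap method.
#' @return scalar power estimate in `[0, 1]`.
#' @export
mwu_power_mc <- function(effect, n_per_group, alpha = 0.05, reps = 10000,
                         seed, method = c("normal", "bootstrap"),
                         x = NULL, y = NULL) {
  method <- match.arg(method)
  n <- as.integer(n_per_group)
  reps <- as.integer(reps)
  if (is.na(n) || n < 3L) stop("'n_per_group' must be >= 3")
  if (is.na(reps) || reps < 100L) stop("'reps' must be >= 100")
  if (missing(seed)) stop("'seed' is required")
  if (method == "bootstrap" && (is.null(x) || is.null(y)))
    stop("bootstrap method needs observed samples 'x' and 'y'")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  S <- if (method == "normal") {
    m <- matrix(stats::rnorm(2 * n * reps), nrow = 2 * n)
    m[(n + 1):(2 * n), ] <- m[(n + 1):(2 * n), ] + effect
    m
  } else {
    rbind(matrix(sample(x, n * reps, replace = TRUE), nrow = n),
          matrix(sample(y, n * reps, replace = TRUE), nrow = n))
  }
  p <- apply(S, 2, function(col)
    mwu_test(col[seq_len(n)], col[(n + 1):(2 * n)])$p_value)
  mean(p < alpha)
}

#' Power of the two-sample t-test (noncentral t)
#'
#' Exact two-sided power of the equal-variance two-sample t-test for effect
#' size Cohen's d and `n` observations per group: noncentrality
#' `d * sqrt(n/2)` with `2n - 2` degrees of freedom.
#'
#' @param d Cohen's d effect size.
#' @param n_per_group observations per group, >= 2.
#' @param alpha significance level (default 0.05).
#' @return power in `[0, 1]`.
#' @export
t_test_power <- function(d, n_per_group, alpha = 0.05) {
  n <- as.integer(n_per_group)
  if (is.na(n) || n < 2L) stop("'n_per_group' must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp = ncp) + stats::pt(crit, df, ncp = ncp,
                                              lower.tail = FALSE)
}
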