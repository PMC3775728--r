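# Reference K^2/p values for the omnibus normality test were computed with an
# independent implementation of the same transformed-moment formulation on
# these exact deterministic vectors.
test_that("omnibus normality statistic matches independent reference values", {
  x1 <- qnorm((1:30 - 0.5) / 30)            # near-normal quantile sample
  x2 <- exp(seq(0, 2, length.out = 25))     # right-skewed
  x3 <- sqrt(1:8)                           # minimal allowed n
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$k2, 0.006458464958, tolerance = 1e-9)
  expect_equal(r1$p_value, 0.996775975885, tolerance = 1e-9)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$k2, 2.917256618714, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.232555049635, tolerance = 1e-9)
  r3 <- dagostino_pearson(x3)
  expect_equal(r3$k2, 0.564014290287, tolerance = 1e-9)
  expect_equal(r3$p_value, 0.754268295159, tolerance = 1e-9)
})

test_that("normality test rejects skewed data and validates its input", {
  set.seed(31)
  p_skew <- replicate(100, dagostino_pearson(rexp(100))$p_value)
  expect_gte(mean(p_skew < 0.05), 0.95)
  expect_error(dagostino_pearson(rnorm(7)), class = "strokecbv_input_error")
  expect_error(dagostino_pearson(rep(2, 20)), class = "strokecbv_input_error")
})

test_that("two-sample t behaves canonically and is swap-symmetric", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  same <- two_sample_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(5)
  a <- rnorm(9, 1); b <- rnorm(12, 2)
  ab <- two_sample_t(a, b); ba <- two_sample_t(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p_value, ba$p_value)
  expect_true(ab$p_value >= 0 && ab$p_value <= 1)
  expect_error(two_sample_t(1, a), class = "strokecbv_input_error")
})

test_that("summary-statistic t equals the t computed from constructed samples", {
  set.seed(77)
  for (i in 1:20) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    s1 <- runif(1, 0.5, 4); s2 <- runif(1, 0.5, 4)
    a <- sample_with_moments(n1, m1, s1, rnorm(n1))
    b <- sample_with_moments(n2, m2, s2, rnorm(n2))
    for (variant in c("pooled", "welch")) {
      full <- two_sample_t(a, b, variant)
      summ <- two_sample_t_summary(n1, m1, s1, n2, m2, s2, variant)
      expect_equal(summ$t, full$t, tolerance = 1e-10)
      expect_equal(summ$df, full$df, tolerance = 1e-10)
      expect_equal(summ$p_value, full$p_value, tolerance = 1e-10)
    }
  }
})

test_that("pooled t p-value agrees with a permutation oracle on small samples", {
  set.seed(19)
  a <- rnorm(8, 0.8); b <- rnorm(7)
  p_t <- two_sample_t(a, b)$p_value
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(4000, {
    idx <- sample(length(pool), length(a))
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.02)
})

test_that("Pearson correlation identities hold", {
  x <- c(0.3, 1.9, 2.5, 4.4, 7.0)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, x[1:3]), class = "strokecbv_input_error")
  expect_error(pearson_r(rep(1, 5), x), class = "strokecbv_input_error")
})

test_that("point-biserial r equals the signed sqrt(SSB/SST) closed form", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    g <- c(0, 1, sample(0:1, n - 2, replace = TRUE))   # both groups present
    y <- rnorm(n, mean = 2 * g)
    r_pkg <- pearson_r(g, y)$r
    m1 <- mean(y[g == 1]); m0 <- mean(y[g == 0]); ybar <- mean(y)
    ssb <- sum(g == 1) * (m1 - ybar)^2 + sum(g == 0) * (m0 - ybar)^2
    sst <- sum((y - ybar)^2)
    expect_equal(r_pkg, sign(m1 - m0) * sqrt(ssb / sst), tolerance = 1e-12)
  }
})

test_that("screening keeps marginally correlated predictors in candidate order", {
  set.seed(3)
  d <- tibble::tibble(y = rnorm(30))
  d$self <- d$y
  d$noise <- rnorm(30)
  sc <- screen_predictors(d, "y", c("self", "noise"))
  expect_equal(sc$predictor, c("self", "noise"))
  expect_true(sc$included[sc$predictor == "self"])
  expect_lt(sc$p_value[1], 1e-12)
  expect_error(screen_predictors(d, "y", "absent"), class = "strokecbv_input_error")
  d$flat <- 1
  expect_warning(sc2 <- screen_predictors(d, "y", c("self", "flat")),
                 "constant")
  expect_false(sc2$included[sc2$predictor == "flat"])
})

test_that("screening type-I rate for a pure-noise predictor is about alpha", {
  set.seed(101)
  hits <- replicate(1000, {
    d <- tibble::tibble(y = rnorm(28), x = rnorm(28))
    screen_predictors(d, "y", "x", alpha = 0.10)$included
  })
  expect_lt(abs(mean(hits) - 0.10), 3 * sqrt(0.1 * 0.9 / 1000))
})

test_that("default-cohort screening keeps occlusion and duration, drops weight", {
  keep <- sapply(1:50, function(s) {
    coh <- generate_cohort(cohort_config(), seed = s)
    coh$acha_occluded <- as.numeric(coh$acha_occluded)
    sc <- screen_predictors(coh, "infarct_volume_total",
                            c("acha_occluded", "duration_h", "weight_g"))
    sc$included
  })
  expect_equal(mean(keep[1, ]), 1)        # AChAo always screened in
  expect_equal(mean(keep[2, ]), 1)        # duration always screened in
  expect_gte(mean(!keep[3, ]), 0.7)       # weight is noise; usually screened out
})

test_that("a single-predictor standardized slope equals the Pearson r", {
  set.seed(15)
  d <- tibble::tibble(x = rnorm(20), y = rnorm(20, 0.5))
  fit <- fit_infarct_model(d, "y", "x")
  expect_equal(fit$coefficients$beta, pearson_r(d$x, d$y)$r, tolerance = 1e-12)
  expect_equal(fit$r_squared, pearson_r(d$x, d$y)$r^2, tolerance = 1e-12)
})

test_that("orthogonal standardized predictors recover their marginal correlations", {
  n <- 16
  x1 <- scale(sin(1:n))[, 1]
  x2_raw <- cos(2 * (1:n))
  x2_raw <- x2_raw - sum(x2_raw * x1) / sum(x1^2) * x1   # orthogonalize
  x2 <- scale(x2_raw)[, 1]
  expect_lt(abs(sum(x1 * x2)), 1e-10)
  y <- 2 * x1 - x2 + scale(rnorm(n))[, 1] * 0.3
  d <- tibble::tibble(x1 = x1, x2 = x2, y = y)
  fit <- fit_infarct_model(d, "y", c("x1", "x2"))
  b <- fit$coefficients$beta
  expect_equal(b[1], pearson_r(x1, y)$r, tolerance = 1e-10)
  expect_equal(b[2], pearson_r(x2, y)$r, tolerance = 1e-10)
  r2 <- fit$r_squared
  expect_equal(fit$adj_r_squared, 1 - (1 - r2) * (n - 1) / (n - 2 - 1),
               tolerance = 1e-12)
  expect_lte(fit$adj_r_squared, fit$r_squared)
})

test_that("standardized coefficients match a normal-equations oracle", {
  set.seed(29)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% rnorm(p) + rnorm(n)
    d <- tibble::as_tibble(as.data.frame(X))
    names(d) <- paste0("x", seq_len(p))
    d$y <- as.numeric(y)
    fit <- fit_infarct_model(d, "y", names(d)[seq_len(p)])
    Z <- scale(X); zy <- scale(d$y)[, 1]
    beta_oracle <- solve(crossprod(Z), crossprod(Z, zy))[, 1]
    expect_equal(fit$coefficients$beta, unname(beta_oracle), tolerance = 1e-10)
  }
})

test_that("degenerate designs raise collinearity errors", {
  d <- tibble::tibble(y = rnorm(10), a = rnorm(10))
  d$b <- d$a * 2
  expect_error(fit_infarct_model(d, "y", c("a", "b")),
               class = "strokecbv_collinearity_error")
  d$flat <- 3
  expect_error(fit_infarct_model(d, "y", "flat"),
               class = "strokecbv_collinearity_error")
  expect_error(fit_infarct_model(d[1:3, ], "y", c("a", "b")),
               class = "strokecbv_input_error")
})

test_that("group comparisons apply the small-cell rule and fixed ordering", {
  coh <- generate_cohort(cohort_config(), seed = 1)
  cmp <- run_group_comparisons(coh)
  expect_equal(cmp$group, c("1h", "2h", "permanent", "pooled"))
  expect_false(cmp$analyzed[cmp$group == "1h"])    # AChAo cell of 2
  expect_false(cmp$analyzed[cmp$group == "2h"])    # AChAo cell of 1
  expect_match(cmp$note[1], "not analyzed")
  expect_true(cmp$analyzed[cmp$group == "permanent"])
  expect_true(cmp$analyzed[cmp$group == "pooled"])
  expect_true(all(cmp$p_value[cmp$analyzed] >= 0 & cmp$p_value[cmp$analyzed] <= 1))

  one <- coh[coh$group == "permanent", ]
  cmp1 <- run_group_comparisons(one)
  expect_equal(cmp1$group, c("permanent", "pooled"))
})
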