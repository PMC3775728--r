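#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into the omnibus
#' statistic K^2 = Z(skew)^2 + Z(kurt)^2, referred to a chi-squared
#' distribution with 2 df. Z(skew) uses D'Agostino's (1970)
#' Johnson-SU transformation of g1; Z(kurt) uses the Anscombe-Glynn (1983)
#' cube-root transformation of g2. Moments use n denominators (population
#' form), the convention of the standard implementations.
#'
#' @param x Numeric sample, n >= 8, non-constant.
#' @return List with `k2`, `p_value`, `z_skew`, `z_kurt`, `n`.
#' @examples
#' dagostino_pearson(qnorm((1:30 - 0.5) / 30))
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8)
    abort("D'Agostino-Pearson test needs n >= 8.", class = "strokecbv_input_error")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    abort("sample has zero variance.", class = "strokecbv_input_error")
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino 1970
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn 1983
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(k2 = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] returning a flat result; the pooled
#' (Student) variant is the default, Welch is available.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    abort("each sample needs n >= 2.", class = "strokecbv_input_error")
  ht <- stats::t.test(a, b, var.equal = variant == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Two-sample t-test from summary statistics
#'
#' Closed-form t from (n, mean, SD) per group, for comparisons against
#' published group summaries.
#'
#' @param n1,mean1,sd1 First group summaries.
#' @param n2,mean2,sd2 Second group summaries.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p_value`.
#' @examples
#' two_sample_t_summary(6, 42.7, 27.62, 7, 144.5, 11.72)
#' @export
two_sample_t_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                 variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2)
    abort("each group needs n >= 2.", class = "strokecbv_input_error")
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation via [stats::cor.test()]; with a binary variable
#' this is the point-biserial correlation.
#'
#' @param x,y Equal-length numeric samples, n >= 3, non-constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    abort("x and y must have equal length.", class = "strokecbv_input_error")
  if (length(x) < 3)
    abort("Pearson correlation needs n >= 3.", class = "strokecbv_input_error")
  if (sd(x) == 0 || sd(y) == 0)
    abort("zero-variance input.", class = "strokecbv_input_error")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Screen candidate predictors by marginal Pearson correlation
#'
#' Computes each candidate's marginal correlation with the response and keeps
#' those with p below `alpha` (0.10 here, the liberal screening level feeding
#' the multiple regression). Constant candidates are dropped with a warning
#' rather than an error, so degenerate cohorts (e.g. no occluded animals)
#' flow through.
#'
#' @param data Data frame with the response and candidate columns.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha Screening level.
#' @return Tibble: `predictor`, `r`, `p_value`, `included` (candidate order
#'   preserved; dropped constants have `NA` r and `included = FALSE`).
#' @export
screen_predictors <- function(data, response, candidates, alpha = 0.10) {
  for (col in c(response, candidates))
    if (!col %in% names(data))
      abort(sprintf("column `%s` not found.", col), class = "strokecbv_input_error")
  y <- data[[response]]
  rows <- purrr::map(candidates, function(col) {
    x <- as.numeric(data[[col]])
    if (sd(x) == 0) {
      warn(sprintf("predictor `%s` is constant; dropped from screening.", col))
      return(tibble::tibble(predictor = col, r = NA_real_, p_value = NA_real_,
                            included = FALSE))
    }
    ct <- pearson_r(x, y)
    tibble::tibble(predictor = col, r = ct$r, p_value = ct$p_value,
                   included = ct$p_value < alpha)
  })
  dplyr::bind_rows(rows)
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of the response on the predictors after z-scoring
#' every variable (sample SD, n-1 denominator), so the slopes are the
#' standardized coefficients (beta) whose magnitudes are comparable across
#' predictors; t-based p-values and the adjusted r^2 come from the same fit
#' (identical to the raw-scale fit's). With a single predictor the beta
#' equals the Pearson correlation exactly.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns (non-constant;
#'   design must be full rank).
#' @return An `infarct_lm` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' fit <- fit_infarct_model(cohort, "infarct_volume_total",
#'                          c("acha_occluded", "duration_h"))
#' tidy(fit)
#' @export
fit_infarct_model <- function(data, response, predictors) {
  for (col in c(response, predictors))
    if (!col %in% names(data))
      abort(sprintf("column `%s` not found.", col), class = "strokecbv_input_error")
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1)
    abort("need n > number of predictors + 1.", class = "strokecbv_input_error")
  z <- function(v) {
    v <- as.numeric(v)
    if (sd(v) == 0)
      abort("constant column in the design.", class = "strokecbv_collinearity_error")
    (v - mean(v)) / sd(v)
  }
  zd <- as.data.frame(lapply(data[c(response, predictors)], z))
  names(zd) <- c(".y", predictors)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- lm(fml, data = zd)
  if (fit$rank < p + 1)
    abort("rank-deficient design (collinear predictors).",
          class = "strokecbv_collinearity_error")
  sm <- summary(fit)
  coefs <- sm$coefficients[predictors, , drop = FALSE]

  # raw-scale coefficients recovered from the standardized fit
  sd_y <- sd(as.numeric(data[[response]]))
  sd_x <- vapply(data[predictors], function(v) sd(as.numeric(v)), numeric(1))
  structure(list(
    fit = fit,
    coefficients = tibble::tibble(
      term = predictors,
      beta = unname(coefs[, "Estimate"]),
      estimate_raw = unname(coefs[, "Estimate"]) * sd_y / sd_x,
      statistic = unname(coefs[, "t value"]),
      p_value = unname(coefs[, "Pr(>|t|)"])),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = n, response = response, predictors = predictors),
    class = "infarct_lm")
}

#' @export
print.infarct_lm <- function(x, ...) {
  cat(sprintf("<infarct_lm> %s ~ %s (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  print(x$coefficients)
  cat(sprintf("r^2 = %.3f, adjusted r^2 = %.3f\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Per-group and pooled AChAo group comparisons
#'
#' Summarizes infarct volume by occlusion-duration group and AChAo status and
#' runs AChAo-vs-patent two-sample comparisons per group plus pooled across
#' groups, in the fixed order 1 h, 2 h, permanent, pooled. Comparisons whose
#' smaller cell has fewer than 3 animals are reported but not tested
#' (`analyzed = FALSE`) — too few animals support no within-group inference.
#' Normality is gated with the D'Agostino-Pearson test, by default on each
#' group's combined volumes (`normality = "group"`; the omnibus test is
#' undefined below n = 8, which per-cell testing rarely reaches at these
#' group sizes); `normality = "cell"` tests each cell where possible.
#' Non-normal (or untestable) comparisons keep their t-test but carry
#' `normality_ok = FALSE`/`NA` flags rather than a silent fallback.
#' No multiple-testing correction is applied.
#'
#' @param data Cohort tibble with `group`, `acha_occluded` and the volume
#'   column.
#' @param volume_col Volume column to compare.
#' @param variant t-test variant, `"pooled"` (Student) or `"welch"`.
#' @param normality `"group"` or `"cell"`.
#' @param alpha Significance level recorded in the `significant` column.
#' @return Tibble with one row per comparison: group sizes, means, SDs,
#'   normality p/flag, `analyzed`, `t`, `df`, `p_value`, `significant`,
#'   `note`.
#' @export
run_group_comparisons <- function(data, volume_col = "infarct_volume_total",
                                  variant = c("pooled", "welch"),
                                  normality = c("group", "cell"),
                                  alpha = 0.05) {
  variant <- match.arg(variant)
  normality <- match.arg(normality)
  for (col in c("group", "acha_occluded", volume_col))
    if (!col %in% names(data))
      abort(sprintf("column `%s` not found.", col), class = "strokecbv_input_error")

  groups_present <- intersect(c("1h", "2h", "permanent"), unique(data$group))
  blocks <- c(as.list(groups_present), list("pooled"))

  rows <- purrr::map(blocks, function(g) {
    d <- if (identical(g, "pooled")) data else data[data$group == g, ]
    v1 <- d[[volume_col]][d$acha_occluded]
    v0 <- d[[volume_col]][!d$acha_occluded]
    row <- tibble::tibble(
      group = if (identical(g, "pooled")) "pooled" else g,
      n_achao = length(v1), n_patent = length(v0),
      mean_achao = if (length(v1)) mean(v1) else NA_real_,
      sd_achao = if (length(v1) > 1) sd(v1) else NA_real_,
      mean_patent = if (length(v0)) mean(v0) else NA_real_,
      sd_patent = if (length(v0) > 1) sd(v0) else NA_real_)

    norm_p <- NA_real_
    norm_ok <- NA
    try_dp <- function(x) if (length(x) >= 8 && sd(x) > 0)
      dagostino_pearson(x)$p_value else NA_real_
    if (normality == "group") {
      norm_p <- try_dp(d[[volume_col]])
      norm_ok <- if (is.na(norm_p)) NA else norm_p > 0.05
    } else {
      p1 <- try_dp(v1); p0 <- try_dp(v0)
      norm_p <- suppressWarnings(min(p1, p0))
      norm_ok <- if (is.na(p1) || is.na(p0)) NA else p1 > 0.05 && p0 > 0.05
    }
    row$normality_p <- norm_p
    row$normality_ok <- norm_ok

    if (min(length(v1), length(v0)) < 3) {
      row$analyzed <- FALSE
      row$t <- NA_real_; row$df <- NA_real_; row$p_value <- NA_real_
      row$significant <- NA
      row$note <- "not analyzed: fewer than 3 animals in a cell"
    } else {
      tt <- two_sample_t(v1, v0, variant)
      row$analyzed <- TRUE
      row$t <- tt$t; row$df <- tt$df; row$p_value <- tt$p_value
      row$significant <- tt$p_value < alpha
      row$note <- if (isFALSE(norm_ok)) "flag: normality test failed" else ""
    }
    row
  })
  dplyr::bind_rows(rows)
}
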