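#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a standardized regression fit
#'
#' @param x An `infarct_lm` from [fit_infarct_model()].
#' @param ... Unused.
#' @return Tibble with one row per predictor: `term`, `beta` (standardized
#'   coefficient), `estimate_raw`, `statistic`, `p_value`.
#' @method tidy infarct_lm
#' @export
tidy.infarct_lm <- function(x, ...) x$coefficients

#' One-row model summary of a standardized regression fit
#'
#' @param x An `infarct_lm`.
#' @param ... Unused.
#' @return Tibble with `r_squared`, `adj_r_squared`, `n`, `n_predictors`.
#' @method glance infarct_lm
#' @export
glance.infarct_lm <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 n = x$n, n_predictors = length(x$predictors))
}
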