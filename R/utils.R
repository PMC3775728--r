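#' @importFrom rlang abort warn hash
#' @importFrom stats rnorm runif sd pchisq pt qt cor lm coef
NULL

# Deterministic 31-bit substream seed from (seed, ...) labels.
# MINSTD-style byte chaining: multiplier small enough that every product
# stays below 2^53, so the arithmetic is exact in doubles.
substream_seed <- function(seed, ...) {
  key <- paste(seed, ..., sep = "\r")
  m <- 2147483647
  h <- seed %% m
  for (b in utf8ToInt(key)) h <- (h * 48271 + b) %% m
  as.integer(h)
}

# Normal draws left-truncated at 0 (rejection sampling; exact for any
# mean/sd and deterministic under the current RNG state).
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(n, 16L), mean, sd)
    out <- c(out, x[x >= 0])
  }
  out[seq_len(n)]
}

# Largest-remainder apportionment of `total` integer units over weights.
apportion <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name), class = "strokecbv_parameter_error")
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0.", name), class = "strokecbv_parameter_error")
  invisible(x)
}
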