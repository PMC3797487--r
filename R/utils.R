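# Internal helpers shared across the pipeline.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the count reconstruction in
#' [confusion_from_summary()] needs conventional half-up rounding so that,
#' e.g., 8.5 species become 9 species.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Deterministic per-stage seed derived from a master seed and a stage tag.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  all(x %in% c(0, 1))
}

# Student-t 95% confidence interval for a vector of replicate values.
# With the "normal" method a +/- 1.96 * sd interval is used instead.
replicate_ci <- function(x, level = 0.95, method = c("t", "normal")) {
  method <- match.arg(method)
  m <- mean(x)
  if (length(x) < 2L || stats::sd(x) == 0) {
    return(c(lo = m, hi = m))
  }
  if (method == "t") {
    q <- stats::qt(1 - (1 - level) / 2, df = length(x) - 1L)
    half <- q * stats::sd(x) / sqrt(length(x))
  } else {
    q <- stats::qnorm(1 - (1 - level) / 2)
    half <- q * stats::sd(x)
  }
  c(lo = m - half, hi = m + half)
}
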