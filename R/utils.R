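# internal helpers shared across modules

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, min = -Inf, max = Inf,
                          open_min = FALSE, open_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_min) x > min else x >= min) &&
    (if (open_max) x < max else x <= max)
  if (!ok)
    stop_fmt("'%s' must be a single finite number in %s%s, %s%s", name,
             if (open_min) "(" else "[", format(min), format(max),
             if (open_max) ")" else "]")
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < min || x != round(x))
    stop_fmt("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# unbiased per-row variance of a numeric matrix
row_vars <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2L) stop_fmt("row variances need at least 2 columns")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# deterministic child seed, kept inside 32-bit integer range
derive_seed <- function(seed, stream) {
  (as.integer(seed) + as.integer(stream) * 104729L) %% 2147483647L
}
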