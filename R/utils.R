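## internal helpers: argument checking and seeded evaluation

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards; with `seed = NULL` the
#' expression runs on the current RNG stream.
#' @noRd
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single non-missing number", call. = FALSE)
  }
  if (!allow_inf && !is.finite(x)) {
    stop("`", name, "` must be finite", call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) stop("`", name, "` must be > ", lower, call. = FALSE)
  } else if (x < lower) {
    stop("`", name, "` must be >= ", lower, call. = FALSE)
  }
  if (x > upper) stop("`", name, "` must be <= ", upper, call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_num(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop("`", name, "` must be a whole number", call. = FALSE)
  }
  invisible(as.integer(x))
}
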