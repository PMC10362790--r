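# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic entry points route through this
# so that seeded calls are reproducible regardless of ambient RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a finite numeric scalar")
  }
  if (strict_lower && x <= lower) stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower) stop_field(field, sprintf("must be >= %g", lower))
  if (strict_upper && x >= upper) stop_field(field, sprintf("must be < %g", upper))
  if (!strict_upper && x > upper) stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

# Robust scale estimate used by the Hampel identifier and the anomalous
# cycle rule: 1.4826 * median absolute deviation.
robust_sigma <- function(x) 1.4826 * stats::median(abs(x - stats::median(x)))
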