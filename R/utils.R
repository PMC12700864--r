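#' @keywords internal
"_PACKAGE"

# clip into [0, 1], preserving dims
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# argument checks that name the offending argument
stop_arg <- function(...) stop(..., call. = FALSE)

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_arg(sprintf("`%s` must be a single probability in [0, 1], got %s",
                     name, format(p)))
  invisible(p)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop_arg(sprintf("`%s` must be non-negative", name))
  invisible(x)
}

check_count <- function(n, name, min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min || n != round(n))
    stop_arg(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(n))
}

# Run an expression under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# derive a per-stage seed from a global one, kept within 32-bit range
# (double arithmetic: the product can exceed integer range before the modulus)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
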