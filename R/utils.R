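#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Polynomial rolling hash of a non-negative integer vector, modulo a Mersenne
## prime. All arithmetic stays below 2^53 so plain doubles are exact.
HASH_MOD <- 2147483647  # 2^31 - 1

hash_ints <- function(x) {
  h <- 5381
  for (v in x) {
    h <- (h * 33 + (v %% HASH_MOD)) %% HASH_MOD
  }
  h
}

## Evaluate expr with a private RNG state: the caller's .Random.seed is
## untouched, so nothing in the package leaks randomness into the session.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  as.integer(hash_ints(c(as.integer(seed) %% HASH_MOD, 7919, stream)))
}

msg_log <- function(...) {
  message("[molgsl] ", ...)
}

stop_input <- function(...) stop(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1) {
    stop_input(sprintf("`%s` must be a single number in [0, 1], got %s",
                       name, deparse(x)))
  }
  invisible(x)
}
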