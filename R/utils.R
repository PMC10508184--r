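# Internal helpers shared across modules.

# Round half away from zero (for non-negative x this is floor(x + 0.5)).
# Used for referral set sizes and generator counts so that e.g.
# round(0.25 * 10) -> 3, independently of R's round-half-even rule.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
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
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be numeric within [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_binary <- function(x, name) {
  if (length(x) == 0L || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0/1 values", name), call. = FALSE)
  }
  invisible(x)
}
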