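#' @keywords internal
"_PACKAGE"

# Input checking helpers used across the package. Errors always name the
# offending argument so that configuration mistakes surface early.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single number")
  ok <- (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop_field(field, sprintf(
      "must lie in %s%g, %g%s", if (open_lo) "(" else "[", lo, hi,
      if (open_hi) ")" else "]"))
  }
  as.numeric(x)
}

#' Restore a reproducible RNG state for a generator call
#'
#' All generators are pure functions of their configuration and seed: the
#' global RNG state is saved, replaced by a seeded Mersenne-Twister stream,
#' and restored on exit.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sub-seed derivation: keeps independent streams for independent stages while
# remaining a deterministic function of the master seed. Kept < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
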