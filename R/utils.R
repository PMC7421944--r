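# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded generators leave the caller's
#' RNG stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_config(field, sprintf("must be a number in %s%g, %g%s",
                               if (lo_open) "(" else "[", lo, hi,
                               if (hi_open) ")" else "]"))
  }
  x
}

check_count <- function(x, field, min = 1) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
  if (!ok) stop_config(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

# p-value floor keeping -log10(p) finite (matches the summary-stat convention)
P_FLOOR <- 1e-300

floor_p <- function(p) pmax(p, P_FLOOR)

# two-sided p from z, floored
p_from_z <- function(z) floor_p(2 * stats::pnorm(-abs(z)))
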