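#' @keywords internal
"_PACKAGE"

## Run an expression under a temporary RNG state so generators are pure
## functions of (arguments, seed) and never disturb the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_param <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_param(name, " must be positive and finite")
  invisible(x)
}

## Interpolated (type-7) quantile, the convention used throughout for
## winsorisation caps and bootstrap percentiles.
quantile7 <- function(x, p) stats::quantile(x, probs = p, type = 7, names = FALSE)
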