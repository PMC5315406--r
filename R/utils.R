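#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# serialise a double so that as.numeric() recovers the identical bit pattern
fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

abort_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# seeded evaluation that restores the caller's RNG state afterwards
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  force(expr)
}
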