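#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rexp setNames
#' @importFrom utils head tail
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic operations in this package funnel through here so that a
# (arguments, seed) pair fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x)
  is.numeric(x) && length(x) == 1L && !is.na(x)
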