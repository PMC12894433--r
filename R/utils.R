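# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) stopf("%s must be a numeric matrix", what)
  if (any(!is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}
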