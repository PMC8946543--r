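#' @importFrom rlang abort warn .data
#' @importFrom stats cor dnorm median quantile rnorm runif sd shapiro.test wilcox.test
#' @importFrom utils modifyList
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a global seed; keeps results < 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483647L
}

# Clip to the 8-bit range and round to whole intensity units.
clip8 <- function(x) {
  round(pmin(pmax(x, 0), 255)) # x first so dim attributes survive
}

`%||%` <- function(a, b) if (is.null(a)) b else a
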