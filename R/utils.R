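#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state so
#' that seeded package functions do not disturb the caller's random stream.
#' A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Derive a decorrelated integer sub-seed from a master seed and a stream
# index, kept well below 2^31.
subSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 100000L * 10007 + stream * 7919 + 13) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample variance (n - 1 denominator); the package-wide convention.
sampleVar <- function(x) stats::var(x)

# Check that a value is a single finite number.
isScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
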