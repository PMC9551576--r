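#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive per-stage seeds from one run seed
#'
#' Deterministic fan-out so every pipeline stage gets an independent stream
#' while the whole run is replayable from a single integer.
#'
#' @param seed run seed (integer).
#' @param n number of stage seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Round-trip a numeric vector through 32-bit float storage
#'
#' Emulates storing intermediate tensors in single precision: each value is
#' written as a 4-byte IEEE float and read back as a double.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with float32-representable values.
#' @export
quantize_float32 <- function(x) {
  v <- readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4L),
               what = "numeric", size = 4L, n = length(x))
  if (is.matrix(x) || is.array(x)) {
    dim(v) <- dim(x)
    dimnames(v) <- dimnames(x)
  }
  v
}

# stopifnot-style check with a formatted message
check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
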