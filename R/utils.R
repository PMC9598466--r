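#' @useDynLib noseguard, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft pt pnorm integrate median sd var quantile setNames
#' @importFrom utils read.delim write.table
#' @importFrom tools file_ext
NULL

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. seed = NULL runs expr with the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what = "values") {
  if (!all(is.finite(x))) stop("non-finite ", what)
  invisible(x)
}
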