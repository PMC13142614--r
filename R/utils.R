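#' @useDynLib msom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test cmdscale dist hclust cutree fft mvfft
#'   median p.adjust pt qt quantile rnorm runif sd setNames splinefun var
#' @importFrom utils read.table write.table head tail
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Smallest 5-smooth (2^a 3^b 5^c) integer >= n; FFT-friendly lengths.
next_fast_len <- function(n) {
  if (n <= 2) return(2L)
  best <- Inf
  p5 <- 1
  while (p5 < 2 * n) {
    p35 <- p5
    while (p35 < 2 * n) {
      p <- p35
      while (p < n) p <- p * 2
      if (p < best) best <- p
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
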