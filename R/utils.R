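#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor fft pnorm pt qnorm rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# Ordered upper-triangle pair index table for n items: (1,2),(1,3),...,(n-1,n).
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}
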