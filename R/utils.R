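#' @importFrom stats rbinom rnorm runif qnorm qchisq median pt lm cor
#'   complete.cases binom.test
#' @importFrom graphics plot abline par hist
#' @importFrom utils head read.delim write.table
NULL

# internal numerics shared across modules

# log(sum(exp(x))) without overflow; x may contain -Inf
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise logSumExp of a matrix
.colLogSumExp <- function(M) {
  m <- apply(M, 2L, max)
  m + log(colSums(exp(sweep(M, 2L, m, "-"))))
}

# derive a per-stage seed from a base seed, kept inside 32-bit integer range
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

.assertFinite <- function(x, what) {
  if (any(!is.finite(x)))
    stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
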