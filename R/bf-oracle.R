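#' Brute-force numeric-integration Bayes factor (validation oracle)
#'
#' Computes the single-SNP marginal-likelihood ratio by direct numerical
#' integration over the effect sizes and the residual variance, completely
#' independently of the closed form in \code{\link{bfSingle}}: the intercept
#' is handled by centering (the flat-prior integral over \eqn{\mu}
#' contributes the same factor to both models), the effects
#' \eqn{(a, d) = \sigma u} are integrated by tensor-product Gauss--Hermite
#' quadrature with respect to their \eqn{N(0, V)} prior, and
#' \eqn{\log \sigma^2} is integrated by composite Simpson's rule on a wide
#' fixed grid around \eqn{\log(TSS/(n-1))}. All sums are accumulated in log
#' space.
#'
#' Intended for validation at small n (<= 50); a convergence check doubles
#' the Gauss--Hermite order and errors out if the two answers disagree
#' beyond \code{convTol}.
#'
#' @inheritParams bfSingle
#' @param nGH Gauss--Hermite order per effect dimension.
#' @param nGrid number of Simpson nodes for the log-variance integral
#'   (forced odd).
#' @param halfWidth half-width of the log-variance integration window.
#' @param convTol maximal allowed absolute change in log10 BF when the
#'   quadrature order is doubled.
#' @return log10 Bayes factor.
#' @examples
#' t <- c(-1.2, 0.3, 0.5, -0.7, 1.1, 0.2, -0.4, 0.8)
#' g <- c(0, 1, 2, 0, 1, 1, 0, 2)
#' bfNumericOracle(t, g, as.numeric(g == 1), sigmaA = 0.1)
#' @export
bfNumericOracle <- function(t, g, h = NULL, sigmaA, sigmaD = sigmaA / 4,
                            nGH = 48L, nGrid = 801L, halfWidth = 16,
                            convTol = 1e-7) {
  n <- .checkBfInputs(t, g, h)
  if (n > 50L) stop("oracle is for small instances (n <= 50)")
  est1 <- .oracleOnce(t, g, h, sigmaA, sigmaD, nGH, nGrid, halfWidth)
  est2 <- .oracleOnce(t, g, h, sigmaA, sigmaD, 2L * nGH, nGrid, halfWidth)
  if (abs(est1 - est2) > convTol)
    stop(sprintf(
      "oracle quadrature not converged: GH %d -> %d moved log10 BF by %.3g",
      nGH, 2L * nGH, abs(est1 - est2)))
  est2
}

.oracleOnce <- function(t, g, h, sigmaA, sigmaD, nGH, nGrid, halfWidth) {
  n <- length(t)
  tc <- t - mean(t)
  TSS <- sum(tc^2)
  W <- cbind(g - mean(g), if (is.null(h)) NULL else h - mean(h))
  v <- c(sigmaA^2, if (is.null(h)) NULL else sigmaD^2)
  keep <- v > 0 & colSums(W^2) > 0
  if (!any(keep)) return(0)
  W <- W[, keep, drop = FALSE]
  v <- v[keep]
  d <- length(v)

  gh <- pracma::gaussHermite(nGH)
  if (d == 2L) {
    U <- as.matrix(expand.grid(sqrt(2 * v[1]) * gh$x, sqrt(2 * v[2]) * gh$x))
    lw <- as.vector(outer(log(gh$w), log(gh$w), "+")) - d / 2 * log(pi)
  } else {
    U <- matrix(sqrt(2 * v[1]) * gh$x, ncol = 1L)
    lw <- log(gh$w) - d / 2 * log(pi)
  }
  M <- crossprod(W)
  cc <- drop(crossprod(W, tc))
  # with beta = sigma * u:  Q(beta)/(2 sigma^2) = TSS/(2 sigma^2) - u'c/sigma
  #                                               + u'Mu/2
  alpha <- drop(U %*% cc)
  q <- rowSums((U %*% M) * U) / 2

  if (nGrid %% 2L == 0L) nGrid <- nGrid + 1L
  v0 <- log(TSS / (n - 1))
  vg <- seq(v0 - halfWidth, v0 + halfWidth, length.out = nGrid)
  sig <- exp(vg / 2)
  inner <- .colLogSumExp(outer(alpha, 1 / sig) + (lw - q))
  lnum <- -(n - 1) / 2 * vg + inner - TSS / (2 * sig^2)
  lden <- -(n - 1) / 2 * vg - TSS / (2 * sig^2)

  (.logSimpson(lnum, vg) - .logSimpson(lden, vg)) / log(10)
}

# log of the composite-Simpson integral of exp(lf) on equispaced x
.logSimpson <- function(lf, x) {
  nn <- length(x)
  h <- x[2] - x[1]
  w <- c(1, rep(c(4, 2), (nn - 3) / 2), 4, 1) * h / 3
  m <- max(lf)
  m + log(sum(w * exp(lf - m)))
}
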