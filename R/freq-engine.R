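#' Additive-model frequentist association test
#'
#' Ordinary least-squares slope of the trait on intercept + dosage, with the
#' two-sided p-value from the exact t reference distribution on n - 2
#' degrees of freedom. No covariates enter here: they are removed during
#' normalization, before association testing. P-values are reported without
#' multiple-testing adjustment.
#'
#' @param t numeric trait vector.
#' @param g numeric dosage vector.
#' @return list with \code{beta} (effect per dosage unit), \code{se} and
#'   \code{p}; all \code{NA} (with \code{monomorphic = TRUE}) when g is
#'   constant.
#' @examples
#' set.seed(1)
#' g <- rbinom(200, 2, 0.3)
#' lmPvalue(0.2 * g + rnorm(200), g)
#' @export
lmPvalue <- function(t, g) {
  n <- length(t)
  if (n < 3L) stop("need n >= 3 observations")
  if (length(g) != n) stop("t and g must have equal length")
  res <- .lmPvalueStats(n, sum(t), sum(t^2), sum(g), sum(g^2), sum(g * t))
  list(beta = res$beta[1], se = res$se[1], p = res$p[1],
       monomorphic = is.na(res$p[1]))
}

# vectorized over SNPs from pooled sums (same sufficient statistics as the BF)
.lmPvalueStats <- function(n, st, stt, sg, sgg, sgt) {
  TSS <- stt - st^2 / n
  Cgg <- sgg - sg^2 / n
  cg <- sgt - sg * st / n
  ok <- Cgg > n * .Machine$double.eps * pmax(sgg, 1)
  beta <- ifelse(ok, cg / Cgg, NA_real_)
  RSS <- pmax(TSS - ifelse(ok, cg^2 / Cgg, 0), 0)
  se <- ifelse(ok, sqrt(RSS / (n - 2) / Cgg), NA_real_)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(beta = beta, se = se, p = ifelse(ok, p, NA_real_))
}

#' @describeIn lmPvalue fixed-effects test from pooled sufficient statistics
#'   (equals the test on the concatenated per-dataset-normalized data).
#' @param statsList list of \code{"bfSuffStats"} or one pooled object.
#' @export
lmPvalueCombined <- function(statsList) {
  s <- if (inherits(statsList, "bfSuffStats")) statsList
       else combineSufficientStats(statsList)
  .lmPvalueStats(s$n, s$st, s$stt, s$sg, s$sgg, s$sgt)
}

#' Genomic control inflation factor
#'
#' \eqn{\lambda} = median of the 1-df chi-square statistics implied by the
#' p-values, divided by the null median \code{qchisq(0.5, 1)} (about
#' 0.4549). Values near 1 indicate no systematic inflation, e.g. from
#' population stratification.
#'
#' @param pvals numeric vector of p-values in (0, 1]; NAs dropped.
#' @return numeric(1) lambda. Warns (but still computes) below 100 values.
#' @export
genomicControlLambda <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) < 100L)
    warning("fewer than 100 p-values: lambda estimate is unstable")
  median(qchisq(pvals, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Expected vs observed quantiles for a QQ plot
#'
#' @param pvals numeric vector of p-values; NAs dropped.
#' @return data.frame with sorted \code{expected} and \code{observed}
#'   -log10 p columns (expected quantiles at (i - 0.5)/N).
#' @export
qqPoints <- function(pvals) {
  pvals <- sort(pvals[!is.na(pvals)])
  if (length(pvals) == 0L) stop("no p-values supplied")
  N <- length(pvals)
  data.frame(expected = -log10(((N:1) - 0.5) / N),
             observed = -log10(rev(pvals)))
}

#' QQ plot of association p-values
#'
#' @param pvals numeric vector of p-values.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @return invisibly, the \code{\link{qqPoints}} data.frame.
#' @export
plotQQ <- function(pvals, main = "QQ plot", ...) {
  qq <- qqPoints(pvals)
  plot(qq$expected, qq$observed, pch = 20, cex = 0.5,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)), main = main, ...)
  abline(0, 1, col = "red")
  invisible(qq)
}
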