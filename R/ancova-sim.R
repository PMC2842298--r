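#' Configuration for the baseline-adjustment bias simulation
#'
#' Knobs for the demonstration that regressing the post-treatment value on
#' genotype while controlling for baseline (the ANCOVA test) yields
#' non-uniform p-values for SNPs that affect pre- and post-exposure measures
#' identically -- i.e. for SNPs that are not treatment-response associations
#' -- while the test of the difference Y - X stays calibrated.
#'
#' Defaults (n = 1000, MAF 0.3, a shared effect explaining 2\% of var(X),
#' residual correlation 0.5, 2000 replicates) make the inflation
#' unmistakable at desk scale.
#'
#' @param n individuals per replicate.
#' @param maf minor-allele frequency.
#' @param sharedVarExplained fraction of var(X) explained by the genotype's
#'   shared effect (the same effect acts on Y).
#' @param corXY residual correlation of X and Y in (-1, 1).
#' @param reps number of replicates (>= 1).
#' @param seed integer seed.
#' @return a classed list of validated settings.
#' @seealso \code{\link{simulateSharedEffect}}
#' @export
ancovaSimConfig <- function(n = 1000L, maf = 0.3, sharedVarExplained = 0.02,
                            corXY = 0.5, reps = 2000L, seed = 1L) {
  if (corXY <= -1 || corXY >= 1) stop("corXY must lie in (-1, 1)")
  if (reps < 1) stop("reps must be >= 1")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (sharedVarExplained < 0 || sharedVarExplained >= 1)
    stop("sharedVarExplained must lie in [0, 1)")
  structure(list(n = as.integer(n), maf = maf,
                 sharedVarExplained = sharedVarExplained, corXY = corXY,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "ancovaSimConfig")
}

#' Simulate p-values of the ANCOVA and difference tests under shared effects
#'
#' Per replicate: genotype g ~ Binomial(2, maf); X = beta g + e_x and
#' Y = beta g + e_y with (e_x, e_y) standard bivariate normal with
#' correlation \code{corXY} and beta sized from
#' \code{sharedVarExplained}. The ANCOVA p-value is the test of the g
#' coefficient in \code{Y ~ g + X}; the difference p-value tests g in
#' \code{(Y - X) ~ g}. Because g has identical effects on X and Y, the
#' difference test sees a true null; the ANCOVA test does not (it tests
#' conditional independence of Y and g given X, which fails whenever
#' \code{corXY < 1} and beta != 0).
#'
#' @param config an \code{\link{ancovaSimConfig}}.
#' @return list with numeric vectors \code{pAncova} and \code{pDiff} of
#'   length \code{reps}.
#' @examples
#' sim <- simulateSharedEffect(ancovaSimConfig(reps = 200, seed = 4))
#' mean(sim$pAncova < 0.05)   # inflated
#' mean(sim$pDiff < 0.05)     # ~ 0.05
#' @export
simulateSharedEffect <- function(config) {
  stopifnot(inherits(config, "ancovaSimConfig"))
  set.seed(config$seed)
  n <- config$n
  vg <- 2 * config$maf * (1 - config$maf)
  ve <- config$sharedVarExplained
  beta <- sqrt(ve / (vg * (1 - ve)))  # residual sd 1 => var(X) = 1/(1-ve)
  rho <- config$corXY
  pA <- pD <- numeric(config$reps)
  for (i in seq_len(config$reps)) {
    g <- rbinom(n, 2L, config$maf)
    ex <- rnorm(n)
    ey <- rho * ex + sqrt(1 - rho^2) * rnorm(n)
    X <- beta * g + ex
    Y <- beta * g + ey
    fitA <- summary(lm(Y ~ g + X))
    pA[i] <- fitA$coefficients["g", "Pr(>|t|)"]
    fitD <- summary(lm(I(Y - X) ~ g))
    pD[i] <- fitD$coefficients["g", "Pr(>|t|)"]
  }
  list(pAncova = pA, pDiff = pD)
}

#' Empirical rejection rates at a set of significance levels
#'
#' @param pvals numeric vector of p-values.
#' @param alphas significance levels.
#' @param level confidence level of the binomial (Wilson-free, exact
#'   \code{binom.test}) interval.
#' @return data.frame with \code{alpha}, \code{rate}, \code{lower},
#'   \code{upper}, \code{n}.
#' @export
summarizeRejections <- function(pvals, alphas = c(0.01, 0.05, 0.1),
                                level = 0.95) {
  if (!length(pvals)) stop("no p-values supplied")
  do.call(rbind, lapply(alphas, function(a) {
    k <- sum(pvals < a)
    ci <- stats::binom.test(k, length(pvals), conf.level = level)$conf.int
    data.frame(alpha = a, rate = k / length(pvals),
               lower = ci[1], upper = ci[2], n = length(pvals))
  }))
}
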