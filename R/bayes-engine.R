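#' Default prior effect-size grid and model priors
#'
#' \code{defaultSigmaGrid} returns the seven prior standard deviations of the
#' additive effect, \eqn{\sigma_a = 0.05, 0.075, 0.1, 0.125, 0.15, 0.2, 0.4}
#' (equal weight on each), over which Bayes factors are averaged; the
#' dominance-effect prior sd is \eqn{\sigma_d = \sigma_a / 4} throughout,
#' putting most weight on near-additive models.
#'
#' \code{defaultModelPriors} returns the prior probabilities of the four
#' association models in the order (H0, HS, HD, HS+D):
#' \eqn{(1 - 10^{-4},\ 0.9\times10^{-4},\ 0.01\times10^{-4},\
#' 0.09\times10^{-4})}. They place overall prior 1e-4 on any association per
#' SNP, overall prior 1e-5 on association with the difference trait D, and
#' are less skeptical of a D association when accompanied by an S
#' association.
#'
#' @return numeric vector (length 7, resp. 4).
#' @examples
#' sum(defaultModelPriors()[3:4])   # 1e-5 response prior per SNP
#' @export
defaultSigmaGrid <- function() c(0.05, 0.075, 0.1, 0.125, 0.15, 0.2, 0.4)

#' @rdname defaultSigmaGrid
#' @export
defaultModelPriors <- function() {
  c(H0 = 1 - 1e-4, HS = 0.9e-4, HD = 0.01e-4, HSD = 0.09e-4)
}

# ---- closed-form BF kernel --------------------------------------------------
# Conjugate linear model with intercept (flat prior), additive effect
# a ~ N(0, va * sigma^2) on the dosage column g, dominance effect
# d ~ N(0, vd * sigma^2) on the heterozygosity column h, residual prior
# p(sigma^2) ~ 1/sigma^2. With W the centered [g, h] design, V = diag(va, vd),
# t_c the centered trait, the Bayes factor against the intercept-only model is
#   BF = |I + V W'W|^{-1/2} (RSS_B / TSS)^{-(n-1)/2},
#   RSS_B = TSS - t_c' W (W'W + V^{-1})^{-1} W' t_c.
# Vectorized over SNPs via centered second moments; returns log10 BF.
.bfKernel <- function(n, TSS, Cgg, cg, va, vd = 0,
                      Chh = NULL, Cgh = NULL, ch = NULL) {
  if (va == 0 && vd == 0) return(rep(0, length(Cgg)))
  if (vd > 0 && !is.null(Chh)) {
    a11 <- Cgg + 1 / va
    a22 <- Chh + 1 / vd
    det <- a11 * a22 - Cgh^2
    quad <- (a22 * cg^2 - 2 * Cgh * cg * ch + a11 * ch^2) / det
    logdet <- log(det) + log(va) + log(vd)
  } else if (va > 0) {
    a11 <- Cgg + 1 / va
    quad <- cg^2 / a11
    logdet <- log1p(va * Cgg)
  } else {  # va == 0, vd > 0: dominance-only prior
    a22 <- Chh + 1 / vd
    quad <- ch^2 / a22
    logdet <- log1p(vd * Chh)
  }
  lbf <- (-0.5 * logdet - (n - 1) / 2 * (log(TSS - quad) - log(TSS))) / log(10)
  # SNPs monomorphic in the (combined) data carry no information: BF = 1
  mono <- Cgg <= 0 & (if (is.null(Chh)) TRUE else Chh <= 0)
  lbf[mono] <- 0
  lbf
}

.checkBfInputs <- function(t, g, h) {
  n <- length(t)
  if (n < 3L) stop("need n >= 3 observations")
  .assertFinite(t, "trait")
  .assertFinite(g, "dosage")
  if (!is.null(h)) {
    .assertFinite(h, "heterozygosity")
    if (length(h) != n) stop("h must match t in length")
  }
  if (length(g) != n) stop("g must match t in length")
  n
}

#' Bayes factor for one SNP at one prior scale
#'
#' Exact marginal-likelihood ratio of the single-SNP model
#' \eqn{t = \mu + a g + d h + \epsilon} against the intercept-only null,
#' under independent priors \eqn{a \sim N(0, \sigma_a^2\sigma^2)},
#' \eqn{d \sim N(0, \sigma_d^2\sigma^2)}, a flat prior on \eqn{\mu} and
#' \eqn{p(\sigma^2) \propto 1/\sigma^2} (the conjugate additive+dominance
#' prior of Bayesian single-SNP regression). Computed in closed form in log
#' space; verified against \code{\link{bfNumericOracle}}.
#'
#' When \code{h} is \code{NULL} the dominance term is dropped and the model
#' is additive-only (the honest fallback when only dosages are available:
#' posterior mean genotypes do not identify the heterozygote state).
#'
#' @param t numeric normalized trait vector.
#' @param g numeric dosage vector in [0, 2].
#' @param h numeric heterozygosity vector (probabilities in [0, 1]) or
#'   \code{NULL}.
#' @param sigmaA prior sd of the additive effect (>= 0).
#' @param sigmaD prior sd of the dominance effect; default
#'   \code{sigmaA / 4}.
#' @return log10 Bayes factor (numeric(1)).
#' @examples
#' t <- c(-1.2, 0.3, 0.5, -0.7, 1.1, 0.2, -0.4, 0.8)
#' g <- c(0, 1, 2, 0, 1, 1, 0, 2)
#' bfSingle(t, g, as.numeric(g == 1), sigmaA = 0.1)
#' @export
bfSingle <- function(t, g, h = NULL, sigmaA, sigmaD = sigmaA / 4) {
  n <- .checkBfInputs(t, g, h)
  if (sigmaA < 0 || sigmaD < 0) stop("prior sds must be >= 0")
  tc <- t - mean(t)
  gc <- g - mean(g)
  TSS <- sum(tc^2)
  if (TSS <= 0) stop("trait has zero variance")
  if (is.null(h) || sigmaD == 0) {
    .bfKernel(n, TSS, sum(gc^2), sum(gc * tc), sigmaA^2, 0)
  } else {
    hc <- h - mean(h)
    .bfKernel(n, TSS, sum(gc^2), sum(gc * tc), sigmaA^2, sigmaD^2,
              Chh = sum(hc^2), Cgh = sum(gc * hc), ch = sum(hc * tc))
  }
}

#' Bayes factor averaged over the prior effect-size grid
#'
#' The arithmetic mean (linear scale, equal weights) of the single-SNP Bayes
#' factors over a grid of \eqn{\sigma_a} values with
#' \eqn{\sigma_d = } \code{sigmaDRatio} \eqn{\times \sigma_a} at each point,
#' computed by log-sum-exp. The averaged BF always lies between the smallest
#' and largest grid BF.
#'
#' @inheritParams bfSingle
#' @param grid numeric vector of \eqn{\sigma_a} values; default
#'   \code{\link{defaultSigmaGrid}()}.
#' @param sigmaDRatio \eqn{\sigma_d / \sigma_a}; default 0.25.
#' @return log10 of the grid-averaged Bayes factor.
#' @export
bfAveraged <- function(t, g, h = NULL, grid = defaultSigmaGrid(),
                       sigmaDRatio = 0.25) {
  if (length(grid) == 0L) stop("empty sigma grid")
  l10 <- vapply(grid, function(sa) bfSingle(t, g, h, sa, sigmaDRatio * sa),
                numeric(1))
  (.logSumExp(l10 * log(10)) - log(length(l10))) / log(10)
}

# ---- sufficient statistics and fixed-effects combination --------------------

#' Per-dataset sufficient statistics for the single-SNP Bayes factor
#'
#' Returns the data summaries from which the Bayes factor (and the additive
#' frequentist test) can be reconstructed exactly: n, the sums and
#' cross-products of the trait with the columns of [1, g, h]. Statistics add
#' component-wise across datasets, which is what makes the fixed-effects
#' combined analysis (one shared effect in all studies) computable from
#' per-study summaries alone.
#'
#' @param t numeric trait vector (one dataset's normalized S or D).
#' @param g dosage vector, or a SNPs x individuals matrix for many SNPs.
#' @param h heterozygosity vector/matrix matching \code{g}, or \code{NULL}.
#' @return An object of class \code{"bfSuffStats"} (a list with elements
#'   \code{n}, \code{st}, \code{stt}, and per-SNP vectors \code{sg},
#'   \code{sgg}, \code{sgt}, and when h is supplied \code{sh}, \code{sgh},
#'   \code{shh}, \code{sht}).
#' @seealso \code{\link{bfCombined}}, \code{\link{combineSufficientStats}}
#' @export
datasetSufficientStats <- function(t, g, h = NULL) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  n <- length(t)
  if (ncol(g) != n) stop("g must have one column per individual")
  .assertFinite(t, "trait")
  out <- list(n = n, st = sum(t), stt = sum(t^2),
              sg = rowSums(g), sgg = rowSums(g^2),
              sgt = drop(g %*% t), hasH = !is.null(h), m = nrow(g))
  if (!is.null(h)) {
    if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
    if (!all(dim(h) == dim(g))) stop("h must match g in shape")
    out$sh <- rowSums(h)
    out$sgh <- rowSums(g * h)
    out$shh <- rowSums(h^2)
    out$sht <- drop(h %*% t)
  }
  class(out) <- "bfSuffStats"
  out
}

#' Pool sufficient statistics across datasets
#'
#' @param statsList list of \code{"bfSuffStats"} objects over the same SNPs.
#' @return A single pooled \code{"bfSuffStats"}.
#' @export
combineSufficientStats <- function(statsList) {
  if (length(statsList) < 1L) stop("need at least one dataset's statistics")
  stopifnot(all(vapply(statsList, inherits, logical(1), "bfSuffStats")))
  m <- unique(vapply(statsList, function(s) s$m, numeric(1)))
  hasH <- unique(vapply(statsList, function(s) s$hasH, logical(1)))
  if (length(m) != 1L || length(hasH) != 1L)
    stop("incompatible sufficient statistics (SNP count or h availability)")
  fields <- c("n", "st", "stt", "sg", "sgg", "sgt",
              if (hasH) c("sh", "sgh", "shh", "sht"))
  out <- lapply(fields, function(f) Reduce(`+`, lapply(statsList, `[[`, f)))
  names(out) <- fields
  out$hasH <- hasH
  out$m <- m
  class(out) <- "bfSuffStats"
  out
}

# centered second moments from pooled sums; returns list for the kernel
.centeredMoments <- function(s) {
  n <- s$n
  list(n = n,
       TSS = s$stt - s$st^2 / n,
       Cgg = pmax(s$sgg - s$sg^2 / n, 0),
       cg = s$sgt - s$sg * s$st / n,
       Chh = if (s$hasH) pmax(s$shh - s$sh^2 / n, 0) else NULL,
       Cgh = if (s$hasH) s$sgh - s$sg * s$sh / n else NULL,
       ch = if (s$hasH) s$sht - s$sh * s$st / n else NULL)
}

#' Fixed-effects combined Bayes factor from per-dataset statistics
#'
#' Pools the per-dataset sufficient statistics component-wise and evaluates
#' the closed-form Bayes factor on the pooled sums. Because the model assumes
#' one shared effect in all studies, this equals \code{\link{bfSingle}} run
#' on the concatenation of the (per-dataset-normalized) individuals exactly
#' -- it is not the product of per-study Bayes factors, which would encode
#' independent per-study effects.
#'
#' @param statsList list of \code{"bfSuffStats"} (one per dataset), or a
#'   single pooled \code{"bfSuffStats"}.
#' @inheritParams bfSingle
#' @return log10 Bayes factor; a vector when the statistics cover several
#'   SNPs.
#' @export
bfCombined <- function(statsList, sigmaA, sigmaD = sigmaA / 4) {
  s <- if (inherits(statsList, "bfSuffStats")) statsList
       else combineSufficientStats(statsList)
  mo <- .centeredMoments(s)
  if (s$hasH && sigmaD > 0)
    .bfKernel(mo$n, mo$TSS, mo$Cgg, mo$cg, sigmaA^2, sigmaD^2,
              Chh = mo$Chh, Cgh = mo$Cgh, ch = mo$ch)
  else
    .bfKernel(mo$n, mo$TSS, mo$Cgg, mo$cg, sigmaA^2, 0)
}

#' @describeIn bfCombined combined BF averaged over the \eqn{\sigma_a} grid.
#' @inheritParams bfAveraged
#' @export
bfCombinedAveraged <- function(statsList, grid = defaultSigmaGrid(),
                               sigmaDRatio = 0.25) {
  if (length(grid) == 0L) stop("empty sigma grid")
  s <- if (inherits(statsList, "bfSuffStats")) statsList
       else combineSufficientStats(statsList)
  L <- vapply(grid, function(sa) bfCombined(s, sa, sigmaDRatio * sa),
              numeric(s$m))
  L <- matrix(L, nrow = s$m) * log(10)
  drop(.colLogSumExp(t(L)) - log(length(grid))) / log(10)
}

# ---- model posteriors -------------------------------------------------------

#' Posterior probabilities over the four association models
#'
#' Combines the sum-trait and difference-trait Bayes factors with prior
#' model probabilities. The model Bayes factors are (1, BF_S, BF_D,
#' BF_S x BF_D) for (H0, HS, HD, HS+D) -- independence of S and D makes the
#' joint BF multiplicative -- and the posterior of model i is
#' \eqn{BF_i \pi_i / \sum_j BF_j \pi_j}, computed in log space so that
#' genome-scan BFs spanning hundreds of orders of magnitude are safe.
#'
#' @param log10bfS,log10bfD log10 Bayes factors for the sum and difference
#'   traits (scalars).
#' @param priors numeric(4) prior model probabilities summing to 1.
#' @return A \linkS4class{ModelPosterior}.
#' @examples
#' modelPosteriors(log10bfS = 6, log10bfD = 1)
#' @export
modelPosteriors <- function(log10bfS, log10bfD,
                            priors = defaultModelPriors()) {
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-9)
    stop("priors must be non-negative and sum to 1")
  lw <- c(0, log10bfS, log10bfD, log10bfS + log10bfD) * log(10) +
    log(unname(priors))
  post <- exp(lw - .logSumExp(lw))
  new("ModelPosterior", priors = unname(priors),
      posteriors = post / sum(post))
}

# vectorized posterior matrix for scans: rows = SNPs, cols = (H0,HS,HD,HSD)
.posteriorMatrix <- function(log10bfS, log10bfD,
                             priors = defaultModelPriors()) {
  lw <- cbind(0, log10bfS, log10bfD, log10bfS + log10bfD) * log(10)
  lw <- sweep(lw, 2L, log(priors), "+")
  mx <- apply(lw, 1L, max)
  w <- exp(lw - mx)
  w / rowSums(w)
}

#' Rescale a posterior for a different response-model prior
#'
#' Exact Bayes-rule sensitivity analysis: multiplying the prior weights of
#' the two treatment-response models (HD and HS+D) by a common factor and
#' renormalizing is equivalent to recomputing the posterior under the new
#' prior, without touching the data. Used to ask how conclusions move under
#' more (factor < 1) or less (factor > 1) skeptical per-SNP response priors.
#'
#' @param posterior a \linkS4class{ModelPosterior}.
#' @param responsePriorFactor positive multiplier of the HD and HS+D prior
#'   weights.
#' @return A \linkS4class{ModelPosterior} under the rescaled prior.
#' @examples
#' mp <- ModelPosterior(c(0.16, 0.005, 0.07, 0.77))
#' responseProbability(rescalePriorSensitivity(mp, 1/5))  # ~0.50
#' responseProbability(rescalePriorSensitivity(mp, 4))    # > 0.95
#' @export
rescalePriorSensitivity <- function(posterior, responsePriorFactor) {
  stopifnot(is(posterior, "ModelPosterior"))
  if (!is.finite(responsePriorFactor) || responsePriorFactor <= 0)
    stop("responsePriorFactor must be > 0")
  f <- c(1, 1, responsePriorFactor, responsePriorFactor)
  w <- posterior@posteriors * f
  pr <- posterior@priors * f
  new("ModelPosterior", priors = pr / sum(pr), posteriors = w / sum(w))
}
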