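#' Configuration for the multi-study synthetic-data generator
#'
#' Describes a set of parallel statin-trial-like studies: per-study sample
#' sizes and raw-phenotype location/scale, per-SNP base minor-allele
#' frequencies with per-study jitter, planted SNP effects expressed as the
#' fraction of variance explained on the normalized sum (S) and difference
#' (D) trait scales, covariate effects, and a deterministic imputation-noise
#' blend on dosages.
#'
#' Effect classes follow the analysis model space: \code{"null"} SNPs affect
#' neither trait, \code{"statin_independent"} SNPs affect S only, and
#' \code{"statin_response"} SNPs affect D (optionally S as well). The class
#' constrains the variance-explained vectors: \code{"null"} forces
#' \code{veS = veD = 0} and \code{"statin_independent"} forces \code{veD = 0}.
#'
#' @slot nPerStudy integer vector of per-study sample sizes.
#' @slot nSnps integer(1).
#' @slot mafBase numeric, per-SNP base MAF in (0, 0.5].
#' @slot mafJitterSd numeric(1), sd of the per-study Gaussian jitter applied
#'   to the base MAF (truncated back into [0.01, 0.5]).
#' @slot effectClass character, per-SNP label.
#' @slot veS,veD numeric, per-SNP variance explained on the normalized S and
#'   D scales.
#' @slot covEffectsS,covEffectsD numeric(4), coefficients of (log BMI, age,
#'   sex, smoking) on the latent S and D scales.
#' @slot mPre,mPost,sScale numeric per-study location (log scale) of raw
#'   pre/post phenotypes and the scale tying latent scores to log-raw values.
#' @slot imputationNoise numeric(1) in [0, 1]; dosages are the blend
#'   \code{(1 - r) * genotype + r * 2 * maf}.
#' @slot trait character(1) phenotype label.
#' @slot studyIds character vector of study labels.
#' @slot seed integer(1) master seed; all randomness derives from it.
#' @seealso \code{\link{simConfig}}, \code{\link{simulateStudy}}
#' @export
setClass("SimConfig",
  representation(nPerStudy = "integer", nSnps = "integer",
                 mafBase = "numeric", mafJitterSd = "numeric",
                 effectClass = "character", veS = "numeric", veD = "numeric",
                 covEffectsS = "numeric", covEffectsD = "numeric",
                 mPre = "numeric", mPost = "numeric", sScale = "numeric",
                 imputationNoise = "numeric", trait = "character",
                 studyIds = "character", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  K <- length(object@nPerStudy)
  if (any(object@nPerStudy < 2L)) msg <- c(msg, "nPerStudy must be >= 2")
  if (any(object@mafBase <= 0 | object@mafBase > 0.5))
    msg <- c(msg, "base MAFs must lie in (0, 0.5]")
  if (object@imputationNoise < 0 || object@imputationNoise > 1)
    msg <- c(msg, "imputationNoise must lie in [0, 1]")
  if (!all(object@effectClass %in%
           c("null", "statin_independent", "statin_response")))
    msg <- c(msg, "unknown effect class")
  if (length(object@veS) != object@nSnps || length(object@veD) != object@nSnps)
    msg <- c(msg, "veS/veD must have one entry per SNP")
  bad <- object@effectClass == "null" & (object@veS != 0 | object@veD != 0)
  if (any(bad)) msg <- c(msg, "null SNPs must have veS = veD = 0")
  bad <- object@effectClass == "statin_independent" & object@veD != 0
  if (any(bad)) msg <- c(msg, "statin_independent SNPs must have veD = 0")
  if (any(object@veS < 0) || any(object@veD < 0))
    msg <- c(msg, "variance-explained values must be >= 0")
  if (sum(object@veS) >= 1 || sum(object@veD) >= 1)
    msg <- c(msg, "variance-explained targets must sum to < 1 per trait")
  if (length(object@mPre) != K || length(object@mPost) != K ||
      length(object@sScale) != K || length(object@studyIds) != K)
    msg <- c(msg, "per-study parameter vectors must match length(nPerStudy)")
  if (length(msg)) msg else TRUE
})

#' Build a synthetic-data configuration
#'
#' Defaults emulate the three statin trials the analysis was designed around:
#' sample sizes (592, 1360, 1976) as in the CAP / PRINCE / TNT study
#' populations, log-normal raw total-cholesterol-like phenotypes with
#' per-study location and scale taken from those populations' untreated and
#' treated means, covariates loosely matched to their clinical tables
#' (age ~ N(60, 10), log-normal BMI around 28, smoking ~ Bernoulli(0.15)),
#' and a small per-study MAF jitter (sd 0.01) of the size seen across the
#' studies' per-trial MAF estimates.
#'
#' @param nPerStudy integer vector of per-study sample sizes.
#' @param nSnps number of SNPs.
#' @param mafBase per-SNP base MAF; default drawn Uniform(0.05, 0.5) from the
#'   seed.
#' @param mafJitterSd sd of per-study MAF jitter.
#' @param effectClass per-SNP class in \code{"null"},
#'   \code{"statin_independent"}, \code{"statin_response"}; recycled.
#' @param veS,veD per-SNP variance explained on the normalized S/D scale;
#'   recycled. Forced to 0 where the effect class requires it.
#' @param covEffectsS,covEffectsD coefficients of (log BMI, age, sex,
#'   smoking) on the latent traits.
#' @param mPre,mPost per-study log-scale locations of raw pre/post values.
#' @param sScale per-study scale linking latent scores to log raw values.
#' @param imputationNoise blend weight r in [0, 1] toward 2*MAF.
#' @param trait phenotype label.
#' @param studyIds study labels.
#' @param seed integer master seed.
#'
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nPerStudy = c(100, 100), nSnps = 10, seed = 7)
#' @export
simConfig <- function(nPerStudy = c(592L, 1360L, 1976L),
                      nSnps = 100L,
                      mafBase = NULL,
                      mafJitterSd = 0.01,
                      effectClass = "null",
                      veS = 0, veD = 0,
                      covEffectsS = c(0.20, 0.010, -0.10, 0.10),
                      covEffectsD = c(-0.05, 0.002, 0.05, -0.05),
                      mPre = c(5.36, 5.37, 5.50),
                      mPost = c(5.03, 5.16, 5.16),
                      sScale = c(0.16, 0.17, 0.12),
                      imputationNoise = 0,
                      trait = "tc",
                      studyIds = NULL,
                      seed = 1L) {
  K <- length(nPerStudy)
  nSnps <- as.integer(nSnps)
  seed <- as.integer(seed)
  if (is.null(mafBase)) {
    set.seed(.deriveSeed(seed, 101L))
    mafBase <- runif(nSnps, 0.05, 0.5)
  }
  mafBase <- rep_len(mafBase, nSnps)
  effectClass <- rep_len(effectClass, nSnps)
  veS <- rep_len(veS, nSnps)
  veD <- rep_len(veD, nSnps)
  veS[effectClass == "null"] <- 0
  veD[effectClass %in% c("null", "statin_independent")] <- 0
  if (is.null(studyIds)) studyIds <- paste0("study", seq_len(K))
  if (length(mPre) != K) mPre <- rep_len(mPre, K)
  if (length(mPost) != K) mPost <- rep_len(mPost, K)
  if (length(sScale) != K) sScale <- rep_len(sScale, K)
  new("SimConfig", nPerStudy = as.integer(nPerStudy), nSnps = nSnps,
      mafBase = mafBase, mafJitterSd = mafJitterSd, effectClass = effectClass,
      veS = veS, veD = veD, covEffectsS = covEffectsS,
      covEffectsD = covEffectsD, mPre = mPre, mPost = mPost, sScale = sScale,
      imputationNoise = imputationNoise, trait = trait, studyIds = studyIds,
      seed = seed)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@nPerStudy), "studies (n =",
      paste(object@nPerStudy, collapse = ", "), "),", object@nSnps, "SNPs\n")
  tab <- table(object@effectClass)
  cat("  effect classes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  imputation noise r =", object@imputationNoise,
      "; seed =", object@seed, "\n")
})

#' Simulate HWE genotype dosages for one SNP
#'
#' Hard genotypes are drawn Binomial(2, maf) under Hardy-Weinberg
#' equilibrium; the returned dosage is the deterministic blend
#' \code{(1 - r) * genotype + r * 2 * maf}, which preserves the expected
#' minor-allele count while attenuating information the way posterior mean
#' genotypes from imputation do. Heterozygote probabilities are blended the
#' same way toward the HWE expectation \code{2 * maf * (1 - maf)}, so that
#' \code{r = 0} gives the indicator of the drawn heterozygote.
#'
#' @param maf minor-allele frequency in (0, 0.5].
#' @param n number of individuals.
#' @param noise blend weight r in [0, 1].
#' @param seed optional integer seed (set before drawing when given).
#' @return list with numeric \code{dosage} and \code{hetProb} of length n.
#' @examples
#' g <- simulateGenotypes(0.24, 100, seed = 1)
#' mean(g$dosage) / 2   # close to 0.24
#' @export
simulateGenotypes <- function(maf, n, noise = 0, seed = NULL) {
  if (length(maf) != 1L || !is.finite(maf) || maf <= 0 || maf > 0.5)
    stop("maf must be a single value in (0, 0.5]")
  if (n < 1) stop("n must be >= 1")
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- rbinom(n, 2L, maf)
  list(dosage = (1 - noise) * g + noise * 2 * maf,
       hetProb = (1 - noise) * as.numeric(g == 1L) +
                 noise * 2 * maf * (1 - maf))
}

# per-study MAFs for all SNPs of a config (deterministic in the seed)
.studyMafs <- function(config, studyIndex) {
  set.seed(.deriveSeed(config@seed, 211L + studyIndex))
  maf <- config@mafBase +
    if (config@mafJitterSd > 0) rnorm(config@nSnps, 0, config@mafJitterSd)
    else 0
  pmin(pmax(maf, 0.01), 0.5)
}

#' Simulate one study of a multi-study configuration
#'
#' Generates covariates, HWE genotypes at the study's jittered MAFs, latent
#' sum and difference scores
#' \deqn{S^* = \sum_j \beta_{S,j} g_j + c_S'z + \epsilon_S, \qquad
#'       D^* = \sum_j \beta_{D,j} g_j + c_D'z + \epsilon_D,}
#' with coefficients \eqn{\beta_j = \sqrt{ve_j / (2\,maf_j(1 - maf_j))}}
#' converted from the variance-explained targets, and independent Gaussian
#' noise scaled so the latent trait has unit variance (hence each planted
#' SNP attains its target). Raw phenotypes are log-normal by construction:
#' \code{X_raw = exp(mPre + s * (S* - D*)/2)},
#' \code{Y_raw = exp(mPost + s * (S* + D*)/2)}, so the baseline X and
#' on-treatment Y measures are monotone images of the latent scores and the
#' rank-based normalization recovers them exactly.
#'
#' Deterministic given \code{config@seed} and \code{studyIndex}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param studyIndex which study to generate (1-based).
#' @return A \linkS4class{StudyDataset}.
#' @examples
#' cfg <- simConfig(nPerStudy = c(120, 150), nSnps = 8, seed = 3)
#' simulateStudy(cfg, 2)
#' @export
simulateStudy <- function(config, studyIndex) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  K <- length(config@nPerStudy)
  if (studyIndex < 1 || studyIndex > K) stop("studyIndex out of range")
  n <- config@nPerStudy[studyIndex]
  m <- config@nSnps
  maf <- .studyMafs(config, studyIndex)
  set.seed(.deriveSeed(config@seed, 7000L + studyIndex))

  # covariates loosely matched to statin-trial clinical tables
  age <- rnorm(n, 60, 10)
  bmi <- exp(rnorm(n, log(28), 0.17))
  sex <- rbinom(n, 1L, 0.7)
  smoking <- rbinom(n, 1L, 0.15)
  Z <- cbind(log(bmi), age, sex, smoking)

  # genotypes: hard draws then deterministic blend toward 2*maf
  r <- config@imputationNoise
  ghard <- matrix(rbinom(m * n, 2L, rep(maf, n)), nrow = m, ncol = n)
  dos <- (1 - r) * ghard + r * 2 * maf
  hp <- (1 - r) * (ghard == 1L) + r * 2 * maf * (1 - maf)

  # effect sizes from variance-explained targets, shared across studies
  # (fixed-effects generative model): beta in units of the base MAF
  vg <- 2 * config@mafBase * (1 - config@mafBase)
  betaS <- sqrt(config@veS / vg)
  betaD <- sqrt(config@veD / vg)

  covVar <- function(cf) {
    sum(cf^2 * c(0.17^2, 10^2, 0.7 * 0.3, 0.15 * 0.85))
  }
  sdEpsS <- sqrt(max(1 - sum(config@veS) - covVar(config@covEffectsS), 1e-8))
  sdEpsD <- sqrt(max(1 - sum(config@veD) - covVar(config@covEffectsD), 1e-8))
  covS <- drop(Z %*% config@covEffectsS)
  covD <- drop(Z %*% config@covEffectsD)
  covS <- covS - mean(covS)
  covD <- covD - mean(covD)
  Sstar <- drop(crossprod(dos, betaS)) + covS + rnorm(n, 0, sdEpsS)
  Dstar <- drop(crossprod(dos, betaD)) + covD + rnorm(n, 0, sdEpsD)

  s <- config@sScale[studyIndex]
  Xraw <- exp(config@mPre[studyIndex] + s * (Sstar - Dstar) / 2)
  Yraw <- exp(config@mPost[studyIndex] + s * (Sstar + Dstar) / 2)

  info <- data.frame(id = paste0("snp", seq_len(m)),
                     chrom = 1L, pos = seq_len(m) * 10000L,
                     allele1 = "A", allele0 = "G", maf = maf)
  StudyDataset(dosages = dos, pre = Xraw, post = Yraw,
               bmi = bmi, age = age, sex = sex, smoking = smoking,
               snpInfo = info, hetProbs = hp,
               studyId = config@studyIds[studyIndex],
               trait = config@trait)
}

#' @describeIn simulateStudy generate all studies of a configuration.
#' @export
simulateStudies <- function(config) {
  lapply(seq_along(config@nPerStudy), function(k) simulateStudy(config, k))
}
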