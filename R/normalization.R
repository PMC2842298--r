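#' Average repeated phenotype measurements
#'
#' Visit-level phenotype values (e.g. two pre-treatment and two on-treatment
#' blood draws) are collapsed to one value per individual by the arithmetic
#' mean of the non-missing visits. Individuals with no non-missing visit are
#' returned as \code{NA} (flagged missing, dropped later by
#' \code{\link{normalizeDataset}}).
#'
#' @param measurements numeric matrix, individuals x visits (a vector is
#'   treated as a single individual's visits).
#' @return numeric vector of per-individual means.
#' @examples
#' averageRepeats(rbind(c(212, 212), c(100, 110), c(150, NA)))
#' @export
averageRepeats <- function(measurements) {
  if (is.null(dim(measurements)))
    measurements <- matrix(measurements, nrow = 1L)
  out <- rowMeans(measurements, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps the value with midrank r (average ranks for ties) to the standard
#' normal quantile \eqn{\Phi^{-1}(r / (n + 1))}. The r/(n+1) offset keeps
#' the extremes finite; ties share one score; the map is order-preserving.
#' Missing values propagate as \code{NA} and do not enter the ranking.
#'
#' @param values numeric vector with at least 2 distinct non-missing values.
#' @return numeric vector of normal scores.
#' @examples
#' rankInverseNormal(c(5, 2, 9))   # 0, -0.6745, 0.6745
#' @export
rankInverseNormal <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2L) stop("need at least 2 non-missing values")
  if (length(unique(x)) < 2L)
    stop("all values identical: rank transform undefined")
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm(r / (length(x) + 1))
  out
}

#' Sum and difference reparameterization
#'
#' The bivariate (pre, post) outcome (X, Y) is recast as the sum
#' S = Y + X and the difference D = Y - X. The map is a bijection
#' (X = (S - D)/2, Y = (S + D)/2): a SNP is associated with (X, Y) if and
#' only if it is associated with (S, D), and association with D is what
#' defines a treatment-response association.
#'
#' @param X,Y numeric vectors of equal length.
#' @return list with components \code{S} and \code{D}.
#' @examples
#' sumDiff(1, 2)
#' @export
sumDiff <- function(X, Y) {
  if (length(X) != length(Y)) stop("X and Y must have equal length")
  list(S = Y + X, D = Y - X)
}

#' Remove covariate effects by least squares
#'
#' Returns the residuals of an ordinary least-squares fit of the trait on an
#' intercept plus the four covariates used throughout: log(BMI), age, sex and
#' smoking status. The residuals are orthogonal to every design column.
#'
#' @param t numeric response vector.
#' @param logBmi,age,sex,smoking covariate vectors (BMI already logged).
#' @return numeric residual vector.
#' @export
adjustCovariates <- function(t, logBmi, age, sex, smoking) {
  X <- cbind(`(Intercept)` = 1, logBmi = logBmi, age = age,
             sex = sex, smoking = smoking)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, t)
}

#' Four-step per-dataset phenotype normalization
#'
#' Produces the final sum (S) and difference (D) traits for one dataset:
#' \enumerate{
#'   \item rank-inverse-normal transform the raw pre-treatment and
#'     post-treatment values separately;
#'   \item form S = post + pre and D = post - pre from the transformed
#'     values;
#'   \item regress S and D each on log(BMI), age, sex and smoking and keep
#'     the residuals;
#'   \item rank-inverse-normal transform each residual vector again.
#' }
#' The final S and D therefore have identical marginal distributions in
#' every dataset of equal size, so differences in phenotype location/scale
#' or allele frequency between studies cannot create spurious associations
#' in a pooled analysis. Any residual correlation between S and D is
#' reported (slot \code{corSD}) rather than forced to zero. Individuals
#' missing any phenotype or covariate are dropped before step 1.
#'
#' Because every step is rank-based or linear, the output is invariant to
#' strictly increasing transformations of the raw pre (or post) values.
#'
#' @param dataset a \linkS4class{StudyDataset}.
#' @return A \linkS4class{NormalizedTraits} for the complete-case
#'   individuals.
#' @examples
#' cfg <- simConfig(nPerStudy = c(150, 150), nSnps = 4, seed = 2)
#' nt <- normalizeDataset(simulateStudy(cfg, 1))
#' nt
#' @export
normalizeDataset <- function(dataset) {
  stopifnot(is(dataset, "StudyDataset"))
  ph <- phenotypes(dataset)
  keep <- stats::complete.cases(
    ph[, c("pre", "post", "bmi", "age", "sex", "smoking")])
  ph <- ph[keep, , drop = FALSE]
  if (nrow(ph) < 3L)
    stop("fewer than 3 complete-case individuals in dataset '",
         studyId(dataset), "'")
  x <- rankInverseNormal(ph$pre)
  y <- rankInverseNormal(ph$post)
  sd1 <- sumDiff(x, y)
  sRes <- adjustCovariates(sd1$S, log(ph$bmi), ph$age, ph$sex, ph$smoking)
  dRes <- adjustCovariates(sd1$D, log(ph$bmi), ph$age, ph$sex, ph$smoking)
  S <- rankInverseNormal(sRes)
  D <- rankInverseNormal(dRes)
  new("NormalizedTraits", S = S, D = D, sampleIds = rownames(ph),
      datasetId = studyId(dataset), trait = traitName(dataset),
      corSD = stats::cor(S, D))
}
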