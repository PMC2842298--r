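#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData
NULL

#' Container for one study's genotype dosages and raw phenotypes
#'
#' A \code{StudyDataset} holds everything the analysis needs from one study
#' (or one study x genotyping-stage block, the unit within which phenotypes
#' are normalized): a SNP x individual matrix of posterior mean genotype
#' dosages in [0, 2], an optional matrix of heterozygote probabilities,
#' per-SNP metadata (id, chromosome, position, alleles) in \code{rowData},
#' and per-individual raw pre-/post-treatment phenotype values plus the
#' covariates used for adjustment (BMI, age, sex, smoking) in \code{colData}.
#'
#' The class extends \linkS4class{SummarizedExperiment}; rows are SNPs and
#' columns are individuals. The assay \code{"dosage"} is required; the assay
#' \code{"hetProb"} is optional (when absent, downstream Bayes factors fall
#' back to an additive-only model).
#'
#' @slot trait character(1), the lipid trait the phenotype columns refer to
#'   (e.g. \code{"tc"}, \code{"ldlc"}, \code{"hdlc"}, \code{"tg"}).
#'
#' @seealso \code{\link{StudyDataset}} (constructor),
#'   \code{\link{simulateStudy}}, \code{\link{normalizeDataset}}
#' @export
setClass("StudyDataset",
  contains = "SummarizedExperiment",
  representation(trait = "character"))

setValidity("StudyDataset", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    dos <- assay(object, "dosage")
    if (any(!is.na(dos) & (dos < 0 | dos > 2)))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  if ("hetProb" %in% assayNames(object)) {
    hp <- assay(object, "hetProb")
    if (any(!is.na(hp) & (hp < 0 | hp > 1)))
      msg <- c(msg, "heterozygote probabilities must lie in [0, 1]")
  }
  cd <- colData(object)
  need <- c("pre", "post", "bmi", "age", "sex", "smoking")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (all(c("pre", "post") %in% colnames(cd))) {
    if (any(!is.na(cd$pre) & cd$pre <= 0) || any(!is.na(cd$post) & cd$post <= 0))
      msg <- c(msg, "raw pre/post phenotype values must be strictly positive")
  }
  if (length(object@trait) != 1L)
    msg <- c(msg, "trait must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a StudyDataset
#'
#' @param dosages numeric matrix, SNPs x individuals, values in [0, 2]
#'   (posterior mean minor-allele counts).
#' @param pre,post strictly positive numeric vectors of raw pre-treatment and
#'   post-treatment phenotype values, one per individual.
#' @param bmi,age numeric covariate vectors (kg/m^2 and years).
#' @param sex,smoking 0/1 covariate vectors.
#' @param snpInfo data.frame (or DataFrame) of per-SNP metadata with columns
#'   \code{id}, \code{chrom}, \code{pos}, \code{allele1} (minor),
#'   \code{allele0} (major); defaults to synthetic ids.
#' @param hetProbs optional matrix of P(heterozygote), same shape as
#'   \code{dosages}.
#' @param studyId character(1) label for the dataset (normalization unit).
#' @param trait character(1) phenotype label.
#' @param sampleIds optional individual ids (column names).
#'
#' @return A \linkS4class{StudyDataset}.
#' @examples
#' cfg <- simConfig(nPerStudy = c(80, 80), nSnps = 5, seed = 1)
#' sd1 <- simulateStudy(cfg, 1)
#' sd1
#' @export
StudyDataset <- function(dosages, pre, post, bmi, age, sex, smoking,
                         snpInfo = NULL, hetProbs = NULL,
                         studyId = "study1", trait = "tc",
                         sampleIds = NULL) {
  dosages <- as.matrix(dosages)
  m <- nrow(dosages)
  if (is.null(snpInfo))
    snpInfo <- data.frame(id = paste0("snp", seq_len(m)), chrom = 1L,
                          pos = seq_len(m), allele1 = "A", allele0 = "G")
  if (anyDuplicated(snpInfo$id))
    stop("duplicate SNP id(s): ",
         paste(unique(snpInfo$id[duplicated(snpInfo$id)]), collapse = ", "))
  if (is.null(sampleIds))
    sampleIds <- paste0(studyId, "_", seq_len(ncol(dosages)))
  rownames(dosages) <- snpInfo$id
  colnames(dosages) <- sampleIds
  asy <- list(dosage = dosages)
  if (!is.null(hetProbs)) {
    hetProbs <- as.matrix(hetProbs)
    dimnames(hetProbs) <- dimnames(dosages)
    asy$hetProb <- hetProbs
  }
  cd <- DataFrame(pre = pre, post = post, bmi = bmi, age = age,
                  sex = sex, smoking = smoking, row.names = sampleIds)
  se <- SummarizedExperiment(assays = asy, rowData = DataFrame(snpInfo),
                             colData = cd)
  metadata(se)$studyId <- studyId
  new("StudyDataset", se, trait = trait)
}

#' Final normalized sum and difference traits for one dataset
#'
#' Holds, for the individuals of a single dataset, the sum (S) and difference
#' (D) scores produced by the four-step normalization pipeline, together with
#' the residual correlation between them (reported, not forced to zero).
#'
#' @slot S,D numeric vectors of standard-normal scores, one per individual.
#' @slot sampleIds character vector of individual ids.
#' @slot datasetId character(1).
#' @slot trait character(1).
#' @slot corSD numeric(1), the empirical correlation of S and D after the
#'   final rank transform.
#' @seealso \code{\link{normalizeDataset}}
#' @export
setClass("NormalizedTraits",
  representation(S = "numeric", D = "numeric", sampleIds = "character",
                 datasetId = "character", trait = "character",
                 corSD = "numeric"))

setValidity("NormalizedTraits", function(object) {
  n <- length(object@S)
  if (length(object@D) != n || length(object@sampleIds) != n)
    return("S, D and sampleIds must have equal length")
  TRUE
})

#' Posterior probabilities over the four association models
#'
#' The model space is \{H0 (no association), HS (sum trait only),
#' HD (difference trait only), HS+D (both)\}; the posterior is proportional
#' to BF_i x prior_i with BFs (1, BF_S, BF_D, BF_S x BF_D). Association with
#' the difference trait D (HD or HS+D) is a treatment-response association.
#'
#' @slot priors numeric(4), prior model probabilities summing to 1, in the
#'   order (H0, HS, HD, HS+D).
#' @slot posteriors numeric(4), posterior probabilities summing to 1.
#' @seealso \code{\link{modelPosteriors}}, \code{\link{responseProbability}},
#'   \code{\link{rescalePriorSensitivity}}
#' @export
setClass("ModelPosterior",
  representation(priors = "numeric", posteriors = "numeric"))

setValidity("ModelPosterior", function(object) {
  msg <- character()
  if (length(object@priors) != 4L || length(object@posteriors) != 4L)
    msg <- c(msg, "priors and posteriors must have length 4")
  else {
    if (abs(sum(object@priors) - 1) > 1e-9)
      msg <- c(msg, "priors must sum to 1")
    if (abs(sum(object@posteriors) - 1) > 1e-9)
      msg <- c(msg, "posteriors must sum to 1")
    if (any(object@posteriors < -1e-12) || any(object@posteriors > 1 + 1e-12))
      msg <- c(msg, "posteriors must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelPosterior-class construct from posterior components
#'   (renormalized to sum to 1) and the prior vector.
#' @param posteriors numeric(4) posterior components (renormalized).
#' @param priors numeric(4) model priors.
#' @export
ModelPosterior <- function(posteriors, priors = defaultModelPriors()) {
  posteriors <- posteriors / sum(posteriors)
  new("ModelPosterior", priors = priors, posteriors = posteriors)
}

setMethod("show", "StudyDataset", function(object) {
  cat("StudyDataset '", metadata(object)$studyId, "' (trait: ", object@trait,
      ")\n", sep = "")
  cat("  ", nrow(object), " SNPs x ", ncol(object), " individuals; assays: ",
      paste(assayNames(object), collapse = ", "), "\n", sep = "")
})

setMethod("show", "NormalizedTraits", function(object) {
  cat("NormalizedTraits for dataset '", object@datasetId, "' (trait: ",
      object@trait, ")\n", sep = "")
  cat("  n = ", length(object@S), "; cor(S, D) = ",
      formatC(object@corSD, digits = 3, format = "g"), "\n", sep = "")
})

setMethod("show", "ModelPosterior", function(object) {
  lab <- c("H0", "HS", "HD", "HS+D")
  cat("ModelPosterior\n")
  cat("  priors    :", paste(sprintf("%s=%.3g", lab, object@priors),
                             collapse = " "), "\n")
  cat("  posteriors:", paste(sprintf("%s=%.4g", lab, object@posteriors),
                             collapse = " "), "\n")
  cat("  P(response) =", format(responseProbability(object), digits = 4), "\n")
})
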