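#' Accessors for pgxscan classes
#'
#' \code{dosages} and \code{hetProbs} return the SNP x individual assay
#' matrices of a \linkS4class{StudyDataset}; \code{snpInfo} its per-SNP
#' metadata; \code{phenotypes} its per-individual phenotype/covariate table;
#' \code{studyId} / \code{datasetId} the dataset label; \code{traitName} the
#' lipid trait; \code{traitS} / \code{traitD} the normalized sum and
#' difference scores of a \linkS4class{NormalizedTraits}; \code{corSD} their
#' residual correlation; \code{responseProbability} the posterior probability
#' of a treatment-response association (P(HD) + P(HS+D)) of a
#' \linkS4class{ModelPosterior}.
#'
#' @param x,posterior object to access.
#' @return The corresponding component.
#' @name accessors
#' @examples
#' mp <- modelPosteriors(log10bfS = 6, log10bfD = 1)
#' responseProbability(mp)
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("hetProbs", function(x) standardGeneric("hetProbs"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))
#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname accessors
#' @export
setGeneric("traitS", function(x) standardGeneric("traitS"))
#' @rdname accessors
#' @export
setGeneric("traitD", function(x) standardGeneric("traitD"))
#' @rdname accessors
#' @export
setGeneric("corSD", function(x) standardGeneric("corSD"))
#' @rdname accessors
#' @export
setGeneric("responseProbability",
           function(posterior) standardGeneric("responseProbability"))

#' @rdname accessors
#' @export
setMethod("dosages", "StudyDataset", function(x) assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("hetProbs", "StudyDataset", function(x) {
  if ("hetProb" %in% assayNames(x)) assay(x, "hetProb") else NULL
})

#' @rdname accessors
#' @export
setMethod("snpInfo", "StudyDataset", function(x) as.data.frame(rowData(x)))

#' @rdname accessors
#' @export
setMethod("phenotypes", "StudyDataset", function(x) as.data.frame(colData(x)))

#' @rdname accessors
#' @export
setMethod("studyId", "StudyDataset", function(x) metadata(x)$studyId)

#' @rdname accessors
#' @export
setMethod("traitName", "StudyDataset", function(x) x@trait)

#' @rdname accessors
#' @export
setMethod("traitName", "NormalizedTraits", function(x) x@trait)

#' @rdname accessors
#' @export
setMethod("datasetId", "NormalizedTraits", function(x) x@datasetId)

#' @rdname accessors
#' @export
setMethod("traitS", "NormalizedTraits", function(x) {
  s <- x@S; names(s) <- x@sampleIds; s
})

#' @rdname accessors
#' @export
setMethod("traitD", "NormalizedTraits", function(x) {
  d <- x@D; names(d) <- x@sampleIds; d
})

#' @rdname accessors
#' @export
setMethod("corSD", "NormalizedTraits", function(x) x@corSD)

#' @rdname accessors
#' @export
setMethod("responseProbability", "ModelPosterior", function(posterior) {
  sum(posterior@posteriors[3:4])
})
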