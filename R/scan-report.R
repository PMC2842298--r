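#' Run the bivariate association scan over one or more studies
#'
#' For every SNP, computes per-dataset and fixed-effects combined log10
#' Bayes factors for the sum (S) and difference (D) traits (averaged over
#' the \eqn{\sigma_a} grid), four-model posterior probabilities, the derived
#' treatment-response probability P(HD) + P(HS+D), additive-model
#' frequentist tests on the pooled per-dataset-normalized data, and per-study
#' plus pooled minor-allele frequencies. Deterministic given its inputs.
#'
#' Studies must cover the same SNPs (identical \code{id} order in
#' \code{rowData}); individuals are aligned between genotypes and normalized
#' traits by sample id, and any normalized individual absent from the
#' genotype matrix is an error naming the offenders. SNPs monomorphic in all
#' datasets get BF = 1 (posteriors equal to the priors) and missing
#' frequentist results, and are flagged.
#'
#' @param studies a \linkS4class{StudyDataset} or list of them.
#' @param normalized optional list of \linkS4class{NormalizedTraits}
#'   matching \code{studies}; computed by \code{\link{normalizeDataset}}
#'   when missing.
#' @param priors numeric(4) model priors.
#' @param grid \eqn{\sigma_a} grid for BF averaging.
#' @param sigmaDRatio \eqn{\sigma_d / \sigma_a}.
#' @param useHet logical; use heterozygote probabilities (dominance column)
#'   when the studies carry them. When FALSE or unavailable the model is
#'   additive-only.
#' @return data.frame with one row per SNP: id, chrom, pos, pooled and
#'   per-study MAF, posteriors (h0, hs, hd, hsd), response_prob, pooled
#'   p/beta/se for S and D, combined and per-study log10 BFs, and a
#'   \code{monomorphic} flag.
#' @examples
#' cfg <- simConfig(nPerStudy = c(150, 200), nSnps = 6, seed = 11)
#' scan <- runScan(simulateStudies(cfg))
#' scan[, c("id", "h0", "response_prob", "p_S", "p_D")]
#' @export
runScan <- function(studies, normalized = NULL,
                    priors = defaultModelPriors(),
                    grid = defaultSigmaGrid(), sigmaDRatio = 0.25,
                    useHet = TRUE) {
  if (is(studies, "StudyDataset")) studies <- list(studies)
  stopifnot(length(studies) >= 1L,
            all(vapply(studies, is, logical(1), "StudyDataset")))
  if (is.null(normalized)) normalized <- lapply(studies, normalizeDataset)
  stopifnot(length(normalized) == length(studies))

  info <- snpInfo(studies[[1]])
  for (st in studies[-1])
    if (!identical(snpInfo(st)$id, info$id))
      stop("studies must cover the same SNPs in the same order")

  K <- length(studies)
  labels <- vapply(studies, studyId, character(1))
  statsS <- statsD <- vector("list", K)
  mafs <- matrix(NA_real_, nrow(info), K,
                 dimnames = list(info$id, labels))
  nUsed <- integer(K)
  for (k in seq_len(K)) {
    ids <- normalized[[k]]@sampleIds
    missing <- setdiff(ids, colnames(studies[[k]]))
    if (length(missing))
      stop("individuals in normalized traits but not in study '",
           labels[k], "': ", paste(utils::head(missing, 10), collapse = ", "))
    G <- dosages(studies[[k]])[, ids, drop = FALSE]
    H <- if (useHet) hetProbs(studies[[k]]) else NULL
    if (!is.null(H)) H <- H[, ids, drop = FALSE]
    statsS[[k]] <- datasetSufficientStats(traitS(normalized[[k]]), G, H)
    statsD[[k]] <- datasetSufficientStats(traitD(normalized[[k]]), G, H)
    freq <- rowMeans(G) / 2
    mafs[, k] <- pmin(freq, 1 - freq)
    nUsed[k] <- length(ids)
  }

  pooledS <- combineSufficientStats(statsS)
  pooledD <- combineSufficientStats(statsD)
  bfS <- bfCombinedAveraged(pooledS, grid, sigmaDRatio)
  bfD <- bfCombinedAveraged(pooledD, grid, sigmaDRatio)
  post <- .posteriorMatrix(bfS, bfD, priors)
  freqS <- lmPvalueCombined(pooledS)
  freqD <- lmPvalueCombined(pooledD)

  mo <- .centeredMoments(pooledS)
  mono <- mo$Cgg <= 0 & (if (is.null(mo$Chh)) TRUE else mo$Chh <= 0)

  out <- data.frame(id = info$id, chrom = info$chrom, pos = info$pos,
                    maf = drop(mafs %*% nUsed) / sum(nUsed),
                    h0 = post[, 1], hs = post[, 2], hd = post[, 3],
                    hsd = post[, 4],
                    response_prob = post[, 3] + post[, 4],
                    p_S = freqS$p, p_D = freqD$p,
                    beta_S = freqS$beta, se_S = freqS$se,
                    beta_D = freqD$beta, se_D = freqD$se,
                    log10bf_S = bfS, log10bf_D = bfD,
                    monomorphic = mono,
                    row.names = NULL)
  for (k in seq_len(K)) {
    out[[paste0("maf_", labels[k])]] <- mafs[, k]
    out[[paste0("log10bf_S_", labels[k])]] <-
      bfCombinedAveraged(statsS[[k]], grid, sigmaDRatio)
    out[[paste0("log10bf_D_", labels[k])]] <-
      bfCombinedAveraged(statsD[[k]], grid, sigmaDRatio)
  }
  out
}

#' Keep SNPs with appreciable evidence against the null
#'
#' Retains rows whose posterior probability of no association (H0) is below
#' the threshold; the default 0.5 keeps SNPs more likely than not to be
#' genuinely associated.
#'
#' @param table a scan table from \code{\link{runScan}} (needs an \code{h0}
#'   column).
#' @param threshold numeric(1) in (0, 1].
#' @return the filtered table.
#' @export
filterTop <- function(table, threshold = 0.5) {
  table[table$h0 < threshold, , drop = FALSE]
}

#' Collapse a scan table to one representative SNP per region
#'
#' SNPs on the same chromosome within \code{windowKb} of each other (gap
#' clustering on sorted positions) form a region; the representative is the
#' row with the smallest posterior on H0, ties broken by the smaller p-value
#' on the trait carrying the evidence (the difference trait when the
#' response posterior exceeds the S-only posterior, the sum trait
#' otherwise), then by position. Rows with missing positions become their
#' own regions with a warning.
#'
#' @param table a scan table with \code{chrom}, \code{pos} and posterior
#'   columns.
#' @param windowKb clustering window in kilobases.
#' @return the representative rows, with a \code{region} id column and a
#'   \code{n_snps_region} count, ordered by chromosome and position.
#' @export
groupRegions <- function(table, windowKb = 500) {
  if (!nrow(table)) return(cbind(table, region = integer(0),
                                 n_snps_region = integer(0)))
  noPos <- is.na(table$pos) | is.na(table$chrom)
  if (any(noPos))
    warning(sum(noPos), " row(s) with missing position treated as ",
            "singleton regions")
  ord <- order(table$chrom, table$pos)
  tab <- table[ord, , drop = FALSE]
  gap <- c(TRUE, diff(tab$pos) > windowKb * 1000 |
                 diff(as.integer(factor(tab$chrom))) != 0)
  gap[is.na(gap)] <- TRUE
  region <- cumsum(gap)
  region[is.na(tab$pos)] <- max(region, na.rm = TRUE) +
    seq_len(sum(is.na(tab$pos)))
  pRel <- ifelse(tab$response_prob >= tab$hs, tab$p_D, tab$p_S)
  pick <- vapply(split(seq_len(nrow(tab)), region), function(i) {
    o <- order(tab$h0[i], pRel[i], tab$pos[i])
    i[o[1]]
  }, integer(1))
  out <- tab[pick, , drop = FALSE]
  out$region <- as.integer(names(pick))
  out$n_snps_region <- as.integer(table(region)[names(pick)])
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Posterior expected number of associations in a scan
#'
#' Sums, over the SNPs of a table, the posterior probability of a
#' treatment-response association (HD or HS+D) and, separately, of any
#' association (1 - H0). Under the default priors an all-null scan of M
#' SNPs gives approximately M x 1e-5 expected response associations.
#'
#' @param table a scan table.
#' @return named numeric: \code{response} and \code{any}.
#' @export
expectedAssociationCount <- function(table) {
  c(response = sum(table$response_prob, na.rm = TRUE),
    any = sum(1 - table$h0, na.rm = TRUE))
}
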