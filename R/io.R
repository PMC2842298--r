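#' Read genotype dosages with SNP metadata
#'
#' Supports the BIMBAM mean-genotype text format (one row per SNP:
#' id, minor allele, major allele, then one dosage per individual,
#' comma-separated) and VCF with a per-genotype dosage (DS) field read via
#' \pkg{VariantAnnotation}. Dosages must lie in [0, 2] and SNP ids must be
#' unique. Alleles are recorded as (minor, major) with the dosage counting
#' the minor allele: any SNP whose dosage frequency exceeds 0.5 is flipped
#' on read (g to 2 - g, alleles swapped) with a message.
#'
#' @param path file path.
#' @param format \code{"bimbam"} or \code{"vcf"}.
#' @param sampleIds optional individual ids for BIMBAM input (the format
#'   itself carries none); defaults to ind1..indN.
#' @return list with \code{dosages} (SNPs x individuals matrix) and
#'   \code{snpInfo} (data.frame: id, chrom, pos, allele1, allele0; chrom/pos
#'   are NA for BIMBAM input unless supplied separately).
#' @seealso \code{\link{writeBimbam}}, \code{\link{readSnpInfo}}
#' @export
readGenotypes <- function(path, format = c("bimbam", "vcf"),
                          sampleIds = NULL) {
  format <- match.arg(format)
  out <- switch(format,
                bimbam = .readBimbam(path, sampleIds),
                vcf = .readDosageVcf(path))
  if (any(out$dosages < 0 | out$dosages > 2, na.rm = TRUE))
    stop("dosage outside [0, 2] in ", path)
  if (anyDuplicated(out$snpInfo$id))
    stop("duplicate SNP id(s) in ", path, ": ",
         paste(unique(out$snpInfo$id[duplicated(out$snpInfo$id)]),
               collapse = ", "))
  freq <- rowMeans(out$dosages) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    message("flipping ", sum(flip),
            " SNP(s) whose dosage counts the major allele")
    out$dosages[flip, ] <- 2 - out$dosages[flip, , drop = FALSE]
    a1 <- out$snpInfo$allele1[flip]
    out$snpInfo$allele1[flip] <- out$snpInfo$allele0[flip]
    out$snpInfo$allele0[flip] <- a1
  }
  out
}

.readBimbam <- function(path, sampleIds = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty BIMBAM file: ", path)
  parts <- strsplit(lines, "[,[:space:]]+")
  nf <- lengths(parts)
  if (length(unique(nf)) != 1L)
    stop("malformed BIMBAM line ", which(nf != nf[1])[1], " in ", path,
         ": expected ", nf[1], " fields, got ", nf[nf != nf[1]][1])
  if (nf[1] < 4L)
    stop("malformed BIMBAM line 1 in ", path, ": fewer than 4 fields")
  ids <- vapply(parts, `[[`, character(1), 1L)
  a1 <- vapply(parts, `[[`, character(1), 2L)
  a0 <- vapply(parts, `[[`, character(1), 3L)
  dos <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-(1:3)]))
    v
  }, numeric(nf[1] - 3L)))
  dos <- matrix(dos, nrow = length(ids))
  bad <- which(rowSums(is.na(dos)) > 0)
  if (length(bad))
    stop("malformed BIMBAM line ", bad[1], " in ", path,
         ": non-numeric dosage")
  if (is.null(sampleIds)) sampleIds <- paste0("ind", seq_len(ncol(dos)))
  dimnames(dos) <- list(ids, sampleIds)
  list(dosages = dos,
       snpInfo = data.frame(id = ids, chrom = NA_integer_, pos = NA_integer_,
                            allele1 = a1, allele0 = a0))
}

.readDosageVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!"DS" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF has no DS (dosage) genotype field: ", path)
  ds <- VariantAnnotation::geno(vcf)$DS
  ds <- matrix(as.numeric(ds), nrow = nrow(ds), dimnames = dimnames(ds))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1], character(1))
  info <- data.frame(id = names(rr),
                     chrom = as.character(GenomeInfoDb::seqnames(rr)),
                     pos = BiocGenerics::start(rr),
                     allele1 = alt, allele0 = as.character(rr$REF))
  list(dosages = ds, snpInfo = info)
}

#' Write a BIMBAM mean-genotype file
#'
#' @param dosages SNPs x individuals matrix in [0, 2].
#' @param snpInfo data.frame with \code{id}, \code{allele1}, \code{allele0}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBimbam <- function(dosages, snpInfo, path) {
  stopifnot(nrow(dosages) == nrow(snpInfo))
  lines <- paste(snpInfo$id, snpInfo$allele1, snpInfo$allele0,
                 apply(dosages, 1L, function(r)
                   paste(format(r, trim = TRUE, digits = 6),
                         collapse = ", ")),
                 sep = ", ")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write phenotype-covariate tables
#'
#' Tab-separated with header: id, pre, post, bmi, age, sex, smoking.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "pre", "post", "bmi", "age", "sex", "smoking")
  miss <- setdiff(need, colnames(ph))
  if (length(miss))
    stop("phenotype table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  ph
}

#' @rdname readPhenotypes
#' @param pheno data.frame as returned by \code{readPhenotypes}.
#' @export
writePhenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write SNP metadata tables
#'
#' Tab-separated with header: id, chrom, pos, allele1 (minor), allele0
#' (major).
#'
#' @param path file path.
#' @return data.frame of SNP metadata.
#' @export
readSnpInfo <- function(path) {
  info <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "allele1", "allele0")
  miss <- setdiff(need, colnames(info))
  if (length(miss))
    stop("SNP table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  info
}

#' @rdname readSnpInfo
#' @param info data.frame of SNP metadata.
#' @export
writeSnpInfo <- function(info, path) {
  utils::write.table(info, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write one study to disk
#'
#' Emits the BIMBAM mean-genotype file, the phenotype/covariate TSV and the
#' SNP metadata TSV for a \linkS4class{StudyDataset}.
#'
#' @param dataset a \linkS4class{StudyDataset}.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths.
#' @export
writeStudy <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- studyId(dataset)
  paths <- c(genotypes = file.path(dir, paste0(id, ".bimbam.txt")),
             phenotypes = file.path(dir, paste0(id, ".pheno.tsv")),
             snps = file.path(dir, paste0(id, ".snps.tsv")))
  writeBimbam(dosages(dataset), snpInfo(dataset), paths["genotypes"])
  ph <- phenotypes(dataset)
  writePhenotypes(cbind(id = rownames(ph), ph), paths["phenotypes"])
  writeSnpInfo(snpInfo(dataset), paths["snps"])
  paths
}

#' Assemble a StudyDataset from files
#'
#' @param genoPath BIMBAM mean-genotype file (or dosage VCF with
#'   \code{format = "vcf"}).
#' @param phenoPath phenotype/covariate TSV.
#' @param snpPath optional SNP metadata TSV overriding chrom/pos.
#' @param studyId,trait labels.
#' @param format genotype file format.
#' @return a \linkS4class{StudyDataset}.
#' @export
readStudy <- function(genoPath, phenoPath, snpPath = NULL,
                      studyId = "study1", trait = "tc",
                      format = c("bimbam", "vcf")) {
  ph <- readPhenotypes(phenoPath)
  geno <- readGenotypes(genoPath, format = format, sampleIds = ph$id)
  info <- geno$snpInfo
  if (!is.null(snpPath)) {
    meta <- readSnpInfo(snpPath)
    m <- match(info$id, meta$id)
    if (anyNA(m)) stop("SNP(s) missing from ", snpPath, ": ",
                       paste(info$id[is.na(m)][1:min(5, sum(is.na(m)))],
                             collapse = ", "))
    info$chrom <- meta$chrom[m]
    info$pos <- meta$pos[m]
  }
  StudyDataset(dosages = geno$dosages, pre = ph$pre, post = ph$post,
               bmi = ph$bmi, age = ph$age, sex = ph$sex,
               smoking = ph$smoking, snpInfo = info,
               studyId = studyId, trait = trait, sampleIds = ph$id)
}

#' Write / read a scan results table
#'
#' Tab-separated with a fixed column order (the \code{\link{runScan}}
#' layout); floating-point fields are printed at 6 significant digits and
#' Bayes factors are on the log10 scale.
#'
#' @param table scan table from \code{\link{runScan}}.
#' @param path output path.
#' @return invisibly, the path (\code{writeScan}); the table
#'   (\code{readScan}).
#' @export
writeScan <- function(table, path) {
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScan
#' @export
readScan <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read and validate a run configuration (YAML)
#'
#' Recognized keys: \code{traits}, \code{sigma_grid}, \code{sigma_d_ratio},
#' \code{priors} (4-vector summing to 1), \code{region_window_kb},
#' \code{threshold}, \code{seed}, and \code{datasets} (a list of entries
#' with \code{id}, \code{genotypes}, \code{phenotypes} and optionally
#' \code{snps}). Missing analysis keys take the package defaults.
#'
#' @param path YAML file.
#' @param checkPaths verify that dataset files exist.
#' @return named list of settings.
#' @export
readRunConfig <- function(path, checkPaths = TRUE) {
  cfg <- yaml::read_yaml(path)
  cfg$sigma_grid <- if (is.null(cfg$sigma_grid)) defaultSigmaGrid()
                    else as.numeric(cfg$sigma_grid)
  cfg$sigma_d_ratio <- if (is.null(cfg$sigma_d_ratio)) 0.25
                       else as.numeric(cfg$sigma_d_ratio)
  cfg$priors <- if (is.null(cfg$priors)) defaultModelPriors()
                else as.numeric(cfg$priors)
  if (length(cfg$priors) != 4L || abs(sum(cfg$priors) - 1) > 1e-9)
    stop("config priors must be 4 values summing to 1")
  cfg$region_window_kb <- if (is.null(cfg$region_window_kb)) 500
                          else as.numeric(cfg$region_window_kb)
  cfg$threshold <- if (is.null(cfg$threshold)) 0.5 else as.numeric(cfg$threshold)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (checkPaths && !is.null(cfg$datasets)) {
    for (d in cfg$datasets) {
      for (f in c("genotypes", "phenotypes"))
        if (!is.null(d[[f]]) && !file.exists(d[[f]]))
          stop("config dataset file does not exist: ", d[[f]])
    }
  }
  cfg
}

#' Reported top associations from the combined statin trials scan
#'
#' The table of top regional associations reported by the combined
#' genome-wide analysis of lipid response to statins in the CAP, PRINCE and
#' TNT trials: per SNP, the four model posterior probabilities (a component
#' printed as "<0.01" is stored at the interval midpoint 0.005), the pooled
#' frequentist p-values for the sum and difference traits, the pooled MAF
#' and the chromosome. Used as the worked-example input for posterior
#' algebra and prior-sensitivity analyses; these are published summary
#' numbers, not individual-level data.
#'
#' @return data.frame with columns \code{snp}, \code{trait}, \code{h0},
#'   \code{hs}, \code{hd}, \code{hsd}, \code{p_S}, \code{p_D}, \code{maf},
#'   \code{chrom}.
#' @examples
#' top <- topAssociations()
#' row <- top[top$snp == "rs8014194", ]
#' mp <- ModelPosterior(c(row$h0, row$hs, row$hd, row$hsd))
#' responseProbability(mp)   # 0.84
#' @export
topAssociations <- function() {
  path <- system.file("extdata", "top_associations.tsv",
                      package = "pgxscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
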