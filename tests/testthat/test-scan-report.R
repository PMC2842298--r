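test_that("runScan populates every field, is deterministic, and flags planted SNPs", {
  cfg <- simConfig(nPerStudy = c(500L, 600L, 700L), nSnps = 8L,
                   effectClass = c("statin_response", "statin_independent",
                                   rep("null", 6)),
                   veS = c(0.03, 0.04, rep(0, 6)),
                   veD = c(0.04, 0, rep(0, 6)),
                   mafJitterSd = 0.01, seed = 19L)
  studies <- simulateStudies(cfg)
  scan <- runScan(studies)
  expect_equal(nrow(scan), 8)
  expect_true(all(c("id", "chrom", "pos", "maf", "h0", "hs", "hd", "hsd",
                    "response_prob", "p_S", "p_D", "log10bf_S", "log10bf_D",
                    "maf_study1", "log10bf_D_study3") %in% colnames(scan)))
  expect_equal(scan$h0 + scan$hs + scan$hd + scan$hsd, rep(1, 8),
               tolerance = 1e-9)
  expect_true(all(scan$maf > 0 & scan$maf <= 0.5))

  # the strongly planted response SNP is detected as such; nulls are not
  expect_gt(scan$response_prob[1], 0.5)
  expect_lt(max(scan$response_prob[3:8]), 0.5)
  # the statin-independent SNP shows S evidence without response evidence
  expect_gt(scan$hs[2], 0.5)
  expect_lt(scan$response_prob[2], 0.5)

  expect_identical(runScan(studies), scan)
})

test_that("runScan validates SNP alignment and sample ids", {
  cfg <- smallConfig(seed = 4L)
  studies <- simulateStudies(cfg)
  swapped <- studies[[2]][rev(seq_len(nrow(studies[[2]]))), ]
  expect_error(runScan(list(studies[[1]], swapped)), "same SNPs")

  nt <- lapply(studies, normalizeDataset)
  nt[[1]]@sampleIds[1] <- "ghost"
  expect_error(runScan(studies, nt), "ghost")
})

test_that("monomorphic SNPs fall back to priors with missing p-values", {
  cfg <- smallConfig(seed = 14L)
  studies <- simulateStudies(cfg)
  for (k in seq_along(studies)) {
    SummarizedExperiment::assay(studies[[k]], "dosage")[4, ] <- 0
    SummarizedExperiment::assay(studies[[k]], "hetProb")[4, ] <- 0
  }
  scan <- runScan(studies)
  expect_true(scan$monomorphic[4])
  expect_equal(scan$h0[4], unname(defaultModelPriors()[1]), tolerance = 1e-9)
  expect_true(is.na(scan$p_D[4]))
  expect_equal(scan$log10bf_S[4], 0)
})

test_that("filterTop applies the H0 threshold inclusively below", {
  tab <- data.frame(id = c("a", "b", "c"), h0 = c(0.16, 0.51, 0.99))
  expect_equal(filterTop(tab)$id, "a")
  expect_equal(nrow(filterTop(tab, threshold = 1.0)), 3)
  expect_equal(nrow(filterTop(tab, threshold = 0.1)), 0)
})

test_that("region grouping merges by window and picks the strongest row", {
  tab <- data.frame(id = paste0("s", 1:6),
                    chrom = c(1, 1, 1, 2, 2, 3),
                    pos = c(1e6, 1.01e6, 1.2e6, 1e6, 3e6, NA),
                    h0 = c(0.2, 0.1, 0.4, 0.3, 0.3, 0.5),
                    hs = c(0.1, 0.1, 0.1, 0.6, 0.1, 0.2),
                    response_prob = c(0.7, 0.8, 0.5, 0.1, 0.6, 0.3),
                    p_S = c(.5, .5, .5, 1e-4, .5, .5),
                    p_D = c(1e-3, 1e-5, 1e-2, .5, 1e-3, .5))
  expect_warning(reg <- groupRegions(tab, windowKb = 500), "missing position")
  # chr1 cluster of three -> middle SNP (smallest H0) wins
  expect_true("s2" %in% reg$id)
  expect_false(any(c("s1", "s3") %in% reg$id))
  # same positions on different chromosomes never merge
  expect_true(all(c("s4", "s5") %in% reg$id))
  expect_equal(nrow(reg), 4)

  # tie on H0 broken by the p-value of the evidence-carrying trait
  tab2 <- data.frame(id = c("x", "y"), chrom = 1, pos = c(1e6, 1.1e6),
                     h0 = c(0.2, 0.2), hs = c(0.7, 0.1),
                     response_prob = c(0.1, 0.7),
                     p_S = c(1e-6, 0.5), p_D = c(0.5, 1e-8))
  expect_equal(groupRegions(tab2, 500)$id, "y")
})

test_that("expected association counts sum posteriors and are additive", {
  pr <- defaultModelPriors()
  tab <- data.frame(h0 = rep(unname(pr[1]), 1000),
                    response_prob = rep(1e-5, 1000))
  cnt <- expectedAssociationCount(tab)
  expect_equal(unname(cnt["response"]), 1000 * 1e-5, tolerance = 1e-9)
  expect_equal(unname(cnt["any"]), 1000 * 1e-4, tolerance = 1e-9)

  tab2 <- data.frame(h0 = c(0.16, rep(1 - 1e-4, 9)),
                     response_prob = c(0.84, rep(1e-5, 9)))
  expect_equal(unname(expectedAssociationCount(tab2)["response"]), 0.84,
               tolerance = 1e-3)
  # additivity over a partition
  expect_equal(expectedAssociationCount(tab2),
               expectedAssociationCount(tab2[1:4, ]) +
               expectedAssociationCount(tab2[5:10, ]))
})
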