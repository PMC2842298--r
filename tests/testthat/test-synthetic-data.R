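test_that("HWE genotype simulation has the right moments and degenerate limits", {
  g <- simulateGenotypes(0.5, 50000, noise = 0, seed = 1)
  expect_equal(mean(g$dosage), 1, tolerance = 0.02)
  expect_equal(var(g$dosage), 0.5, tolerance = 0.02)
  expect_true(all(g$dosage %in% c(0, 1, 2)))
  expect_true(all(g$hetProb[g$dosage == 1] == 1))
  expect_true(all(g$hetProb[g$dosage != 1] == 0))

  # full imputation-noise blend collapses to the expected dosage
  g2 <- simulateGenotypes(0.3, 100, noise = 1, seed = 2)
  expect_equal(g2$dosage, rep(0.6, 100))
  expect_equal(g2$hetProb, rep(2 * 0.3 * 0.7, 100))

  # empirical MAF within 3 binomial SDs of the target
  maf <- 0.24; n <- 4000
  g3 <- simulateGenotypes(maf, n, seed = 7)
  se <- sqrt(maf * (1 - maf) / (2 * n))
  expect_lt(abs(mean(g3$dosage) / 2 - maf), 3 * se)

  expect_error(simulateGenotypes(0.6, 10), "maf")
  expect_error(simulateGenotypes(0, 10), "maf")
  expect_error(simulateGenotypes(0.2, 10, noise = 1.2), "noise")
})

test_that("simulateStudy is deterministic and respects effect classes", {
  cfg <- smallConfig()
  s1 <- simulateStudy(cfg, 1)
  s2 <- simulateStudy(cfg, 1)
  expect_identical(dosages(s1), dosages(s2))
  expect_identical(phenotypes(s1), phenotypes(s2))
  expect_s4_class(s1, "StudyDataset")
  expect_true(all(dosages(s1) >= 0 & dosages(s1) <= 2))
  expect_true(all(phenotypes(s1)$pre > 0))
  expect_true(all(phenotypes(s1)$post > 0))
})

test_that("null SNPs are uncorrelated with D while planted classes hit targets", {
  # large single study so sampling error is small
  cfg <- simConfig(nPerStudy = 3932L, nSnps = 3L,
                   effectClass = c("null", "statin_independent",
                                   "statin_response"),
                   veS = c(0, 0.05, 0.01), veD = c(0, 0, 0.01),
                   mPre = 5.4, mPost = 5.1, sScale = 0.15, seed = 5L)
  st <- simulateStudy(cfg, 1)
  nt <- normalizeDataset(st)
  G <- dosages(st)[, names(traitS(nt))]
  D <- traitD(nt); S <- traitS(nt)

  expect_lt(abs(cor(G[1, ], D)), 0.05)               # null
  expect_lt(abs(cor(G[2, ], D)), 0.05)               # statin-independent
  expect_gt(abs(cor(G[2, ], S)), 0.15)               # ... but acts on S
  # response SNP explains ~1% of var(D) on the normalized scale
  # (Monte Carlo band: +/- 3 sd of r^2 at r ~ 0.1, n ~ 4000)
  r2 <- cor(G[3, ], D)^2
  expect_gt(r2, 0.002)
  expect_lt(r2, 0.021)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nPerStudy = c(100, 100), nSnps = 2,
                         effectClass = "statin_response", veD = c(0.6, 0.5),
                         veS = 0, seed = 1),
               "sum")
  cfg <- smallConfig()
  expect_error(simulateStudy(cfg, 9), "out of range")
  # classes force their zero constraints silently in the constructor
  cfg2 <- simConfig(nPerStudy = c(50, 50), nSnps = 2,
                    effectClass = "statin_independent", veS = 0.02,
                    veD = 0.02, seed = 1)
  expect_true(all(cfg2@veD == 0))
})
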