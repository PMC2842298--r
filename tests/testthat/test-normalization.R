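test_that("averageRepeats takes per-individual means of non-missing visits", {
  expect_equal(averageRepeats(rbind(c(212, 212))), 212)
  expect_equal(averageRepeats(rbind(150)), 150)
  expect_equal(averageRepeats(rbind(c(100, 110), c(120, NA))), c(105, 120))
  expect_true(is.na(averageRepeats(rbind(c(NA, NA)))))
})

test_that("rank-inverse-normal transform matches the normal quantile oracle", {
  out <- rankInverseNormal(c(5, 2, 9))
  expect_equal(out, qnorm(c(2, 1, 3) / 4))
  expect_equal(out[1], 0)
  expect_equal(out[2], -out[3])

  # median of an odd-length all-distinct vector maps to 0
  x <- c(10, 3, 7, 1, 22)
  expect_equal(rankInverseNormal(x)[order(x)][3], 0)

  # monotone and idempotent on its own ranks
  x <- rnorm(51)
  y <- rankInverseNormal(x)
  expect_true(all(diff(y[order(x)]) > 0))
  expect_equal(rankInverseNormal(y), y)

  # ties share one score; NAs pass through
  z <- rankInverseNormal(c(1, 1, 2, NA))
  expect_equal(z[1], z[2])
  expect_true(is.na(z[4]))

  expect_error(rankInverseNormal(c(3, 3, 3)), "identical")
  expect_error(rankInverseNormal(c(1)), "2 non-missing")
})

test_that("sum/difference reparameterization is an exact bijection", {
  sd1 <- sumDiff(1, 2)
  expect_equal(sd1, list(S = 3, D = 1))
  x <- rnorm(20); y <- rnorm(20)
  sd2 <- sumDiff(x, y)
  expect_equal((sd2$S - sd2$D) / 2, x)
  expect_equal((sd2$S + sd2$D) / 2, y)
  expect_equal(sumDiff(x, x)$D, rep(0, 20))
  expect_error(sumDiff(1:3, 1:4), "equal length")
})

test_that("covariate adjustment matches the normal-equations oracle", {
  set.seed(10)
  n <- 40
  lb <- rnorm(n); age <- rnorm(n, 60, 8); sex <- rbinom(n, 1, .5)
  sm <- rbinom(n, 1, .2)
  t <- 0.5 * lb - 0.02 * age + 0.3 * sex + rnorm(n)
  r <- adjustCovariates(t, lb, age, sex, sm)
  X <- cbind(1, lb, age, sex, sm)
  beta <- solve(crossprod(X), crossprod(X, t))
  expect_equal(r, drop(t - X %*% beta), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(X, r))), 1e-8)   # orthogonal to design

  # exact linear response gives ~zero residuals
  t2 <- 1 + 2 * lb + 3 * age - sex + sm
  expect_lt(max(abs(adjustCovariates(t2, lb, age, sex, sm))), 1e-8)

  # collinear column is named in the error
  expect_error(adjustCovariates(t, lb, age, sex, sex), "collinear")
})

test_that("four-step normalization yields exchangeable traits and rank invariance", {
  cfg <- smallConfig(seed = 8L, nPerStudy = c(200L, 200L))
  s1 <- simulateStudy(cfg, 1)
  nt1 <- normalizeDataset(s1)

  n <- length(traitS(nt1))
  # final marginals are exactly the Phi^{-1}(r/(n+1)) score set
  expect_equal(sort(unname(traitS(nt1))), qnorm(seq_len(n) / (n + 1)))
  expect_equal(sort(unname(traitD(nt1))), qnorm(seq_len(n) / (n + 1)))
  expect_lt(abs(corSD(nt1)), 0.15)

  # strictly monotone transforms of raw values leave the output identical
  ph <- phenotypes(s1)
  s1b <- StudyDataset(dosages = dosages(s1), pre = ph$pre^3,
                      post = exp(ph$post / max(ph$post)),
                      bmi = ph$bmi, age = ph$age, sex = ph$sex,
                      smoking = ph$smoking, snpInfo = snpInfo(s1),
                      studyId = studyId(s1), trait = traitName(s1),
                      sampleIds = rownames(ph))
  nt1b <- normalizeDataset(s1b)
  expect_identical(traitS(nt1b), traitS(nt1))
  expect_identical(traitD(nt1b), traitD(nt1))
})

test_that("equal-size datasets share one multiset of scores regardless of study scale", {
  # two studies differing only in affine location/scale of the raw phenotypes
  cfg <- simConfig(nPerStudy = c(180L, 180L), nSnps = 4L,
                   mPre = c(5.3, 6.1), mPost = c(5.0, 5.9),
                   sScale = c(0.12, 0.3), seed = 21L)
  nts <- lapply(simulateStudies(cfg), normalizeDataset)
  expect_equal(sort(unname(traitS(nts[[1]]))), sort(unname(traitS(nts[[2]]))))
  expect_equal(sort(unname(traitD(nts[[1]]))), sort(unname(traitD(nts[[2]]))))
})

test_that("individuals with missing phenotype or covariates are dropped", {
  cfg <- smallConfig(seed = 3L)
  s1 <- simulateStudy(cfg, 1)
  ph <- phenotypes(s1)
  ph$bmi[1] <- NA
  s1b <- StudyDataset(dosages = dosages(s1), pre = ph$pre, post = ph$post,
                      bmi = ph$bmi, age = ph$age, sex = ph$sex,
                      smoking = ph$smoking, snpInfo = snpInfo(s1),
                      studyId = studyId(s1), sampleIds = rownames(ph))
  nt <- normalizeDataset(s1b)
  expect_equal(length(traitS(nt)), nrow(ph) - 1L)
  expect_false(rownames(ph)[1] %in% names(traitS(nt)))
})
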