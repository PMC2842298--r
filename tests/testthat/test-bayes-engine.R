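test_that("closed-form BF agrees with the numeric-integration oracle", {
  w <- workedBfInstance()
  cf <- bfSingle(w$t, w$g, w$h, sigmaA = 0.1)
  or <- bfNumericOracle(w$t, w$g, w$h, sigmaA = 0.1)
  expect_lt(abs(cf - or) / abs(or), 1e-6)

  # additive-only and dominance-degenerate variants
  expect_lt(abs(bfSingle(w$t, w$g, NULL, 0.2) -
                bfNumericOracle(w$t, w$g, NULL, 0.2)), 1e-7)

  # a handful of random instances across n, maf and sigma
  set.seed(99)
  for (i in 1:10) {
    n <- sample(8:50, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (var(g) == 0) next
    h <- as.numeric(g == 1)
    t <- rnorm(n) + runif(1, -0.5, 0.5) * g
    sa <- sample(defaultSigmaGrid(), 1)
    cf <- bfSingle(t, g, h, sa)
    or <- bfNumericOracle(t, g, h, sa)
    expect_lt(abs(cf - or) / max(abs(or), 1e-3), 1e-5)
  }
})

test_that("BF degenerate cases: zero prior scale and monomorphic SNPs give BF = 1", {
  w <- workedBfInstance()
  expect_equal(bfSingle(w$t, w$g, w$h, sigmaA = 0, sigmaD = 0), 0)
  expect_equal(bfSingle(w$t, rep(1, 8), rep(0, 8), sigmaA = 0.2), 0)
  expect_equal(bfNumericOracle(w$t, rep(1, 8), rep(0, 8), sigmaA = 0.2), 0)
  expect_error(bfSingle(w$t[1:2], w$g[1:2], NULL, 0.1), "n >= 3")
  expect_error(bfSingle(c(w$t[-1], NA), w$g, NULL, 0.1), "non-finite")
})

test_that("BF is invariant to trait location shifts and allele relabeling", {
  w <- workedBfInstance()
  for (sa in c(0.05, 0.2)) {
    base <- bfSingle(w$t, w$g, w$h, sa)
    expect_equal(bfSingle(w$t + 17.3, w$g, w$h, sa), base, tolerance = 1e-12)
    expect_equal(bfSingle(w$t, 2 - w$g, w$h, sa), base, tolerance = 1e-12)
    # the oracle shares the flat-intercept invariance
    expect_equal(bfNumericOracle(w$t + 5, w$g, w$h, sa),
                 bfNumericOracle(w$t, w$g, w$h, sa), tolerance = 1e-7)
  }
})

test_that("grid averaging is the linear-scale mean and is bounded by the grid", {
  w <- workedBfInstance()
  grid <- defaultSigmaGrid()
  per <- vapply(grid, function(sa) bfSingle(w$t, w$g, w$h, sa), numeric(1))
  avg <- bfAveraged(w$t, w$g, w$h)
  expect_equal(avg, log10(mean(10^per)), tolerance = 1e-12)
  expect_gte(avg, min(per))
  expect_lte(avg, max(per))
  expect_equal(bfAveraged(w$t, w$g, w$h, grid = 0.1),
               bfSingle(w$t, w$g, w$h, 0.1))
  expect_error(bfAveraged(w$t, w$g, w$h, grid = numeric(0)), "empty")
})

test_that("sufficient statistics are additive and reproduce the BF exactly", {
  set.seed(12)
  n1 <- 60; n2 <- 85
  g1 <- rbinom(n1, 2, 0.3); g2 <- rbinom(n2, 2, 0.35)
  h1 <- as.numeric(g1 == 1); h2 <- as.numeric(g2 == 1)
  t1 <- rnorm(n1) + 0.2 * g1; t2 <- rnorm(n2) + 0.2 * g2
  s1 <- datasetSufficientStats(t1, g1, h1)
  s2 <- datasetSufficientStats(t2, g2, h2)

  # stats reproduce the per-dataset BF
  expect_equal(bfCombined(s1, 0.1), bfSingle(t1, g1, h1, 0.1),
               tolerance = 1e-12)
  # component-wise additivity
  pooled <- combineSufficientStats(list(s1, s2))
  expect_equal(pooled$n, n1 + n2)
  expect_equal(pooled$sgt, s1$sgt + s2$sgt)

  # fixed-effects combination == single analysis of the concatenated data
  tAll <- c(t1, t2); gAll <- c(g1, g2); hAll <- c(h1, h2)
  for (sa in defaultSigmaGrid()) {
    expect_lt(abs(bfCombined(list(s1, s2), sa) -
                  bfSingle(tAll, gAll, hAll, sa)) /
              max(abs(bfSingle(tAll, gAll, hAll, sa)), 1e-6), 1e-10)
  }
  expect_equal(bfCombinedAveraged(list(s1, s2)),
               bfAveraged(tAll, gAll, hAll), tolerance = 1e-10)

  # permutation of dataset order is exactly neutral
  expect_identical(bfCombined(list(s1, s2), 0.15),
                   bfCombined(list(s2, s1), 0.15))
  expect_error(combineSufficientStats(list()), "at least one")
  expect_error(combineSufficientStats(list(s1, datasetSufficientStats(t2, g2))),
               "incompatible")
})

test_that("expected BF under the null is 1 and log10 BF concentrates at/below 0", {
  set.seed(31)
  n <- 60; reps <- 4000
  g <- rbinom(n, 2, 0.3); h <- as.numeric(g == 1)
  bfs <- replicate(reps, 10^bfSingle(rnorm(n), g, h, 0.2))
  # E[BF] = 1 under the null; MC tolerance 4 se
  expect_lt(abs(mean(bfs) - 1), 4 * sd(bfs) / sqrt(reps))
  # right-skew with unit mean puts the bulk of null log10 BFs below 0
  expect_lt(median(log10(bfs)), 0)
  expect_gt(mean(log10(bfs) < 0), 0.7)
})

test_that("model posteriors follow the prior-weighted BF arithmetic", {
  pr <- defaultModelPriors()
  expect_equal(sum(pr), 1)
  expect_equal(unname(sum(pr[3:4])), 1e-5)

  # no evidence: posteriors equal priors
  mp0 <- modelPosteriors(0, 0)
  expect_equal(mp0@posteriors, unname(pr), tolerance = 1e-12)
  expect_equal(responseProbability(mp0), 1e-5, tolerance = 1e-9)

  # direct-arithmetic worked case: BF_S = 1e6, BF_D = 10
  mp <- modelPosteriors(6, 1)
  w <- c(1 * pr[1], 1e6 * pr[2], 10 * pr[3], 1e7 * pr[4])
  expect_equal(mp@posteriors, unname(w / sum(w)), tolerance = 1e-9)
  expect_equal(mp@posteriors[1], 0.0055, tolerance = 1e-2)
  expect_equal(mp@posteriors[3], 5.5e-8, tolerance = 1e-2)
  expect_equal(responseProbability(mp), 0.497, tolerance = 1e-2)

  # huge BFs are safe in log space
  mp2 <- modelPosteriors(300, 250)
  expect_equal(sum(mp2@posteriors), 1, tolerance = 1e-12)
  expect_true(all(mp2@posteriors >= 0 & mp2@posteriors <= 1))

  expect_error(modelPosteriors(1, 1, priors = c(0.5, 0.2, 0.2, 0.2)), "sum")
})

test_that("response probability and prior rescaling reproduce the worked example", {
  mp <- rs8014194Posterior()
  expect_equal(responseProbability(mp), 0.84, tolerance = 0.01)

  # all mass on HS means zero response probability
  expect_equal(responseProbability(ModelPosterior(c(0, 1, 0, 0))), 0)

  expect_equal(responseProbability(rescalePriorSensitivity(mp, 1)),
               responseProbability(mp))
  expect_equal(responseProbability(rescalePriorSensitivity(mp, 1 / 5)),
               0.50, tolerance = 0.02)
  expect_gt(responseProbability(rescalePriorSensitivity(mp, 4)), 0.95)
  expect_error(rescalePriorSensitivity(mp, 0), "> 0")
})

test_that("posterior probabilities are calibrated when effects come from the prior", {
  # generate per-SNP data from the model's own prior (additive only),
  # score with matched model priors, and check realized frequency of truth
  # among SNPs whose response-type posterior lands in a probability bucket
  set.seed(77)
  m <- 3000; n <- 400
  grid <- defaultSigmaGrid()
  pi1 <- 0.1
  isAssoc <- rbinom(m, 1, pi1) == 1
  post <- numeric(m)
  for (j in seq_len(m)) {
    g <- rbinom(n, 2, 0.3)
    t <- rnorm(n)
    if (isAssoc[j]) {
      sa <- sample(grid, 1)
      t <- t + rnorm(1, 0, sa) * g
    }
    lbf <- bfAveraged(t, g, NULL, grid)
    post[j] <- 1 / (1 + (1 - pi1) / pi1 * 10^(-lbf))
  }
  inBucket <- post >= 0.55 & post <= 0.95
  expect_gt(sum(inBucket), 30)
  realized <- mean(isAssoc[inBucket])
  predicted <- mean(post[inBucket])
  se <- sqrt(predicted * (1 - predicted) / sum(inBucket))
  expect_lt(abs(realized - predicted), 3.5 * se)
})
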