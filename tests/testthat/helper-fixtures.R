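# shared fixtures built in code

# small multi-study config with one planted SNP of each effect class
smallConfig <- function(seed = 42L, nPerStudy = c(150L, 200L), nSnps = 6L) {
  simConfig(nPerStudy = nPerStudy, nSnps = nSnps,
            effectClass = c("null", "statin_independent", "statin_response",
                            rep("null", nSnps - 3L)),
            veS = c(0, 0.05, 0.03, rep(0, nSnps - 3L)),
            veD = c(0, 0, 0.05, rep(0, nSnps - 3L)),
            seed = seed)
}

# small worked BF instance reused across the oracle comparisons
workedBfInstance <- function() {
  t <- c(-1.2, 0.3, 0.5, -0.7, 1.1, 0.2, -0.4, 0.8)
  g <- c(0, 1, 2, 0, 1, 1, 0, 2)
  list(t = t, g = g, h = as.numeric(g == 1))
}

# rs8014194 worked-example posterior components (printed "<0.01" at 0.005)
rs8014194Posterior <- function() {
  ModelPosterior(c(0.16, 0.005, 0.07, 0.77))
}
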