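---
title: "Bivariate Bayesian scans for drug-response associations"
author: "pgxscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate Bayesian scans for drug-response associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxscan)
```

## The problem

Statins lower plasma cholesterol, but the size of the reduction varies
between people, and part of that variation is genetic. A genome-wide search
for SNPs that modify the response faces two coupled difficulties. First,
simply testing the change score `post - pre` against genotype has low power,
because the change has high variance. Second, the tempting alternative --
regressing the post-treatment value on genotype while adjusting for baseline
(ANCOVA) -- is biased in a genetic association setting: a SNP that shifts
pre- and post-treatment levels by the same amount is not a response SNP, yet
the ANCOVA test will tend to reject for it (see the last section).

`pgxscan` implements a bivariate treatment of the problem for multi-study
data such as the CAP, PRINCE and TNT statin trials. Writing X and Y for the
normalized baseline and on-treatment values, the analysis works with the sum
and difference traits

$$S = Y + X, \qquad D = Y - X,$$

a bijective reparameterization under which S and D are (near) uncorrelated.
Association with D is, by definition, a *treatment-response* association;
association with S alone is *treatment-independent*. Each SNP is scored
under four hypotheses -- $H_0$ (neither), $H_S$ (S only), $H_D$ (D only),
$H_{S+D}$ (both) -- with Bayes factors $(1, BF_S, BF_D, BF_S \times BF_D)$
and prior probabilities combined into posterior model probabilities. The
bivariate formulation gains power for the realistic case of SNPs that move
both S and D (e.g. a SNP affecting Y alone affects both), and it formalizes
the intuition that a modest D signal is more believable when it accompanies
an S signal.

## The Bayes factor

For a single SNP with centered dosage column $g$ and centered
heterozygosity column $h$, the single-trait model is

$$t = \mu + a\,g + d\,h + \varepsilon,\qquad
  a \sim N(0, \sigma_a^2\sigma^2),\quad
  d \sim N(0, \sigma_d^2\sigma^2),$$

with a flat prior on $\mu$, $p(\sigma^2) \propto 1/\sigma^2$, and
$\varepsilon \sim N(0, \sigma^2)$ -- the conjugate additive-plus-dominance
prior of Bayesian single-SNP regression. With $W = [g, h]$ (centered),
$V = \mathrm{diag}(\sigma_a^2, \sigma_d^2)$, total sum of squares
$\mathrm{TSS}$ and shrunken residual sum of squares
$\mathrm{RSS}_B = \mathrm{TSS} - t_c'W(W'W + V^{-1})^{-1}W't_c$, the
marginal-likelihood ratio against the intercept-only null is

$$BF = |I + V\,W'W|^{-1/2}
       \left(\frac{\mathrm{RSS}_B}{\mathrm{TSS}}\right)^{-(n-1)/2}.$$

`bfSingle()` evaluates this in log space. We did not take the closed form on
trust: `bfNumericOracle()` recomputes the same ratio by brute-force
quadrature (Gauss--Hermite in the effects, Simpson in $\log\sigma^2$, the
intercept handled by centering) and the test suite requires agreement to
better than 1e-5 relative on batches of random instances; in practice the
two agree to ~1e-12. The flat-intercept limit makes the BF invariant to
location shifts of the trait, and it is also invariant to allele relabeling
($g \to 2 - g$) and to the overall scale of $t$.

Defaults follow the published analysis: $\sigma_d = \sigma_a/4$ (most
weight near-additive while allowing dominance), and the BF is the
equal-weight average over
$\sigma_a \in \{0.05, 0.075, 0.1, 0.125, 0.15, 0.2, 0.4\}$
(`defaultSigmaGrid()`), computed by log-sum-exp because genome-scan BFs
span hundreds of orders of magnitude.

When only dosages are available the heterozygote state is not identified,
so `h` is dropped and the model degrades, loudly documented, to
additive-only; with simulated or imputation-style data the per-genotype
heterozygote probabilities are carried in the `StudyDataset` container and
used directly.

```{r bf-example}
t <- c(-1.2, 0.3, 0.5, -0.7, 1.1, 0.2, -0.4, 0.8)
g <- c(0, 1, 2, 0, 1, 1, 0, 2)
h <- as.numeric(g == 1)
c(closed = bfSingle(t, g, h, sigmaA = 0.1),
  oracle = bfNumericOracle(t, g, h, sigmaA = 0.1))
```

## Normalization: why four steps

Studies differ in populations, assays and protocols, so raw phenotypes are
never compared across studies. Within each *dataset* (one study x
genotyping-stage block, e.g. CAP-Stage I), `normalizeDataset()` applies:

1. rank-inverse-normal transform of raw pre and post values separately;
2. $S = \mathrm{post} + \mathrm{pre}$, $D = \mathrm{post} - \mathrm{pre}$;
3. OLS removal of log(BMI), age, sex, smoking from S and from D;
4. rank-inverse-normal transform of each residual vector.

The tie rule maps midrank $r$ to $\Phi^{-1}(r/(n+1))$; the $n+1$
denominator keeps extreme scores finite and is a package decision (the
procedure's description does not fix a tie rule). After step 4 the S (and
D) scores of every equal-sized dataset are *the same multiset*, so
between-study differences in allele frequency or phenotype scale cannot
manufacture associations in the pooled analysis -- the motivation for
rank rather than log transforms, even though for lipids the result is close
to working with centered logs. Any correlation between the final S and D is
reported (`corSD()`), not forced to zero; it is small in practice.
Individuals missing any phenotype or covariate are dropped from the dataset
before step 1 (the OLS step needs complete cases). Repeated visit values
are averaged first (`averageRepeats()`).

## Multi-study combination

The combined analysis assumes each SNP has one effect in all studies
("fixed effects"): `datasetSufficientStats()` reduces each dataset to
$n$, $\sum t$, $\sum t^2$ and the cross-products of $[1, g, h]$ with
itself and with $t$; these add component-wise across datasets, and
`bfCombined()` evaluates the closed form on the pooled sums. This equals
`bfSingle()` on the concatenated individuals *exactly* (tested at 1e-10
relative) and is deliberately not the product of per-study BFs, which would
correspond to independent per-study effects. Per-study BFs are still
reported per SNP for inspection. The companion frequentist scan
(`lmPvalue()`, `lmPvalueCombined()`) is the additive-model OLS slope with
the exact t reference distribution on the pooled normalized data, no
covariates (they were removed in normalization), no multiplicity
adjustment; `genomicControlLambda()` and `qqPoints()`/`plotQQ()` provide
the calibration diagnostics.

## Priors and posterior reporting

`defaultModelPriors()` is
$(1 - 10^{-4},\ 0.9\times10^{-4},\ 0.01\times10^{-4},\ 0.09\times10^{-4})$:
prior $10^{-4}$ on any association per SNP, overall $10^{-5}$ on a response
association (so a 2.5M-SNP scan expects 25 genuine response SNPs a priori),
and less skepticism about a D association accompanied by an S association.
The response probability of a SNP is $P(H_D) + P(H_{S+D})$.

Posteriors at this skeptical prior are sensitive to it, so
`rescalePriorSensitivity()` performs the exact Bayes-rule rescaling:
multiply the posterior components of the two response models by a factor
and renormalize, equivalent to changing the response prior without
re-touching data. The package ships the published top-association table of
the combined CAP/PRINCE/TNT scan (`topAssociations()`), whose printed
"<0.01" entries we store at the censoring-interval midpoint 0.005 -- the
standard treatment of an interval-censored printed value, and the choice
under which the worked sensitivity numbers land where the published
discussion puts them:

```{r sensitivity}
row <- subset(topAssociations(), snp == "rs8014194")
mp <- ModelPosterior(c(row$h0, row$hs, row$hd, row$hsd))
responseProbability(mp)                                  # 0.84
responseProbability(rescalePriorSensitivity(mp, 1 / 5))  # ~0.50
responseProbability(rescalePriorSensitivity(mp, 4))      # >0.95
```

Scan tables follow the supplementary-table layout (`runScan()`,
`writeScan()`): per SNP the four posteriors, response probability, pooled
and per-study MAFs and log10 BFs, and the frequentist p-values for S and D.
Reporting rules: `filterTop()` keeps SNPs with $P(H_0) < 0.5$ ("more likely
than not associated"); `groupRegions()` collapses SNPs within a window (500
kb by default -- "region" is not defined by the published analysis, so it
is a parameter) to the row with the smallest $P(H_0)$, ties broken by the
p-value of the evidence-carrying trait, then position;
`expectedAssociationCount()` sums posterior probabilities, the quantity
behind statements like "the posterior expected number of response
associations".

## The synthetic cohort generator

No individual-level statin-trial data are distributable, so `simConfig()` /
`simulateStudies()` generate cohorts with the statistical structure the
analysis assumes, and every claim in the test suite is made against them:

* **Study heterogeneity.** Defaults emulate three trials of sizes 592,
  1360 and 1976 with distinct raw-phenotype locations and scales taken
  from the trials' clinical tables (total-cholesterol-like values), and
  per-study MAF jitter (sd 0.01) of the size seen across per-trial MAF
  estimates.
* **Raw phenotypes are log-normal by construction**:
  $X_{raw} = \exp(m_{pre} + s(S^*-D^*)/2)$,
  $Y_{raw} = \exp(m_{post} + s(S^*+D^*)/2)$ from latent unit-variance
  $S^*, D^*$. Logs of raw lipids are approximately normal, and making raw
  values a monotone image of the latent scores makes the
  rank-normalization's behaviour exactly testable.
* **Effect sizes are variance-explained fractions** on the normalized
  trait scale -- the only effect-size currency the published results use
  (a top response SNP explaining 1% of the variance in statin-induced
  change) -- converted internally to dosage coefficients via
  $\beta_j = \sqrt{ve_j / 2\,maf_j(1 - maf_j)}$, with residual noise
  scaled so the latent traits have unit variance.
* **Effect classes** mirror the model space: `null`,
  `statin_independent` (S only; the class constraint forces
  $\beta_D = 0$) and `statin_response`. In the parameter-recovery tests
  the planted response SNP takes $ve_S = ve_D$, the signature of a SNP
  acting on the post-treatment level only -- the archetypal response
  mechanism the bivariate design is built around.
* **Imputation noise** is the deterministic blend
  $(1-r)\,g + r\,2\,maf$ toward the HWE mean, which preserves the
  expected dosage and attenuates information like a posterior mean
  genotype; heterozygote probabilities blend likewise toward
  $2\,maf(1-maf)$. It is not a draw of posterior genotype triples -- a
  simplification adequate for additive/near-additive BFs.
* **Covariates** (age ~ N(60, 10), log-normal BMI around 28, sex ~
  Bernoulli(0.7), smoking ~ Bernoulli(0.15)) are loosely matched to the
  trials' clinical tables; their exact distributions are immaterial
  because normalization removes them.

What the generator deliberately does *not* emulate: linkage
disequilibrium between SNPs, relatedness, population stratification, or
case/control ascertainment within a trial. Passing tests therefore show
correctness of the statistical machinery under the model's own
assumptions, not robustness to those real-data complications (the
published analysis addressed stratification empirically via genomic
control and PCA).

All randomness flows from one integer seed, expanded deterministically per
study and stage; equal seeds give bit-identical cohorts.

## Numerical and design choices

* All BF and posterior arithmetic is in log space; grid averaging by
  log-sum-exp.
* SNPs monomorphic in all datasets get BF = 1, posteriors equal to the
  priors, missing frequentist results, and a flag.
* Dosages are minor-allele counts; readers flip any SNP whose dosage
  frequency exceeds 0.5 (with a message) and swap the recorded alleles.
* Coordinates are 1-based base pairs.
* The oracle integrates on a fixed wide window in $\log\sigma^2$ with a
  convergence check that doubles the Gauss--Hermite order and refuses to
  answer if the result moves by more than 1e-7; it is restricted to
  n <= 50 where tensor quadrature is reliable.
* The covariate regression refuses rank-deficient designs and names the
  collinear column rather than silently dropping it.

## Scale of the shipped checks

The test suite exercises the full pipeline at sizes chosen to make the
statistical properties sharp while staying desk-sized: the null-calibration
check scans 100,000 null SNPs at total n = 4,000 across three studies (in
chunks of 5,000 SNPs) and requires genomic-control lambda in [0.97, 1.03]
and 5% type-I error within a 99% binomial band; parameter recovery plants a
response SNP explaining 1% of var(D) at total n = 3,932 (596 + 1360 + 1976)
and requires `response_prob > 0.5` and $p_D < 5\times10^{-7}$ in a majority
of 50 replicates; the ANCOVA-bias demonstration uses 2,000 replicates of
n = 1,000 with a shared effect explaining 2% of baseline variance and
residual pre/post correlation 0.5 -- sizes at which the inflation is
unmistakable while the difference test stays within its binomial band.

## The ANCOVA pitfall, demonstrated

`simulateSharedEffect()` draws cohorts in which one SNP shifts pre- and
post-exposure values identically -- by construction *not* a response SNP --
and compares the p-value distribution of the ANCOVA test (`Y ~ g + X`)
with that of the difference test (`(Y - X) ~ g`):

```{r ancova}
sim <- simulateSharedEffect(ancovaSimConfig(reps = 500, seed = 4))
summarizeRejections(sim$pAncova, alphas = 0.05)  # inflated
summarizeRejections(sim$pDiff, alphas = 0.05)    # calibrated
```

The ANCOVA test targets conditional independence of Y and g given X, which
fails whenever the shared effect is nonzero and the residual pre/post
correlation is below 1 -- so its rejection rate grows with the effect size
and with decreasing correlation, while the difference test sees a true
null. In a randomized trial ANCOVA is the right tool because randomization
makes baseline independent of group; genotype is not randomized against
baseline, hence the bias. The demonstration is a caution, not an
endorsement of change-score testing in general.

## Known limitations

* Additive-only degradation without heterozygote information (above).
* The fixed-effects assumption loses power under real between-study effect
  heterogeneity; it does not inflate the null after per-dataset
  normalization, which is why it is the default and the only model offered.
* Per-SNP analysis only: no LD-aware or multi-SNP models, no incorporation
  of external association priors per SNP (though `modelPosteriors()`
  accepts per-call priors, which is the hook one would use).
* The S/D definition of "response" is scale-dependent for SNPs affecting
  both pre and post levels; on the normalized (approximately log) scale it
  roughly captures differential *percentage* response.
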