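---
title: "Genomic selection for hybrid breeding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for hybrid breeding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridgs)
```

## The problem

Hybrid rice breeding works from a pool of inbred lines. Crossing any two of
them produces an F1 hybrid whose genotype is fully determined by the
parents, so the genotypes of enormous candidate populations — every
permissible cross among thousands of lines — are available *in silico* for
free. What is expensive is the phenotype: only a small training set of
hybrids can be grown and measured. Genomic selection bridges the gap: fit a
whole-genome mixed model to the phenotyped hybrids, predict every untested
candidate from marker data alone, and send only the most promising few to
the field.

`hybridgs` implements that workflow end to end: genotype coding and hybrid
deduction, marker quality control, kinship construction, REML estimation of
the GBLUP mixed model, partitioned-kinship BLUP prediction, replicated
cross-validation, a weighted breeding index for multi-trait ranking, and
broad-sense heritability from replicated block designs. A synthetic-data
generator produces parents, crosses and polygenic phenotypes with the same
statistical structure, so every stage can be exercised and calibrated
without any external download.

## Genotype coding and hybrid deduction

At a biallelic SNP the two homozygotes are coded $-1$ and $1$ and the
heterozygote $0$. Inbred parents are homozygous almost everywhere, so an F1
hybrid's code is the mean of its parents' codes: $(-1 + 1)/2 = 0$,
$(-1 + (-1))/2 = -1$, and, when one parent is residually heterozygous,
the half codes $(-1 + 0)/2 = -0.5$ and $(0 + 1)/2 = 0.5$. The half codes
are the *expected* dosage over the segregating gametes, which is the right
quantity for a linear prediction model. Missing parental calls propagate
to the hybrid and are mean-imputed after filtering.

Marker QC keeps a marker when its minor allele frequency is strictly above
`maf_min` (default 0.1) and its missing fraction is at most `missing_max`
(default 0.25). The allele frequency is read off the codes as
$p = (\bar z + 1)/2$. Filtering precedes imputation, so imputed values
(which are off the discrete code grid) never influence the QC decisions;
mean imputation then preserves each marker's allele frequency exactly.

## The mixed model

For $n$ phenotyped hybrids and $m$ markers the model is

$$ y = X\beta + \sum_{k=1}^{m} Z_k \gamma_k + \varepsilon
     = X\beta + \xi + \varepsilon, $$

with iid marker effects $\gamma_k \sim N(0, \phi^2/m)$ and residuals
$\varepsilon \sim N(0, I\sigma^2)$. Marginalising the marker effects gives

$$ \operatorname{var}(y) = K\phi^2 + I\sigma^2 = (K\lambda + I)\sigma^2,
   \qquad K = \frac{1}{m}\sum_k Z_k Z_k^{\mathsf T},
   \qquad \lambda = \phi^2/\sigma^2 . $$

The kinship matrix is used exactly in this raw cross-product form — no
centering, no allele-frequency scaling — so that the model is the exact
marginal of the marker-effect model above. A VanRaden-style centered
variant is available behind `compute_kinship(..., method = "vanraden")`
for users who want relationship coefficients on the conventional scale,
but it is not the default.

Individual marker effects are never estimated; $\lambda$ is the single
parameter, found by restricted maximum likelihood.

### Eigen-accelerated REML

With $K = U\,\mathrm{diag}(d)\,U^{\mathsf T}$ computed once, the rotation
$y^* = U^{\mathsf T} y$, $X^* = U^{\mathsf T} X$ turns
$K\lambda + I$ into $H = \mathrm{diag}(d\lambda + 1)$ and every likelihood
evaluation into $O(nq^2)$ work. The profiled restricted log likelihood is

$$ L(\lambda) = -\tfrac12 \sum_i \log h_i
   - \tfrac12 \log\bigl|X^{*\mathsf T} H^{-1} X^*\bigr|
   - \tfrac{n-q}{2}\log\hat\sigma^2(\lambda) - \tfrac{n-q}{2}, $$

with $\hat\beta$ the GLS estimate and
$\hat\sigma^2 = (y - X\hat\beta)^{\mathsf T}V_0^{-1}(y - X\hat\beta)/(n-q)$
(REML divisor $n - q$, $q$ the column rank of $X$). The additive constant
$-\frac{n-q}{2}\log 2\pi$ is dropped throughout; all likelihood
comparisons in the package share this convention, and the test suite
verifies the rotated evaluation against dense solves of the same
expression to $10^{-8}$.

Maximisation is Newton iteration on $\theta = \log\lambda$, which enforces
$\lambda > 0$ without constraints. Both derivatives are analytic in the
rotated basis (they are checked against central finite differences in the
tests). Steps are limited to $|\Delta\theta| \le 5$ and backtracked until
the likelihood increases; convergence is $|\Delta\theta| < 10^{-8}$ with a
50-iteration cap, and a golden-section search on
$\log\lambda \in [\log 10^{-8}, \log 10^{8}]$ serves as fallback if Newton
stalls. An estimate below $10^{-7}$ is reported as the boundary value
$\lambda = 0$ (no genetic signal). Ill-conditioned fixed-effect systems
fall back to a pseudo-inverse with a warning instead of failing.

### Prediction of untested hybrids

Stacking training (subscript 1) and test (subscript 2) hybrids partitions
the kinship into blocks, and the BLUP of the unobserved phenotypes is

$$ \hat y_2 = X_2\hat\beta +
   \hat\lambda K_{21}\,(K_{11}\hat\lambda + I)^{-1}(y_1 - X_1\hat\beta). $$

`blup_predict()` reuses the training eigendecomposition for the inverse,
so predicting even very large candidate sets costs one matrix-vector
product per hybrid. Because $K_{21}$ is an identity-by-state quantity it is
never exactly zero, which is what lets a diverse training population say
something about hybrids with no pedigree ties to it — albeit much less
than about hybrids that share parents with the training set, a contrast
the synthetic-data tests make explicit.

### Implied genomic heritability

`fit_reml()` reports
$h^2_{\text{genomic}} = \hat\lambda\bar k_c/(\hat\lambda\bar k_c + 1)$
where $\bar k_c$ is the mean diagonal of the doubly-centered kinship
matrix ($\bar k_c = \overline{\mathrm{diag}\,K} - \overline{K}$). The
centering matters with the raw cross-product kinship: markers whose codes
have nonzero mean contribute a component to $K$ that is absorbed by the
intercept and carries no variance *among* hybrids; REML is invariant to
adding any multiple of the all-ones matrix to $K$, so only the centered
part of $K$ is estimable. For mean-centered codes (allele frequencies at
one half) $\bar k_c$ equals the raw mean diagonal and the two definitions
coincide. Defined this way, the implied heritability is calibrated against
the generator: simulations at $n = 500$, $m = 1000$ recover
$h^2 \in \{0.2, 0.5, 0.8\}$ with mean error below $0.05$ over 50
replicates (this is one of the suite's acceptance checks).

## Dominance and genotype-by-environment extensions

The additive-plus-dominance (A–D) model adds a second kernel built from
heterozygosity codes $W = \max(0, 1 - |2Z|)$ — heterozygote 1, homozygote
0, half codes 0.5 (the probability the hybrid is heterozygous when one
parent segregates) — giving
$V = (K\lambda_A + K_D\lambda_D + I)\sigma^2$ with
$K_D = \frac1m\sum_k W_k W_k^{\mathsf T}$. The genotypic
(heterozygosity-indicator) parameterisation was chosen because the
package targets F1 hybrids, where dominance manifests exactly at
heterozygous loci.

The G×E model stacks $E$ environments with environment-specific fixed
means; the genetic covariance is a shared main effect
$(J_E \otimes K)\,\phi^2_{\text{main}}$ plus an environment-specific
deviation $(I_E \otimes K)\,\phi^2_{g\times e}$ — a linear-kernel
multi-environment GBLUP. Per-environment predictions combine both parts:
the covariance between a test hybrid in environment $e$ and a training
record in environment $f$ is
$K_{21}(\lambda_{\text{main}} + \lambda_{g\times e}[e = f])\sigma^2$.

Both extensions have two variance ratios, so the single-kernel eigen trick
no longer diagonalises the covariance. They are evaluated densely through
a Cholesky factorisation and maximised over the log ratios by Nelder–Mead
polished with BFGS. This is the right trade-off at training-population
scale (the dense evaluation is exact, and $n$ in the hundreds costs
milliseconds per step); it would need revisiting for $n$ in the tens of
thousands. When the second component is structurally unidentifiable —
a zero dominance kernel, or a single environment — the model *is* the
additive model, and the fit delegates to the additive eigen path, which
makes the nesting identity exact to machine precision rather than merely
to optimizer tolerance.

## Cross-validation and heritability

`cross_validate()` runs replicated K-fold cross-validation (default
10-fold, 10 replicates, replicate $r$ partitioned with seed
$\texttt{seed} + r - 1$). Folds are unstratified random splits with sizes
differing by at most one. The kinship is computed once on the full sample
and sub-blocked per fold — this matches the partitioned-BLUP algebra
above, and avoids recomputing an $O(mn^2)$ product hundreds of times.
Prediction ability is the Pearson correlation between observed and
out-of-fold predicted values. At strong signal the expected ability
approaches $\sqrt{h^2}$ (predicting the phenotype cannot beat the genetic
signal it contains); the suite checks both this and the null calibration
(ability centred on zero for pure-noise phenotypes).

`fit_crbd()` estimates broad-sense heritability from a randomized
complete block design without replication within cells:
$y_{jk} = \mu + \alpha_j + \beta_k + \varepsilon_{jk}$, hybrids random,
blocks fixed. The default estimator is Henderson's expected-mean-squares
method of moments, $\hat\sigma^2_G = (MS_G - MS_E)/b$, with
$h^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_E)$; a negative moment estimate
is reported raw and truncated at zero for $h^2$. A REML alternative
(`method = "reml"`), built on the package's own mixed-model machinery
over the block-stacked design, is available for comparison.

## The synthetic-data generator

`sim_config()` fixes the simulated study system:

* **Parents** (`simulate_parents`): per marker an allele frequency is drawn
  uniformly from `[maf_low, maf_high]` (defaults 0.1–0.5, the spectrum
  left after a MAF > 0.1 filter on a diverse panel); each parent is
  homozygous $\pm 1$ at that frequency, heterozygous with probability
  `residual_het_rate` (default 0.01 — inbred lines are occasionally
  residually heterozygous), missing at `missing_rate` (default 0).
  Markers are independent: the prediction machinery never uses positions,
  so linkage is deliberately out of scope.
* **Phenotypes** (`simulate_phenotypes`): marker effects are iid normal —
  exactly the polygenic assumption the GBLUP model marginalises — with
  optional dominance effects on the heterozygosity codes and optional
  environment-specific effect draws. Each realized genetic component is
  rescaled to its requested variance share, and the residual draw is
  rescaled against the realized per-environment genetic variance so the
  realized broad-sense heritability equals `h2_target` *exactly*, not
  just in expectation. Empirical calibration was chosen over an analytic
  variance formula because it stays correct under any
  dominance/G×E/QTL-count setting.
* **Bundles** (`make_training_and_test`): a half diallel over the simulated
  panel is sampled into a phenotyped training set and an unphenotyped test
  set, either sharing parents (`"overlap"`) or from split parent pools
  (`"disjoint"`, emulating prediction of an unrelated population). True
  genetic values are always returned for oracle comparisons.

Everything is bit-reproducible given the seed; generators use isolated
RNG state and never touch the session RNG.

What the generator does *not* emulate: linkage disequilibrium and genome
structure, population stratification, selection history, shared
environmental (plot/field) effects, and trait correlation structure.
Passing tests therefore demonstrate the correctness and calibration of
the estimation machinery under the model's own assumptions, not the
field performance of genomic selection on real rice panels.

## Numerical conventions and edge cases

* Eigenvalues of kinship matrices are clipped at zero below
  $10^{-10}\max(d)$; matrices asymmetric beyond $10^{-8}$ (relative) are
  rejected.
* Trait standardization for the breeding index uses the population (divisor
  $n$) standard deviation over the candidate set being ranked — the
  reference population is configurable because ranking 44 636 candidates
  against themselves and against the training set are both defensible;
  the candidate set is the default. Zero-variance traits are an error
  naming the trait.
* Index ties are broken lexicographically by hybrid id; the bottom tail is
  drawn from hybrids not already in the top tail, so the two selections
  are disjoint even under massive ties.
* All trait directions default to "larger is better"; a per-trait
  `direction` flag flips signs for traits where smaller is preferred.
* Cross ids are the sorted pair `"A_x_B"`, so reciprocal crosses collapse
  deterministically; in three-line enumeration the maintainer is recorded
  as the female parent separately from the sorted id.
* Degenerate inputs (constant phenotype, all-missing marker, empty filter
  result, single block) produce explicit warnings or errors rather than
  numeric garbage.

## Problem sizes used in the checks

The test suite exercises dense-oracle equivalence at $n \le 20$ (100
random instances), optimizer agreement at $n = 60$ (50 instances),
heritability recovery at $n = 500$, $m = 1000$ (50 replicates per level),
cross-validation calibration at $n = 200$ (null) and $n = 400$
($h^2 = 0.8$), and CRBD recovery at $n = 1000$ hybrids in two blocks
(20 seeds). These sizes were chosen so the whole suite completes in a few
minutes while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* The raw cross-product kinship is the model's exact marginal but is not
  on the conventional relationship scale; diagonal elements depend on
  allele frequencies. Use the VanRaden option for interpretable
  coefficients.
* The A–D and G×E fits are dense and quadratic-to-cubic in $n$; they are
  meant for training-population sizes, not for candidate-set scoring
  (which only ever needs the additive machinery).
* Multi-trait fitting is a loop over independent univariate fits; genetic
  correlations between traits are not modelled.
* The CRBD estimator assumes every hybrid is observed in every block;
  incomplete hybrids are dropped, not modelled.
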