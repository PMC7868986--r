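---
title: "Multi-omic hybrid prediction: models, HAT predictability and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic hybrid prediction: models, HAT predictability and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyblup)
```

## Scope and model

`hyblup` predicts the phenotypes of untested hybrids from predictor layers
measured on their inbred parents: genome-wide markers (G), transcript
abundances (T), metabolite abundances (M), and the parents' own phenotypic
records (P). All four layers share one coding rule. If $M_{jk}$ and
$F_{jk}$ are the male and female parent values of feature $k$ for cross
$j$, the hybrid designs are

$$Z_{jk} = \tfrac12 (M_{jk} + F_{jk}), \qquad
  W_{jk} = \tfrac12 |M_{jk} - F_{jk}|.$$

For markers coded $-1/0/1$ this is the familiar hybrid genotype coding
($Z = 1, 0, -1$ and $W = 0, 1, 0$ for the two homozygotes and the
heterozygote derived from homozygous parents); for continuous layers $Z$
is the mid-parent value and $W$ half the absolute parental difference.
Self-crosses have identically zero $W$ rows, and the coding is symmetric
in the two parents.

Each layer contributes an additive and (optionally) a dominance kinship,
$K_a = ZZ^\top/m$ and $K_d = WW^\top/m$ with $m$ the layer's feature
count, and the phenotype vector follows the multi-kernel mixed model

$$y = X\beta + \textstyle\sum_l (Z_l \gamma_{la} + W_l \gamma_{ld}) + \varepsilon,
  \qquad
  \mathrm{var}(y) = V = \textstyle\sum_i K_i \phi^2_i + I\sigma^2 .$$

Variance components maximise the restricted likelihood
$L(\theta) = -\tfrac12\ln|V| - \tfrac12\ln|X^\top V^{-1}X|
- \tfrac12 (y - X\hat\beta)^\top V^{-1} (y - X\hat\beta)$, and a test set
is predicted by the conditional expectation
$\hat y_2 = X_2\hat\beta + (\sum_i K_{21,i}\hat\phi^2_i) V_{11}^{-1}
(y_1 - X_1\hat\beta)$.

Note the dominance kernel is built from the $W$ design ($WW^\top/m$), the
only construction consistent with the dominance term of the model; the
package never reuses $ZZ^\top$ for the dominance component.

## HAT predictability

Cross-validated predictability of BLUP can be computed without refitting.
With $C = \sum_i K_i\hat\phi^2_i$, the matrix $H = C V^{-1}$ maps the
fixed-effect-adjusted phenotypes $\xi = y - X\hat\beta$ onto their fitted
genetic predictions, $\hat\xi = H\xi$. Because the off-diagonal parts of
$C$ and $V$ coincide, the leave-one-out prediction error at frozen
$\hat\beta$ and $\hat\theta$ is *exactly*
$e_j = \hat e_j / (1 - H_{jj})$ with $\hat e = (I - H)\xi$, and for a fold
$k$, $e_k = (I - H_{kk})^{-1}\hat e_k$. Hence

$$\mathrm{PRESS} = \sum_k e_k^\top e_k, \qquad
  R^2_{\mathrm{HAT}} = 1 - \mathrm{PRESS}/\mathrm{SS},$$

with SS the mean-adjusted total sum of squares. The test suite verifies
this identity to $10^{-8}$ relative error against a brute-force
leave-out oracle across 25 random instances with one to four kernels, and
the block (K-fold) version likewise. $H$ is not symmetric, so the K-fold
formula is implemented as a linear solve with the fold's diagonal block,
never as a symmetric quadratic form.

Two definitions of predictability coexist. The HAT route reports
$1-\mathrm{PRESS}/\mathrm{SS}$; brute-force cross-validation primarily
reports the squared Pearson correlation between pooled out-of-fold
predictions and observations, with the PRESS-based number also attached.
`compare_hat_cv()` can force a common definition; under the shared PRESS
definition with frozen full-sample $\hat\beta$ and $\hat\theta$, the
leave-one-out difference is zero to numerical precision. With each
method's native definition, the two agree to about 0.01 on simulated
two-kernel data at $n = 200$, averaged over 20 ten-fold partitions — the
HAT number runs very slightly higher, as expected from the definitional
gap, so both are always reported rather than reconciled.

Conventions worth stating:

- $\hat\beta$ and $\hat\theta$ in the HAT evaluations come from the full
  sample; this is the method's defining approximation relative to per-fold
  re-estimation. `cross_validate()` offers both `vc_mode = "full_sample"`
  and `"per_fold"`, and reports name the mode; on simulated data at
  $n = 200$ the two differ by well under 0.03.
- SS is mean-adjusted even when the fixed design carries parental
  covariates; `ss_convention = "fixed_adjusted"` switches to the
  OLS-residual convention, and every report records which was used.
- Leverages $H_{jj} \ge 1 - 10^{-10}$ raise an error naming the
  observation (a perfectly leveraged point has no out-of-sample residual).

## The nine parental models

Parental phenotypic records may enter as a random kernel layer exactly
like an omic layer (`Random`), or as fixed covariates. The fixed codings
per trait are the mid-parent value (`A`), half the absolute parental
difference (`D`), both (`AD`), or the raw male and female values as
separate columns (`P`); the trait scope is either the target trait
(`-One`) or every trait in the parental matrix (`-All`). Column counts are
therefore $t$, $t$, $2t$ and $2t$ for $t$ traits in scope. The `AD` coding
of P equals what the coding module produces for a P-layer design, which
the tests check directly.

Two design choices the model family leaves open:

- Fixed parental columns are centered before REML (the intercept absorbs
  the means, and centering keeps the optimizer well-scaled); candidate
  crosses are centered with the *training* means so the two samples share
  a scale. A rank guard drops trailing linearly dependent columns with a
  warning rather than failing, since degenerate blocks arise naturally
  (e.g. difference columns over self-crosses).
- Separate female/male coefficients in the `P` coding are only
  interpretable (e.g. as maternal effects) when the cross plan records a
  real parent order; canonical unordered plans trigger a warning.

## Standardization and kernel scaling

Predictors are standardized *after* coding, over the full hybrid design —
training and candidate crosses jointly when ranking untested crosses —
because the training-versus-candidate kinship blocks only make sense on a
common scale. The variance uses the population (divide-by-$n$) convention
so the $1/m$-scaled kernel diagonal averages exactly one; the convention
is stored in the design object and echoed in run manifests. Constant
columns are zeroed, not dropped, preserving feature alignment across
plans. Kernels are scaled $1/m$ per layer regardless of $m$ (so a
four-trait P layer is scaled by $1/4$); a trace-normalization flag exists
but is off by default.

## REML implementation

The restricted likelihood is maximised over log-reparameterized
components, $\theta_i = \epsilon + e^{\lambda_i}$ with floor
$\epsilon = 10^{-8}\,\mathrm{var}(y)$, using BFGS with numerical
gradients, at most 200 iterations and relative tolerance $10^{-8}$. Three
deterministic starts (equal split, residual-heavy, genetic-heavy) are
tried and the best kept, which in practice resolves the occasional local
ridge when kernels are nearly collinear. Each likelihood evaluation uses a
Cholesky factorization of $V$ with escalating diagonal jitter
($10^{-10} \to 10^{-6}$, logged) if the factorization fails. Convergence
status, iteration counts and the log-likelihood are recorded on the fit.
Flat directions are possible by construction — duplicated kernels identify
only the sum of their components — and the tests pin exactly that
behaviour rather than pretending the components separate.

## What the simulator emulates

The generator mirrors the data situation the models assume: a biparental
RIL panel (homozygous $\pm1$ genotypes, linkage via a two-state chain with
per-marker switch probability `recomb_fraction`), omic features that are
sparse linear functions of markers with a controlled heritable fraction,
parental phenotypes equal to each line's own additive value plus noise,
and hybrid phenotypes $y = \mu + Z\gamma_a + W\gamma_d + \varepsilon$ with
each component rescaled to hit its target variance exactly. Effect vectors
are drawn once per dataset, matching how REML treats one realized sample,
and layer seeds derive deterministically from the master seed so enlarging
one layer never perturbs another.

Defaults are desk-scale but realistic for the setting: 120 parents, 5
chromosomes × 60 markers with `recomb_fraction = 0.1` (blocks of roughly
ten linked markers), 300 transcripts and 200 metabolites at heritability
0.5, four traits with additive/dominance/residual variances 2/1/1, 250
training hybrids, and parental noise variance 1 (parental heritability
about 2/3). The default trait architecture is polygenic (every marker
carries an effect) because that is the generating model REML assumes;
sparse architectures are available (`n_additive_qtl`), under which the
kernel model is deliberately misspecified and variance recovery degrades —
useful for robustness probes, not for calibration checks.

What passing tests on these data do **not** show: real omic layers have
correlated, non-Gaussian noise, environment and batch structure, and
transcript/metabolite-to-hybrid relations that are not linear functions of
parental genotype; real populations have allele-frequency structure the
$\pm1$ mosaic lacks. Results on simulated data validate the algebra and
the estimation machinery, not field performance.

## Problem sizes and verification experiments

The bundled verification experiments (test suite and
`scripts/acceptance.R`) use: exactness checks at $n \le 150$ with 1–4
kernels (25 instances); HAT-versus-CV agreement at $n = 200$ with 20
ten-fold partitions; REML recovery at $n = 300$ over 50 replicates
(observed mean relative bias is a few percent, comfortably within the 10%
band we assert); and 50-replicate directional experiments at $n = 150$ for
the additive-dominance and parental-augmentation contrasts, asserting an
advantage in at least 90% of replicates. These sizes make every experiment
rerun in minutes on a single core while keeping Monte-Carlo error small
relative to the asserted margins.

Two published-scale facts are exercised without external data: 210 parents
enumerate to 21,945 candidate crosses, and the packaged reference summary
of predicted top/bottom-200 crosses for the rice RIL population reproduces
the published percent gains (46.4 / 40.6 / 90.7 / 41.4 for YIELD, TILLER,
GRAIN, KGW under the full GTMP predictor) and the with-P versus without-P
tail averages (53.3/34.5 versus 49.3/37.6 for YIELD). Absolute
predictabilities of the real rice traits depend on the original dataset
and are out of scope here; the CLI can run them given the data.

## Known limitations

- REML refits are dense-matrix computations; the implementation targets
  training sets up to a few thousand hybrids, not biobank scale.
- The HAT shortcut is exact only at frozen variance components; if
  per-fold re-estimation matters for a dataset (it rarely does at these
  sizes), `cross_validate(vc_mode = "per_fold")` is the honest, slower
  route.
- No marker-frequency-centered kinship, no pedigree kinship, no
  genotype-by-environment terms, and no non-BLUP learners behind the HAT
  interface.
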