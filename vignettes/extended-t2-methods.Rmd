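---
title: "Extended T2 tests for longitudinal family sequencing data: model, choices, limits"
author: "pedT2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended T2 tests: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedT2)
```

## The problem

Whole-genome sequencing studies of complex disease often sample large
pedigrees rather than unrelated individuals, and most of what they find is
rare variation. A window-based case/control test for such data has to deal
with three correlation sources at once:

* **LD** — variants within a window are correlated with each other;
* **kinship** — individuals within a family are correlated with each other;
* **serial correlation** — covariates measured repeatedly over time are
  correlated across visits.

pedT2 implements a family of Hotelling-type statistics that handle all
three through a Kronecker-structured covariance, together with a
genotype-only permutation null, and a gene-dropping simulator so that the
whole pipeline can be exercised and calibrated without any external data.

## The statistic

For one genome window, order the $n$ individuals cases-first and form three
blocks: $Z$ ($n \times T$ common-variant dosages), $V$ ($n \times S$
CMC-collapsed rare-variant scores), and for the longitudinal tests $A$
($n \times CJ$, $C$ covariates at $J$ visits, covariate-major). Stack the
columns into $\eta$ and let $D_r = (u_1,\dots,u_n)'$, $u_i = 1$ for cases.
With $w = D_r - \tfrac{n_c}{n}\mathbf{1}$, the contrast
$H\eta$ stacks $d_X = \tfrac{n_c n_d}{n}(\bar X_c - \bar X_d)$ for each
block $X$, and the statistic is the quadratic form

$$T^2 = (H\eta)'\,\Gamma^{-1} (H\eta), \qquad
\Gamma = H \Lambda H', \quad
\Lambda = \mathrm{diag}(\Sigma_Z \otimes \Phi,\;
                        \Sigma_V \otimes \Phi,\;
                        \Sigma_A \otimes \Phi^*),$$

where $\Phi$ is the kinship-derived individual correlation and $\Phi^*$
(identity or $\Phi$) plays the same role for the environmental covariates.
The Kronecker structure contracts exactly:

$$T^2 = \frac{d_{ZV}'\,\hat\Sigma_{ZV}^{-1}\,d_{ZV}}{w'\Phi w}
      + \frac{d_{A}'\,\hat\Sigma_{A}^{-1}\,d_{A}}{w'\Phi^* w},$$

with $w'Iw = n_c n_d / n$ identically. Covariances are the pooled
within-group (cases/controls) estimates with divisor $n-2$, the classical
two-sample Hotelling pooling. With $\Phi = \Phi^* = I$, one block and an
invertible covariance, $T^2$ is *exactly* the textbook two-sample
Hotelling statistic — this reduction is enforced to $10^{-10}$ in the test
suite and pins down every constant; the published description of the
scaling is typographically ambiguous, so the quadratic form above is the
definition used throughout.

Six methods are exposed, differing in the rare-variant aggregator and the
covariance split:

| method | rare collapsing | covariance | covariates |
|---|---|---|---|
| `T2` | sum within adjacency runs | joint over $[Z\,|\,V]$ | no |
| `CMC.ZXpaper` | sum | separate $\Sigma_Z$, $\Sigma_V$ | no |
| `CMC.ZXcode` | max within runs | joint | no |
| `*.longi` | as above | $\Sigma_A$ always separate | yes |

Rare variants (MAF $< 0.05$, strict) are grouped into maximal runs of
consecutive rare variants delimited by common variants; runs before the
first and after the last common variant form their own groups, so no
variant is discarded. Max-collapsing uses the same runs with `max` in
place of `sum`, so the two schemes stay comparable.

## Numerical choices

* **Zero-variance columns** are dropped before covariance estimation: they
  contribute nothing to the contrast and make $\hat\Sigma$ singular.
* **Singular $\hat\Sigma$** uses an eigenvalue-truncated pseudo-inverse
  with relative cutoff $10^{-10} \cdot \lambda_{\max}$. `df_mode = "rank"`
  counts the retained eigenvalues (the "rank of the data matrix"
  convention); `df_mode = "n_variables"` counts retained columns.
* **Kinship scaling.** Whether $\Phi$ should hold kinship coefficients
  $\varphi$ (diagonal $1/2$) or the additive relationship $2\varphi$
  (diagonal 1) is not stated in the source material. The default is
  $2\varphi$, which makes $\Phi$ the expected genotype correlation under
  no inbreeding, $\Phi = I$ exactly for unrelated samples, and the
  classical-Hotelling reduction exact. `compute_kinship(scale="kinship")`
  preserves the other behaviour; the statistic simply scales by the
  corresponding factor in $w'\Phi w$.
* **Permutation ties** count as $\ge$ (the published formula), with a
  $10^{-9}$ relative slack so that round-off between the compiled and
  reference eigendecompositions cannot turn an exact tie into a strict
  inequality. An optional $(r+1)/(L+1)$ pseudo-count mode exists but is
  off by default, matching the published formula.
* **Permutation scope.** Rows of $[Z\,|\,V]$ are permuted across all
  individuals (labels, covariates and $\Phi$ fixed); a within-family mode
  is available for users concerned about exchangeability across families.
  One plan is shared across the windows of a run so results reproduce
  bit-for-bit from the seed.

## The permutation null and what it does (not) guarantee

Permuting genotypes only, as published, preserves the response–covariate
relationship; consequently the covariate term of the `.longi` statistics is
*constant* across permuted replicates and cancels from the permutation
rank. The longitudinal advantage under permutation inference therefore
comes from the any-time response definition (more cases), not from the
covariate block itself. This consequence is asserted in the test suite; the
source material does not discuss it.

A subtler point: the $p$-values of all windows in one scan share a single
response realization and a single observed genotype arrangement, so they
are mutually dependent. Their empirical distribution over windows can
deviate from uniform by several percent even when the test is exactly
calibrated marginally. Calibration checks in this package therefore use
independent simulation replicates (fresh phenotypes and genotypes per
replicate), where a Kolmogorov–Smirnov comparison against the uniform is
valid; on those, the type-I error at $0.05$ sits inside the 95% binomial
band and KS passes at the 1% level (see `test-acceptance.R`, which
computes everything it claims).

Asymptotic chi-square $p$-values are reported for completeness but are
anti-conservative under family structure — the pooled covariance assumes
independent rows, which genotypes of relatives are not. On the simulated
family null the genomic inflation factor $\lambda$ (median chi-square
quantile over $0.4549$) is about $1.13$, and about $0.97$ for unrelated
individuals; the direction reproduces the published Q-Q behaviour, and the
permutation $p$-values are the ones to use.

## What the simulator emulates

`sim_scenario()` defaults describe a study of 20 three-generation families
averaging about 40 members (sibship sizes 3–7 at both generations),
mirroring the scale of the motivating data set (849 individuals in 20
families, sizes 21–74); the calibration experiments use the 10-family
minimum for runtime. Genotypes: founder haplotypes are Li–Stephens-style
mosaics of a $K = 200$ template pool (switch probability 0.1 per adjacent
variant pair) whose templates carry AR(1)-latent LD (parameter 0.5);
meioses apply a single-crossover process (0.01 per adjacent pair). The MAF
spectrum is 30% common (uniform on $[0.05, 0.5]$) and 70% rare (uniform on
$[0.001, 0.05)$). Phenotypes: $C = 3$ covariates (an age-like drifting one
and two stationary ones) at $J = 3$ visits with AR(1) correlation 0.8;
events follow a per-visit logistic model on the causal dosage burden, the
current covariates and a shared individual intercept
($\mathcal N(0,1)$), with the visit intercept calibrated so the any-time
prevalence hits the 0.3 target — roughly the hypertension-like setting of
the motivating study.

An earlier design drew one pool template per founder chromosome; with
$K = 200$ templates and several hundred individuals this made nominally
unrelated founders share entire chromosomes — cryptic relatedness that
inflated $\lambda$ to $\sim 1.36$ and correlated all windows. The mosaic
design keeps sharing local, which is also what real unrelated haplotypes
look like.

What the generator does **not** emulate: realistic human demography or
ascertainment, genotype error, missing data or unequal visit counts
(excluded from scope), dosage uncertainty (it emits integer allele counts,
while imputed "dose" data are fractional — real dose data have fewer exact
permutation ties), and gene-centred variant clustering. A green
calibration test therefore establishes correctness of the machinery under
this stated world, not robustness to everything real data can do.

## Design decisions that were genuinely open

* **Window convention**: 0-based half-open BED tiles of width 10 kbp on
  position $-1$; tiling runs from position 1 to the last variant position.
* **MAF**: mean dosage over $2n$, folded to $\le 0.5$; computed on all
  individuals (dose data carry no phasing or founder labels).
* **Exactly-threshold variants** (MAF $= 0.05$) are common: the published
  rule is strict "$<$".
* **Leading/trailing rare runs** form their own collapsed groups — the
  published description covers only runs *between* common variants, and
  this choice loses no variants.
* **Binomial comparison of methods**: one-sided exact tail
  $P(X \ge \max(k_A, k_B))$, $X \sim \mathrm{Bin}(k_A + k_B, 1/2)$. For
  the published 93-vs-15 comparison this gives $3.202\times 10^{-15}$;
  the printed value is $3.8\times 10^{-15}$, which no convention we tried
  (two-sided, other $n$, normal/Poisson approximations, continuity
  corrections) reproduces — we treat the printed number as a misprint and
  report the exact value. The published figure caption for the same
  comparison prints different counts (79/19/5) than the text (93/5/15);
  the text is taken as authoritative.
* **"Similar" margin** when comparing per-window powers: two Monte-Carlo
  standard errors of the difference at the 0.05 cutoff, with windows
  excluded when both powers fall below twice the cutoff; both are
  configurable, since the source defines neither.
* **Single-time-point comparators** use the time-1 response and no
  covariate block. A sensitivity mode with $J = 1$ covariates is reachable
  through the engine API, since the published description is ambiguous on
  whether the comparator saw any covariates.

## Known limitations

Missing data and unequal numbers of repeated measures are out of scope (as
in the source material, which lists them as future work), as are
quantitative traits, X-linked kinship, weighted burden scores, SKAT-style
variance-component tests and sparse covariance estimators. The asymptotic
$p$-values should not be used for inference in family data; they exist to
demonstrate exactly that.
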