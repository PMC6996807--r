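---
title: "Random regression models for genomic prediction of longitudinal traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression models for genomic prediction of longitudinal traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`rrgp` analyses traits recorded repeatedly over time on genotyped
accessions — the motivating setting is automated greenhouse phenotyping of a
rice diversity panel, where daily water use (WU, kg/day, derived from pot
weights) and projected shoot area (PSA, an image-based shoot biomass proxy)
are recorded for every plant over 20 days of imaging.

The single-trait random regression model (ST-RRM) for the adjusted
phenotype $y_{jt}$ of accession $j$ at day $t$ is

$$y_{jt} = \sum_{k=0}^{2}\phi_k(t)\,b_k
         + \sum_{k=0}^{2}\phi_k(t)\,u_{jk}
         + \sum_{k=0}^{2}\phi_k(t)\,p_{jk} + e_{jt},$$

with a fixed mean trajectory $b$, additive-genetic regression coefficients
$u_j$, permanent-environment coefficients $p_j$ (the smooth, accession-
specific non-genetic component that makes repeated records of one plant
resemble each other), and a day-specific residual. In matrix form
$y = Xb + Zu + Qp + e$ with

$$\operatorname{Var}(u) = C \otimes G,\qquad
  \operatorname{Var}(p) = D \otimes I,\qquad
  \operatorname{Var}(e) = \bigoplus_t R(t),$$

where $G$ is the genomic relationship matrix and $C$, $D$ are coefficient
covariance functions. The multi-trait model (MT-RRM) stacks two traits;
$C$ and $D$ gain cross-trait blocks ($C_{12}$, $D_{12}$) and each day's
residual becomes a full $2\times 2$ block $R(t)$.

All regressions use Legendre polynomials of standardized time
$x = -1 + 2(t - t_{\min})/(t_{\max} - t_{\min})$. The basis is constructed
as $\Phi = M\Lambda$ ($M$ monomials, $\Lambda$ the normalized Legendre
coefficients) and scaled by $\sqrt 2$ so that the intercept column is
identically one; column $k$ is $\sqrt{2k+1}\,P_k(x)$. All reported variance
components are specific to this convention (the unscaled orthonormal basis
sits behind `scale_intercept = FALSE`).

Per-day summaries follow from quadratic forms in the basis rows $t_i$:
genomic correlation
$r_g(t) = t_i C_{12} t_i' / \sqrt{(t_i C_1 t_i')(t_i C_2 t_i')}$ and
narrow-sense heritability
$h^2(t) = t_i C_q t_i' / (t_i C_q t_i' + t_i D_q t_i' + v_{e_q}(t))$.
The denominator of $h^2$ is a convention: the permanent-environment variance
is included by default (it is non-genetic variance a breeder cannot select
on), and `include_pe = FALSE` excludes it. The choice moves levels, not
shapes.

# Genomic relationship matrix

`compute_grm()` builds $G = WW'/m$ from mean-centered dosage columns scaled
to unit *population* variance (divisor $n$), which makes
$\mathrm{mean}(\mathrm{diag}(G)) = 1$ an exact identity and is the default;
the classical denominator $2\sum p_k(1-p_k)$ is available as
`scaling = "vanraden"`. QC removes markers with call rate $\le$ 0.95 or
minor allele frequency $\le$ 0.05 (strict "keep above threshold" semantics,
both thresholds configurable). Missing genotypes are rejected — imputation
belongs upstream — except for a mean-impute testing convenience flag.

A centered GRM is exactly singular (the ones vector is in its null space;
equivalently off-diagonals average $-1/(n-1)$). Two stabilizations are
provided and serve different purposes:

* `add_ridge()` (default $10^{-6}$) makes inversion well defined and is
  applied once when a matrix enters the mixed-model machinery;
* `blend_grm()` forms $(1-w)G + wI$ with $w = 0.05$, the usual identity
  blending in genomic-evaluation practice. Blending — not the tiny ridge —
  is what the Gibbs sampler needs: with only a ridge, the location updates
  are nearly reducible along the null direction (we measured lag-500
  autocorrelations above 0.95) while the direct MME solve is unaffected.
  `gibbs_rrm()` warns when it receives a near-singular matrix.

# Estimation

## Mixed model equations

`solve_mme()` builds Henderson's equations with $C^{-1}\otimes G^{-1}$ and
$D^{-1}\otimes I$ on the random blocks and the day-block residual precision
on the data part, solves by dense Cholesky, and verifies
$\|LHS\,\hat s - RHS\| \le \mathrm{tol}\,\|RHS\|$. Random-effect columns are
ordered coefficient-major (coefficient index outer, accession inner), the
ordering under which $\operatorname{Var}(u) = C \otimes G$ holds exactly for
the trait-major layout of `cov_components()`; the realized-covariance
verification path (`realized_covariance()`) pins this convention in the test
suite, because a silent Kronecker-ordering mismatch is the classic random
regression implementation error.

Genetic values of unphenotyped accessions follow the projection
$\hat a_{tst}(t) = G_{tst,trn} G_{trn,trn}^{-1}\,\Phi\hat u_{trn}$, which at
fixed variances is identical to carrying the accessions through the joint
MME with zero phenotype rows (tested to $10^{-6}$).

## Gibbs sampler

`gibbs_rrm()` re-implements the conjugate Gibbs scheme of the BLUPF90-family
samplers: multivariate-normal location updates, inverse-Wishart draws for
$C$ (scale $U'G^{-1}U$) and $D$ (scale $P'P$), and per-day residual blocks
from complete trait pairs (inverse-Wishart) or per-trait scaled inverse
chi-square when a day carries only one trait, in which case the cross term
is held at zero.

Two implementation choices matter for mixing and are worth recording:

* Each accession's genetic block is updated with its permanent-environment
  block *integrated out* (the marginal record covariance
  $B_p D B_p' + R_a$ is local to the accession), and $p_a \mid u$ is then
  redrawn conjugately. Without this partial collapsing, the genetic /
  permanent-environment partition mixes extremely slowly whenever the
  genomic structure separating them is modest — we measured effective
  sample sizes near 5 for the genomic correlation with plain
  accession-block updates.
* Default priors are weakly informative and data-scaled: with $v_q$ the
  within-day phenotypic variance of trait $q$ (the trait variance with the
  mean trajectory removed), the inverse-Wishart scales partition it as 10%
  genetic and 30% residual with $\nu = \dim + 2$, and 2.5% permanent
  environment with $\nu = \dim + 10$ (scale matched so the prior mean stays
  at that share). The asymmetry is deliberate. Near-zero prior scales are
  *not* a safe default here: when the data only weakly separate $D$ from
  $C$, they make $D \to 0$ a quasi-absorbing state of the chain. And a
  *vague* $D$ prior lets chains settle in the mirrored degenerate mode
  where the permanent-environment term absorbs the genetic trajectories
  outright; the moderate concentration of the $D$ prior repels both
  corners without overriding identified data (its weight is that of ~16
  pseudo-observations against hundreds of accessions).

Chain defaults are 30,000 iterations, 10,000 burn-in, thinning 10;
`ess()` provides an initial-positive-sequence effective-sample-size
diagnostic, and convergence is deliberately not auto-detected. The
`fixed_variances` option disables all variance updates (every retained draw
equals the input components) and corresponds to the fixed-variance
prediction runs of the cross-validation pipeline.

# The study pipeline

`compute_wu()` derives daily water use as the previous day's after-watering
pot weight minus the current day's before-watering weight; a missing
previous day yields a missing value, never an error. `stage1_blue()` fits
the per-day, per-trait adjustment model (accession fixed; experiment-
replicate, smarthouse block, and accession-by-experiment interaction
random) and returns sum-to-zero accession BLUEs. The random-term variances
are estimated by REML (`lme4`) — the standard tool for exactly this model
class — while the BLUEs themselves are computed by this package's own
GLS/MME solve at those components, so a fit at user-supplied components is
exactly reproducible and testable against a dense GLS oracle.

`run_cv1()` and `run_cv2()` implement the two prediction scenarios:

* **CV1** (unphenotyped accessions): random 245/112 training/testing splits
  (sizes configurable), variance components estimated on the training set
  (single-trait for ST-RRM; one bivariate estimation shared by MT-RRM1 and
  MT-RRM2), then fixed-variance prediction. ST-RRM and MT-RRM1 project
  through the relationship matrix; MT-RRM2 carries the testing accessions'
  secondary-trait records in the model and reads target-trait genetic
  values directly from the BLUP solutions.
* **CV2** (forecasting): models train on the first `t_split` (default 10)
  days — the secondary trait over all days for MT-RRM2 — and the fitted
  regressions are evaluated at the remaining days. The basis bounds stay
  fixed at the full design range, so training on early days and evaluating
  later days uses the same polynomials; this is the single most
  consequential convention in the forecasting scenario, and the alternative
  (standardizing over the training window) is available by passing explicit
  bounds to `time_grid()`.

Accuracy is the Pearson correlation between predicted genetic values and
observed BLUEs per day, averaged across repeats (per-repeat values are
returned, so pooling predictions instead is a one-liner for the caller). On
synthetic data the runners also report accuracy against the simulated true
genetic values — a diagnostic for how much of the ceiling is measurement
noise in the BLUEs. Every repeat and every chain derives its seed
deterministically from the master seed, making accuracy tables reproducible
bit for bit. No stratification is applied to the splits.

# The synthetic data generator

`simulate_dataset()` emulates the greenhouse study end to end: `n = 357`
accessions, `m = 2000` markers (allele frequencies uniform on
`maf_range`, Hardy-Weinberg dosages, no LD or population structure),
20 daily records of two traits, with exponential-like mean trajectories
specified through their projection on the quadratic Legendre basis (so the
fixed regression is well-specified; a deliberately misspecified
true-exponential option exists for robustness checks). Genetic coefficients
are drawn as $u \sim N(0, C\otimes G^\ast)$, where $G^\ast$ is the blended
GRM of the simulated genotypes — the generative covariance and the matrix
handed to analysis are the same object, so the full estimation loop is
exactly self-consistent.

The default $C$, $D$, $R(t)$ are built from a shared-trajectory factor
model: a common genetic factor $f(x) = 0.68 + 0.32x$ whose variance grows
over the imaging period, trait-specific intercept-level genetic variance,
and a small isotropic jitter keeping every matrix well conditioned. The
implied regime is the one the study design targets: WU heritability rising
from about 0.30 to 0.64, PSA from about 0.50 to 0.78 (WU below PSA at every
day), and a genomic correlation rising from 0.30 to about 0.80. Residual
variances decline mildly over time with a same-day cross-trait correlation
of 0.3.

Two generator-design points deserve an explicit record:

* **The permanent-environment share is deliberately modest** (3% and 2.5%
  of the per-trait scale, against 40–130% genetic). With unstructured
  synthetic kinship, the likelihood separates $C$ from $D$ only weakly (a
  Fisher-information calculation at $n = 250$, $m = 2000$ puts the
  standard error of the PE variance at the size of the parameter itself),
  so a generator with a large PE share would make its own recovery
  property unattainable regardless of sampler quality. With a modest
  share, any residual split ambiguity moves $h^2(t)$ by at most ~0.05.
* **What passing tests do and do not show.** The generator has no linkage
  disequilibrium, population structure, or family relatedness, so realized
  genomic relationships between training and testing accessions are weak
  (the projection ceiling of CV1 is far below what structured panels give),
  and the benefit of joint modelling for *projecting to unphenotyped
  accessions* is correspondingly small: with 20 daily records, training
  genetic values are already estimated at $r \approx 0.95$ from the target
  trait alone. The strong, robust multi-trait gains on synthetic data are
  those that do not depend on kinship structure: MT-RRM2's use of the
  testing accessions' secondary-trait records, and the forecasting
  scenario. Passing the synthetic cross-validation checks therefore
  demonstrates correctness of the machinery and the information pathways,
  not the magnitude of multi-trait gains on a real, structured diversity
  panel.

# Numerical choices

* Dosage columns are scaled by population variance; monomorphic markers are
  a hard error in `compute_grm()` (the generator drops zero-variance
  realizations before building its GRM).
* $G^{-1}$ is computed once per fit from the ridged/blended matrix;
  conditional precision matrices receive an escalating jitter retry only if
  a Cholesky fails outright.
* `genomic_correlation()` clips $|r_g| \le 1$ only for overshoot below
  $10^{-10}$ (anything larger errors), and reports days with zero genetic
  variance as missing.
* Gibbs reproducibility runs entirely through R's RNG — a single
  `set.seed()` reproduces chains exactly; cross-validation derives child
  seeds for every repeat and chain from the master seed.
* Sizes used by the packaged checks: parameter recovery runs 300 accessions
  x 20 days x 2 traits with a 30,000-iteration chain; cross-validation
  checks run 150/70 splits with 10 repeats and shortened chains. These are
  the package's chosen verification scales; the same functions run the full
  357-accession design unchanged.

# Known limitations

* Two traits at most (the bivariate case of the motivating design); the
  algebra generalizes but the residual-block and summary code paths are
  written for $n_{traits} \le 2$.
* No REML estimator; variance components come from the Gibbs sampler only.
* Missing-genotype imputation, LD pruning, and population-structure
  correction are out of scope; the PLINK adapter reads the text `.ped/.map`
  pair only.
* With weakly structured kinship the genetic / permanent-environment
  partition is poorly identified no matter the sampler; on such data the
  per-day heritability is trustworthy, the individual $C$-vs-$D$
  attribution less so.
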