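---
title: "Predicting hybrid values from parental genomic and phenomic data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hybrid values from parental genomic and phenomic data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridps)
```

## The problem

Hybrid maize breeding crosses inbred lines from two heterotic pools (dent
and flint). A hybrid's value decomposes into the general combining
abilities (GCA) of its two parents and a cross-specific deviation (SCA).
Genomic prediction estimates these from marker-based kinships; phenomic
selection replaces the markers by cheap near-infrared (NIR) spectra
measured on the parental lines, betting that tissue chemistry captures
genetic similarity. `hybridps` implements the full comparison pipeline:
relationship kernels from markers, pedigree or spectra; multi-kernel REML;
per-wavelength variance decomposition of the spectra; and two
cross-validation scenarios of increasing difficulty.

## Models

All prediction models share the linear mixed model

$$Y = 1_n\mu + Z_d\, g_{GCA_d} + Z_f\, g_{GCA_f} + Z_{df}\, g_{SCA} + \varepsilon,$$

with $g_{GCA_d} \sim N(0, K_{GCA_d}\sigma^2_d)$,
$g_{GCA_f} \sim N(0, K_{GCA_f}\sigma^2_f)$,
$g_{SCA} \sim N(0, K_{SCA}\sigma^2_{df})$ and
$\varepsilon \sim N(0, I\sigma^2_\varepsilon)$. The models differ only in
the kernels:

* **G-BLUP** — VanRaden method-1 kinship adapted to inbreds coded as
  allele shares 0/0.5/1,
  $K(i,i') = \sum_m (G_{im}-f_m)(G_{i'm}-f_m) \,/\, \sum_m f_m(1-f_m)$,
  with allele frequencies $f_m$ estimated within the pool
  (`vanraden_gca_kinship()`).
* **P-BLUP** — a family-structured pedigree relationship
  (`pedigree_kernel()`): one coefficient within families, one (constant)
  across families. This constancy is exactly why pedigree carries no
  information under family-holdout CV.
* **H-BLUP** — the spectral relationship $H = S^{*}S^{*\prime}/L$, where
  $S^*$ is the column-centered and -scaled matrix of pretreated spectra
  (first derivative of the normalized spectra) and $L$ the number of
  wavelengths (`spectral_relationship()`). Several spectra origins
  (tissue x trial) can enter one model as separate random effects
  (`standard_model_catalog()` builds the usual named set, including the
  combined and all-origin models).

For every source, the SCA kernel between crosses $(i \times j)$ and
$(i' \times j')$ is the product of the parental GCA entries
(`sca_kernel()`). All kernels are scaled so the sample variance of their
$n^2$ entries is 1 (`scale_unit_variance()`) — we read "sample variance of
the matrix" literally as the variance over all entries; the alternative
mean-diagonal normalization is used only inside the heritability scans
(below). Near-singular kernels get diagonal jitter
$|\lambda_{min}| + 10^{-6}$ (`ensure_psd()`).

## REML engine

`fit_reml()` estimates the variance components by average-information
(AI) REML. Each iteration forms $V = \sum_k \sigma^2_k Z_k C_k Z_k' +
\sigma^2_\varepsilon I$, the projection $P$, the score vector and the AI
matrix. The AI proposal uses an *active set*: components pushed below the
variance floor are pinned there and the system is re-solved for the rest,
which avoids the slow boundary crawl that plain clamping produces on
null-signal data. Remaining safeguards, in order: step halving (up to
$2^{-12}$), then an EM step, which always ascends. Convergence requires
the restricted log-likelihood change below `tol` ($10^{-8}$ by default)
and the relative change of all off-floor parameters below $10^{-6}$; a
flat likelihood over three consecutive iterations is also accepted, since
boundary components can dither indefinitely at machine precision. The
variance floor is $10^{-10}\,\mathrm{var}(y)$. The fixed part is an
intercept for the hybrid models, but `fit_reml()` accepts any fixed
design matrix; the wavelength adjustment uses genotype cell-means and the
bivariate model uses trial effects.

BLUPs are computed for *every* level of each kernel, including levels
without observations: $\hat u_k = \hat\sigma^2_k C_k Z_k' \hat V^{-1}(y -
X\hat\beta)$. Out-of-sample prediction (`predict_hybrids()`) is then a
lookup, and a new hybrid with zero kernel covariance to the training set
is predicted at the intercept. Tests verify the fitter against exhaustive
grid searches of the restricted likelihood, against the mixed-model
equations solved directly, and against `lme4` on the spatial-adjustment
model.

## Spectra preprocessing

The pretreatment chain is enforced by state tags
(`raw -> adjusted -> normalized -> derivative`):

1. `average_technical_replicates()` — arithmetic mean of the technical
   spectra within each microplot.
2. `adjust_wavelength_means()` — per wavelength, a mixed model with
   genotype (fixed for the reported means; random for heritability) and
   row and column random intercepts. This row+column model is our
   approximation of a smooth spatial surface fit: it captures the additive
   field trend, is exactly testable, and avoids re-implementing tensor
   P-spline machinery; a smooth-surface extension is deliberately out of
   scope. Broad-sense heritability per wavelength is the classical
   repeatability $\sigma^2_g / (\sigma^2_g + \sigma^2_e/\bar n_{rep})$.
   On unreplicated designs it is reported missing, with a warning.
3. `normalize_spectra()` — per-spectrum centering and scaling (the SNV
   convention). "Centered and scaled" is ambiguous between rows and
   columns; we read it per spectrum because the per-wavelength
   standardization demanded by the H matrix happens separately inside
   `spectral_relationship()`, and reading both as the same step would
   double-count one sentence of the pretreatment recipe.
4. `savitzky_golay_first_derivative()` — local least-squares polynomial
   derivative, default window 37 points and order 2. Edge wavelengths
   where the window does not fit are dropped (the grid shrinks by
   window−1 points): padding would invent data. The filter coefficients
   come from the `signal` package and are rescaled by the grid spacing;
   exactness on quadratics (tolerance $10^{-9}$) and linearity are tested.
   Non-uniform grids — real spectrometers change sampling interval along
   the range — must be resampled first (`resample_uniform()`, linear
   interpolation).

## Per-wavelength variance decomposition

For spectra observed in two trials, `scan_bivariate()` fits, per
wavelength, the bivariate polygenic model with trial fixed effects, genetic
covariance $\begin{pmatrix}\sigma^2_{u_1} & \sigma_{u_{12}}\\
\sigma_{u_{12}} & \sigma^2_{u_2}\end{pmatrix}\otimes K$ and heterogeneous
residuals, and reduces the estimates to across-site components: genetic
$\sigma^2_G = \sigma_{u_{12}}$, interaction $\sigma^2_{G\times E} =
\tfrac12(\sigma^2_{u_1}+\sigma^2_{u_2}) - \sigma_{u_{12}}$, residual
$\sigma^2_e = \tfrac12(\sigma^2_{e_1}+\sigma^2_{e_2})$
(`yamada_decomposition()`). The 2x2 genetic matrix is parameterized by its
Cholesky factor and fitted by direct likelihood optimization (Nelder-Mead,
then a BFGS polish), which keeps it positive semidefinite without
constraints; whether boundary estimates should instead be allowed is an
open modeling choice, and the Cholesky route is ours. A negative estimated
covariance (possible, since the factor's off-diagonal is unconstrained) is
floored at zero when proportions are formed — it means no detectable
genetic signal. Non-converged wavelengths are flagged, never interpolated.

Two conventions matter here. First, the kinship is normalized to mean
diagonal 1 inside the scans, so the genomic variance is on the phenotypic
scale and proportions are comparable across wavelengths — the standard
convention in genomic heritability estimation. Second, with a single trial
(`scan_univariate()`) GxE is not estimable and the genomic heritability
$\sigma^2_g/(\sigma^2_g+\sigma^2_e)$ absorbs it; the univariate scan
refuses fewer than 10 genotypes as unstable.

## Cross-validation scenarios

`make_cv_sparse()` draws seeded random k-fold partitions (default five
folds, five repetitions; remainders go to the lowest-index folds after the
shuffle). `make_cv_new_dent_flint()` enumerates (dent family x flint
family) pairs: the predicted set is the hybrids of that pair, the
calibration set excludes *both* families on their respective sides, and
only partitions with at least 10 predicted hybrids are kept. We implement
the family holdout as single-pair holdouts with two-sided exclusion — the
strictest reading of "parents from different families than the calibration
parents"; grouped multi-family holdouts would be a straightforward
extension. `run_scenario()` applies every model to byte-identical
partitions and records per-fold Pearson predictive ability. Undefined
correlations (numerically constant predictions, as for pedigree under
family holdout) are reported missing with a reason, never coerced to zero;
summaries show the count of defined folds.

## The synthetic-data generator

No real dataset ships with the package, so `simulate_dataset()` generates
one with the statistical structure the analysis assumes. The default
preset (`sim_config_maize()`) mirrors the study design this pipeline
targets: per pool, 4 founders crossed into 6 connected biparental
families, 15 doubled-haploid lines each (90 lines per pool), 10
chromosomes of 150 cM carrying 40 markers at uniform positions, a sparse
factorial with about 4 crosses per parent (~360 hybrids), and per-trait
variances $\sigma^2_{GCA_d} = \sigma^2_{GCA_f} = 1$, $\sigma^2_{SCA} =
0.25$, $\sigma^2_e = 1$ — GCA-dominated with a non-trivial SCA share, as
hybrid yield traits typically are.

Choices a user should know about:

* **Meiosis** uses the Haldane map function with no interference — the
  standard closed-form-testable choice; the line derivation is one meiosis
  plus doubling (DH) or iterated selfing (SSD), so SSD lines keep residual
  heterozygosity.
* **GCA architecture**: marker effects are i.i.d. normal on the
  frequency-centered genotypes, rescaled so the realized GCA variance over
  the pool's lines hits the target exactly. **SCA** is drawn directly from
  $N(0, K_{SCA}\sigma^2_{SCA})$ — the covariance the fitted model assumes —
  which keeps recovery experiments well-posed rather than testing a
  dominance model the pipeline never fits.
* **Spectra**: per wavelength, absorbance = baseline + $\sqrt{h^2_l}\,g$ +
  $\sqrt{gxe_l}\,d_t$ + residual, with $g$ a polygenic score (marker
  loadings smoothed along the wavelength grid by a moving average of width
  `smooth_width`, default 11 points — real spectra are smooth, and the
  exact spectral correlation is a free emulation knob), $d_t$ an
  independent trial-specific polygenic deviation and a smooth residual.
  The three parts are made sample-orthogonal per wavelength before
  scaling: with few founders, a pool's polygenic scores are dominated by
  family contrasts, and independent draws would otherwise be strongly
  correlated, corrupting the intended variance shares. After
  orthogonalization the shares equal `h2_profile` / `gxe_profile` exactly,
  and the round trip through `scan_bivariate()` recovers stepped profiles
  within ±0.1 at 60 genotypes and 150 wavelengths. The per-wavelength
  heritability-generating process of real spectra is unknown; profiles
  here are user-specified emulation targets, not estimates.
* **Field layout** (optional): plots on a near-square grid, a fraction of
  genotypes duplicated, additive random row and column effects and
  per-plot noise — enough structure to exercise the spatial adjustment,
  not a model of real field heterogeneity.

What passing tests on these data do *not* show: robustness to scatter
artifacts and instrument response of real NIRS, to selection during line
derivation, to non-additive marker architecture behind GCA, or to spatial
trends beyond additive row/column effects. The generator is a correctness
harness, not a field emulator.

## Problem sizes and runtime choices

The shipped analyses and tests use the preset factorial (90+90 parents,
~360 hybrids), 150-wavelength grids, 60-genotype scans for round-trip
recovery, 20 replicate simulations for the variance-recovery experiment
and 5 seeds for the scenario comparison — sizes at which every experiment
is stable yet the full suite completes in minutes on one core. All
generators are pure functions of `(config, seed)`; scans are per-wavelength
independent, so results are identical in any evaluation order.

## Known limitations

* The spatial adjustment is additive in rows and columns; smooth 2-D
  surfaces and the effective-dimension heritability of P-spline fits are
  not reproduced.
* The bivariate scan handles exactly two trials; more trials would need a
  multi-trial covariance model the pipeline does not fit.
* Pedigree kernels are the two-level family structure, not a full
  coancestry recursion; with real pedigrees, supply your own kernel via
  `kernel_matrix()`.
* Scenario conclusions on synthetic data are qualitative (orderings,
  identifiability), not quantitative forecasts of any real dataset's
  predictive ability.
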