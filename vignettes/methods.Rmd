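---
title: "Dissecting GWAS summary statistics by a conditioning trait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting GWAS summary statistics by a conditioning trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioslice)
```

## The problem

Two complex traits — here a binary focal trait such as schizophrenia and a
quantitative conditioning trait such as a composite loneliness/social-isolation
measure — can share predisposing common variation. `pleioslice` splits the
focal trait's GWAS summary statistics by each variant's behaviour in the
conditioning trait:

* **noLNL** — not associated with the conditioning trait (`p >= alpha`,
  default `alpha = 0.05`);
* **CONC** — associated (`p < alpha`) with the *same* effect sign on the
  shared effect allele in both traits;
* **DISC** — associated with *opposite* signs.

Because concordance is defined by strict sign inequalities, a variant whose
beta is exactly zero in either trait fits neither set; such variants are
labelled `excluded_zero_beta` rather than silently binned. The partition is
then pushed through four downstream analyses: clumping-and-thresholding
polygenic scores, stratified LD-score regression, annotation-stratified
cross-trait genetic covariance, and bidirectional two-sample Mendelian
randomization.

Signs are only comparable after harmonization. `harmonize_pair()` joins the
two tables on variant id, re-expresses trait 2 on trait 1's effect allele
(strand complements are resolved before declaring a mismatch; unresolvable
pairs are dropped, never guessed), and handles palindromic A/T and C/G
variants by policy. The default policy drops palindromic variants whose
effect-allele frequency is missing or falls in [0.42, 0.58] in either trait —
a common two-sample-MR default; the source analysis does not state its
palindrome handling, so this is a documented choice, not a reproduction.
Genomic coordinates are 1-based with closed intervals throughout; BED input is
converted on read. The extended-MHC default exclusion window is
chr6:25–34 Mb (GRCh37 convention), overridable.

## Polygenic scores

Scores are plain clumping-and-thresholding: greedy LD clumping (smallest p
retained as index, neighbours within `window_kb` with `r2 > r2_threshold`
removed; ties broken by chromosome, position, id, so results are independent
of row order), then `score_i = sum_j beta_j dosage_ij` over variants with
`p <= threshold`. Missing dosages impute as `2*eaf`, falling back to the
cohort mean. Scores are standardized over the full cohort, so the fitted
coefficient exponentiates to an odds ratio per SD.

Score performance is the increase in Nagelkerke pseudo-R² between logistic
models with and without the score,
\[
R^2_N = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}},
\]
with `L_0` the intercept-only likelihood. Observed-scale R² converts to the
liability scale with the ascertainment-corrected transformation of Lee et al.
(2012), parameterized by population prevalence `K` (default 0.01, the primary
analysis value; sex-specific prevalences 0.0079/0.0045 are exposed for the
sensitivity analysis) and sample case fraction `P`; at `P = K` it reduces to
the unascertained scaling `K(1-K)/z^2`. Confidence intervals for the delta-R²
use bootstrap resampling of individuals with the normal-interval method
(default 5000 replicates); failed replicates are redrawn, with a hard cap of
100 redraws. Decile profiles contrast each score decile against the median
5th decile by covariate-adjusted logistic regression; ties rank stably on
(score, id), and a decile with all cases or all controls reports a missing,
not infinite, OR.

The sex contrast follows the source procedure literally: within each sex,
bootstrap subsamples of 500 cases and 500 controls (reduced with a warning if
a stratum is smaller), liability-R² per subsample, and a two-sided t-test
*between the two bootstrap distributions*. That t-test treats resamples as
independent observations, so its p-value is strongly anti-conservative; it is
implemented exactly as described and the test suite therefore judges the
machinery by the sign and magnitude of the male–female gap, not by the
nominal rejection rate. Whether standardization should happen within strata
was left open by the source; scores standardize over the full cohort and each
bootstrap model refits covariates within the subsample.

## Stratified LD-score regression

LD scores come from a reference dosage panel:
`l(j,c) = sum_k r2_adj(j,k)` over same-chromosome variants within the window
(default 1000 kb), with the unbiased estimator
`r2_adj = r2 - (1-r2)/(n_ref - 2)` and an exact self-term of 1. The
heritability model is
\[
E[\chi^2_j] = N \textstyle\sum_c \tau_c\, \ell(j,c) + \text{intercept},
\]
fitted by two-pass weighted least squares: a first pass with overcounting
weights `1/max(l_total, 1)`, then weights
`1/(max(l_total,1) * max(1, chi2_hat)^2)` approximating the reference
implementation's heteroskedasticity correction. The intercept is always free.
Per-annotation heritability is `tau_c M_c`; enrichment is the h² share over
the SNP share, so the all-variants annotation has enrichment exactly 1.
Standard errors for every derived quantity come from a delete-one-block
jackknife over genome-contiguous blocks (default 200, auto-reduced for toy
genomes at 10 variants per block minimum). The tissue-contrast test compares
a gene-set annotation's tau inside versus outside a partition, one-sided,
with independence-approximated jackknife SEs.

Cross-trait covariance restricted to an annotation fits
`E[z_1 z_2] = sqrt(n1 n2) rho_c l(j,c)/M_c + c0` on the annotation's variants
by ordinary least squares, the free intercept absorbing sample overlap and
phenotypic correlation. This is cross-trait stratified LD-score regression
standing in for GNOVA's method-of-moments estimator — the estimand is the
same and inference is the same block jackknife; GNOVA's explicit
sample-overlap modelling is out of scope. Annotations under 50 variants are
refused rather than fitted.

## Mendelian randomization

Instruments are exposure variants at `p < 5e-8` (an explicit, never
automatic, fallback of `5e-6` mirrors the source's exception for one
under-instrumented trait), clumped at `r2 0.001` within 10 Mb, harmonized,
and oriented so every exposure beta is positive (the conventional Egger
orientation; unstated in the source and documented here). Five estimators
are provided: IVW (zero-intercept WLS, multiplicative random-effects SE with
the residual scale floored at 1), MR-Egger (free intercept; the intercept is
the directional-pleiotropy test; t reference with J-2 df), weighted median
(cumulative-weight interpolation at 0.5; parametric-bootstrap SE), and simple
and weighted mode (normal-kernel density of the Wald ratios, modified
Silverman bandwidth `0.9 min(sd, mad) J^{-1/5}` times a `phi` factor, default
1). Wald-ratio SEs use the first-order delta method `se_out/|beta_exp|`.
Diagnostics: Cochran's Q against chi-square with J-1 (IVW) or J-2 (Egger)
df, leave-one-out IVW refits, and MR-PRESSO's global residual-sum-of-squares
simulation test with Bonferroni per-instrument outlier flags and an
outlier-corrected IVW (the distortion test is not reproduced, matching the
source's reporting). `run_bidirectional()` swaps exposure and outcome roles
and applies Benjamini–Hochberg FDR across the direction-by-method grid.

## The synthetic world

`sim_config()` states the emulated study once: discovery GWAS sizes 82,315
(focal; 35,476 cases + 46,839 controls) and 487,647 (conditioning), a target
cohort of 1,927 cases and 1,561 controls, prevalence 1%, conditioning-trait
SNP-heritability 4.2%, and sharing parameters targeting a genetic correlation
of 0.17. With independently drawn shared-effect magnitudes the expected
genic correlation is `frac_shared * (2 f_conc - 1) * 2/pi`, so the defaults
`frac_shared = 0.4`, `f_conc = 0.834` target 0.17 in closed form. The focal
trait's liability h² defaults to 0.24, a typical SNP-heritability for
schizophrenia; the genome itself (2000 variants in AR(1) blocks of 20,
rho 0.9, MAF 0.05–0.5, blocks 2 Mb apart so clumping and LD windows never
span blocks) is a desk-scale stand-in and deliberately does not mimic real
human LD maps.

Genotypes arise from two latent AR(1) Gaussian haplotypes thresholded at
each variant's frequency. GWAS tables use exact LD-convolved marginal
effects per block (`beta_marg = R b`) plus block-correlated sampling noise at
the `1/sqrt(n)` scale — one-cohort marginal estimation in miniature. The
binary focal trait is emitted on the log-odds scale through the
liability-to-log-odds slope `dnorm(t)/(K(1-K))` rather than by simulating an
ascertained discovery cohort of PGC size, and the mode is recorded. The
target cohort draws fresh genotypes, builds liability as the standardized
genetic score plus normal residual, and ascertains cases above the upper-K
quantile. Liability is normalized to unit variance *within each sex*: the
female multiplier `sex_effect_scale` therefore reallocates the genetic share
of liability instead of silently multiplying female prevalence several-fold —
without this, sex-scaled worlds over-ascertain genetically unremarkable
female cases and the intended female-loaded score contrast is not even a
property of the generated data. Covariates (age, ten ancestry components)
are drawn independent of liability, so adjustment code paths are exercised
without confounding.

What a green test does and does not establish: recovery tests show the
estimators identify the architectures this generator produces — blocky LD,
normal effect sizes, no population structure, no assortative mating, no
uncorrected stratification. They do not certify behaviour on real cohort
data, reference-panel mismatch, or MAF-dependent architectures.

## Numerical choices and degenerate inputs

* p-values computed from z-scores clamp at 1e-300 so extreme associations
  never underflow to 0 and get dropped by the `(0,1]` field contract;
  user-supplied `p = 0` still violates the contract and is dropped.
* Boundary `p == alpha` is `noLNL` (the source states strict `< 0.05`).
* Clumping removes strictly `r2 > threshold`; a monomorphic index variant
  has no defined LD and removes nothing.
* A constant (or all-zero) score reports delta-R² 0; separation and
  non-convergence are hard errors, never silent fallbacks.
* `n_boot = 1` collapses the bootstrap CI to a point with a warning.
* Jackknife with a constant statistic reports SE 0 and p 0 with a
  degeneracy flag.
* One MR instrument collapses to its labelled Wald ratio; Egger and the
  median/mode estimators refuse below 3 instruments, MR-PRESSO below 4;
  flagging every instrument as an outlier is a hard error.

## Known limitations

The LDSC weighting scheme is an approximation of the reference tool's and is
exercised far from genome scale; enrichment estimates at a few hundred
variants carry large jackknife noise, and in dense-causal worlds with block
LD nearly every block is conditioning-associated, which genuinely (not
artifactually) compresses the enrichment contrast between partitions. The
cross-trait estimator absorbs sample overlap only through its intercept.
The t-test-on-bootstrap-distributions sex comparison is reproduced as
specified despite its anti-conservatism. No baseline-LD annotations,
continuous annotations, shrinkage scores, COJO-style selection, CAUSE, or
Steiger filtering.
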