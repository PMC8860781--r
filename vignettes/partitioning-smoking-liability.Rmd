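---
title: "Partitioning the genetic liability to smoking: methods and design choices"
author: "smokesub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning the genetic liability to smoking: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesub)
```

## The scientific problem

Educational attainment (EA) is both a phenotype and a genetic confounder of
smoking: many variants associated with lifetime smoking act, at least in part,
through the pathways that also shape education and socioeconomic status, and
gene--environment correlation (rGE) with neighborhood SES rides along with
them. `smokesub` implements a summary-statistics pipeline that separates the
two components. A mediation model is placed on the per-SNP associations: with
$a_j$ the SNP--EA association and $\beta_{smok,j}$ the SNP--smoking
association, a single genome-wide path $b$ carries EA's effect on smoking, and
the direct ("smoking-without-EA") association of SNP $j$ is

$$ c'_j = \beta_{smok,j} - b\, a_j . $$

Downstream, SBLUP-shrunk polygenic scores (PGS) from the three sets of
summary statistics (all-smoking, EA, smoking-without-EA) enter a ladder of
regression models against a neighborhood-environment measure, with
gene--environment interaction (G$\times$E) and rGE checks.

## Estimators

**Per-SNP association.** Ordinary least squares of the outcome on each SNP
dosage plus covariates, evaluated for all SNPs at once via the Frisch--Waugh
decomposition. The binary smoking indicator is analyzed on the observed scale
with the same linear model, mirroring what linear mixed-model GWAS tools do;
logistic regression is reserved for the individual-level PGS models. QC keeps
SNPs with MAF $\ge$ 1%, Hardy--Weinberg $p \ge 10^{-10}$ (1-df chi-square)
and call rate $\ge$ 95%, all boundaries inclusive, with failures attributed
in that order.

**LD score regression.** LD scores $\ell_j$ are sums of small-sample-adjusted
squared correlations $r^2 - (1-r^2)/(n-2)$ within an LD block. Heritability is
the slope of $\chi^2_j$ on $\ell_j$ times $m/N$, with a free intercept and a
single round of heteroskedasticity-weight updating
($w_j = 1/(\ell_j (1 + N \hat h^2 \ell_j / m)^2)$); fully iterating the
weights changes desk-scale estimates negligibly, so one round is used.
$N$ is the median per-SNP sample size, robust to per-SNP missingness.
Cross-trait covariance regresses $z_{1j} z_{2j}$ on $\ell_j$; its free
intercept absorbs the phenotypic correlation induced by complete sample
overlap. All standard errors are delete-one block jackknifes over 20
contiguous SNP blocks; the genetic correlation is clamped into $[-1, 1]$
with the raw value retained, since sampling noise can push the ratio outside
the bounds at desk scale.

**Mediation path and subtraction.** The genome-wide path is the ratio
$b = \widehat{gcov}(EA, smok)/\hat h^2_{EA}$, the algebraically equivalent
two-stage form of fitting the mediation model per SNP by weighted least
squares on a genetic covariance matrix; its SE propagates paired jackknife
pseudovalues of numerator and denominator. We treat $b$ as a single
genome-wide parameter — the standard subtraction practice — rather than
freeing it per SNP; the per-SNP alternative would make $c'$ identically zero.
The per-SNP subtraction variance is
$se_s^2 + b^2 se_e^2 + a_j^2 se_b^2 - 2 b\, r\, se_s se_e$, with $r$ the
cross-trait intercept clamped into $(-1, 1)$ so the quadratic form stays
positive; uncertainty in $b$ is propagated by default. Strand-ambiguous A/T
and C/G SNPs are dropped during allele harmonization, and swapped a1/a2
records are sign-flipped.

**SBLUP.** Joint weights solve $(N R_B + \lambda I) w_B = N \beta_B$ per LD
block with $\lambda = m (1 - h^2)/h^2$; the whole genome enters without a
p-value threshold. Because $R_B$ is a correlation matrix the system lives on
the standardized-genotype scale, so marginal betas are converted in by
$\sqrt{2 f (1-f)}$ and the weights converted back; this makes the solution
match the individual-level ridge estimator on standardized genotypes
(checked against a dense solve in the tests). Scores are sums of dosage
$\times$ weight, missing dosages replaced by twice the allele frequency, and
standardized in the scoring sample.

**The model ladder.** Model 0 is covariates only (age, sex, PCs, optionally
genotyping batch; sex keeps its 1 = male / 2 = female numeric coding); 1a
adds the all-smoking PGS, 1b the EA + smoking-without-EA pair, 2a/2b the
environment main effect, 3a/3b the PGS$\times$E terms flanked by the full
Keller covariate set (every PC$\times$E and PC$\times$PGS product), guarding
the interaction test against confounded interactions. All continuous
predictors are standardized before products are formed. With family
clustering the fits are exchangeable-GEE with robust sandwich SEs (written
in-package since no GEE library is assumed); because GEE has no likelihood,
$R^2$ — Nagelkerke for binary outcomes against the intercept-only model,
ordinary otherwise — is reported from a non-clustered refit of the same
design, for the null model as well. $\Delta R^2$ is taken against model 0.
PGS and environment terms are flagged at the displayed threshold
$p < 0.006$ (0.05 over 8 independent tests; the division is exact, 0.00625,
and rounding happens only in display). For a 15-trait correlation panel the
same exact division gives 0.00333, displayed 0.003 — we do not reproduce the
occasionally seen "0.05/15 = 0.002" rounding.

**rGE checks.** EA or the neighborhood measure is regressed on one PGS plus
covariates; the reported $R^2$ excludes age and sex (reduced refit on the PGS
and genetic covariates only), isolating the genetic share.

**Multiple imputation.** Exposure missingness is filled by proper
stochastic-regression imputation (coefficient draws from their asymptotic
normal, scaled-inverse-chi-square variance draws, residual noise added),
25 datasets by default, pooled by Rubin's rules
($T = W + (1 + 1/m) B$, t reference with Rubin degrees of freedom).

## The synthetic cohort generator

No restricted cohort data are needed anywhere: the generator emulates the
assumed causal structure directly.

* **LD**: within-block AR(1) latent-gamete correlation $\rho$, thresholded to
  alleles at the MAF quantile, dosage = two independent gametes. Blocks are
  independent, laid contiguously over up to 22 chromosomes at 100 kb spacing.
  This is the minimal structure that exercises clumping, LD score regression
  and SBLUP while keeping closed-form oracles (the implied dosage correlation
  is computable by enumerating the nine dosage-pair cells over the bivariate
  normal).
* **Phenotypes**: $EA = G_{ea} + e_1$ with $\mathrm{var}(G_{ea})$ scaled to
  exactly $h^2_{ea}$; exposure $= \gamma\,\mathrm{std}(G_{ea}) + e_2$ (rGE by
  construction); smoking liability
  $L = G_{dir} + b\,EA + \delta\,\mathrm{std}(G_{dir})\mathrm{std}(E) + e_3$
  with the residual sized so $\mathrm{var}(L) = 1$, and the binary smoker
  flag thresholded at the empirical $1 - K$ quantile. A configuration whose
  variance contributions exceed 1 is rejected. The liability column is kept
  in the output: path coefficients are defined on the liability scale, and
  analyzing the thresholded binary attenuates the observed-scale genetic
  covariance by roughly $\phi(\tau)/\sqrt{K(1-K)}$, which is the package's
  reason for running liability-scale GWAS in its own calibration studies
  while analyzing the binary trait in the individual-level models, as the
  study design it emulates does.
* **Defaults** follow the emulated system: EA heritability 0.142, direct
  smoking heritability 0.072, mediation path $-0.375$ (total smoking
  $h^2 \approx 0.092$ and a negative EA--smoking genetic correlation), rGE
  path sized for about 2% of exposure variance, prevalence 0.43, exposure
  missingness 10.3% (missing-at-random, tilted by age so the MI stage is
  well-posed), no generative interaction. Age, sex, PCs and batch are drawn
  independently of genotype, so PCs carry no confounding by default. Family
  granularity is a free parameter (`cluster_size`), since twin-pair versus
  extended-pedigree structure is not fixed by the design we emulate.

What the generator does **not** emulate: realistic human LD maps,
imputation-quality variation, the X chromosome, population stratification,
or assortment. Passing calibration therefore demonstrates internal
consistency of the estimators under the assumed model, not robustness to the
full messiness of real cohorts.

## Calibration studies and problem sizes

The `study_*` functions rerun each stage end-to-end on fresh cohorts; the
test suite and `scripts/acceptance.R` call them at these sizes:

* Subtraction recovery: 20 replicates of $n = 8000 \times m = 2000$ with
  $b = 0.4$ and full mediation. The study sets
  $h^2_{ea} = h^2_{dir} = 0.5$ with 200 LD blocks ($\rho = 0.95$): at low
  heritability or few blocks the ratio $\widehat{gcov}/\hat h^2_{EA}$ is
  dominated by realized-architecture noise (the chi-square/LD-score slope is
  identified from between-block contrast, and 2000 SNPs carry only as many
  independent architecture draws as blocks), so this is a deliberate
  identifiability choice of the study design. Expected
  $r_g(\text{subtracted}, \text{smoking}) = \sqrt{0.5/0.58} \approx 0.93$
  under these conditions, and $r_g(\text{subtracted}, EA) \approx 0$.
* LDSC calibration: 20 replicates each at generative $h^2 = 0.5$ and $0$,
  $n = 4000 \times m = 2000$; complete-overlap null-rg study at the same
  size.
* SBLUP oracle: one $500 \times 50$ block, weight correlation with the dense
  ridge solve.
* G$\times$E: 500 null Keller-covariate logistic fits at $n = 2000$
  (type-I error), 50 replicates at $n = 10{,}000$ with $\delta = 0.15$
  (sign recovery). The PGS here is built from the true direct effects, so
  the study isolates the test's calibration from PGS estimation noise.
* Multiple imputation: 50 replicates of $n = 1000$ with 10% MCAR
  missingness, 10 imputations each, pooled-CI coverage of the true slope.

## Numerical choices and degenerate inputs

* Monomorphic SNPs return HWE $p = 1$ (no information) and are excluded by
  the MAF filter; monomorphic dosage columns get $se = \infty$, $z = 0$ in
  the GWAS rather than NaN.
* Missing dosages are mean-imputed within SNP after call-rate filtering for
  association, and frequency-imputed ($2f$) for scoring.
* Jackknife blocks are contiguous in SNP order; at least 2 blocks, default
  20; the mediation-path jackknife requires numerator and denominator to
  share the same partition and errors otherwise.
* Clumping ties break by p-value then SNP id, making locus output invariant
  to input row order.
* The GEE working correlation is moment-estimated from Pearson residual
  cross-products, clamped into $[0, 0.99]$; singleton-only cluster sets
  reduce exactly to the independence fit, and a single all-encompassing
  cluster is rejected.
* Zero-variance polygenic scores (all-zero weights) raise an explicit
  standardization error instead of emitting NaNs.

## Limitations

The estimators are validated under the generator's own assumptions. The
AR(1)-block LD model has no long-range LD, so the clumping distance rule is
exercised only across blocks; observed-scale heritability for the binary
trait is reported without a liability transform, matching the reporting
convention of the emulated design; and the in-sample LD reference for SBLUP
avoids reference-mismatch noise that a real application would face. The CLI
(`smokesub_cli()`, installed as `exec/smokesub`) is a thin wrapper over the
same functions and adds no behavior of its own.
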