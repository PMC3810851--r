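---
title: "Direct imputation of summary-statistic Z-scores: model and methods"
author: "zimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct imputation of summary-statistic Z-scores: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zimpute)
```

## The problem

A GWAS or meta-analysis reports a signed standard-normal statistic
$Z_j$ for each genotyped SNP, but only a fraction of the SNPs segregating
in the population are genotyped. Genotype-imputation pipelines fill the
gaps by reconstructing subject-level genotypes at untyped sites, which
requires access to individual genotypes and considerable computation.
When only the summary statistics are available — the common case for
published meta-analyses, and the only case for many family studies —
the statistics themselves can be imputed directly.

The statistical basis is that, under the null hypothesis of no
association, the vector of Z-scores at a set of nearby SNPs is
asymptotically multivariate normal with mean zero and correlation matrix
equal to the linkage-disequilibrium (LD) correlation of the underlying
genotypes. Writing $Z_t$ for the typed statistics, $\Sigma_{tt}$ for the
typed–typed LD correlation block and $\Sigma_{ut}$ for the
untyped–typed block, the conditional expectation of the untyped
statistics is

$$
\hat{Z}_u \;=\; \Sigma_{ut}\,\Sigma_{tt}^{-1}\,Z_t ,
$$

and the null-hypothesis variance of each imputed statistic,

$$
r^2_{\text{pred},i} \;=\; \big[\Sigma_{ut}\,\Sigma_{tt}^{-1}\,\Sigma_{tu}\big]_{ii} \in [0,1],
$$

serves as its imputation-quality score: it is the fraction of the unit
null variance of $Z_{u,i}$ that the typed neighbours explain. Both
quantities need only the summary statistics and a reference panel that
supplies the LD structure — no subject-level data. Because the
correlation of null statistics does not depend on relatedness among the
study subjects, statistics originating from family-based association
tests can be imputed the same way; this package consumes Z-scores from
any source.

## Windowed computation

Inverting one chromosome-wide $\Sigma_{tt}$ is unnecessary because LD is
local. The package partitions each chromosome's typed SNPs into
consecutive *prediction windows* of `pred_size` SNPs and extends each by
`flank_size` typed SNPs on either side (the *extended window*); the
conditional mean for the untyped SNPs assigned to a prediction window is
computed from the typed SNPs of its extended window only. Untyped SNPs
are assigned to windows by a half-open rule on position (a SNP belongs
to the window whose first core SNP is the last one not after it;
upstream SNPs join the first window, downstream the last), so every
untyped SNP is imputed exactly once. When the extended window spans all
typed SNPs the result provably equals the one-shot full-matrix answer,
and the test suite asserts that equality to 1e-10.

Defaults are `pred_size = 100` and `flank_size = 250` typed SNPs per
side. These are this package's own choices: windows an order of
magnitude wider than typical LD blocks make the truncation error
negligible while keeping each solve at a few hundred variables.

## Numerical choices

* **Solver.** $\Sigma_{tt} + \lambda I$ is factorized by Cholesky;
  the conditional mean and the $r^2_{\text{pred}}$ diagonal come from
  triangular solves. No explicit inverse is formed.
* **Ridge `lam`.** LD blocks estimated from a finite panel are often
  numerically singular (perfectly correlated SNP pairs are common).
  The default `lam = 1e-3` on the correlation scale makes the solve
  well-posed while perturbing well-conditioned answers below reporting
  precision; `lam = 0` is available and raises an informative error on
  a singular block. With `lam > 0`, $r^2_{\text{pred}}$ is computed with
  the same ridge, so it remains the null variance of the reported
  statistic; it shrinks relative to `lam = 0`.
* **Collinearity rescue.** If a window's block still fails the
  positive-definiteness check, one member of each typed pair with
  $|r| > 0.999$ is pruned (the lower-position SNP is kept — a
  deterministic tie-break) and the window is retried.
* **Reporting.** The imputed value is the raw conditional mean, the
  literal conditional expectation; the variance-standardized convention
  $\hat{Z}_u / \sqrt{r^2_{\text{pred}}}$ is available behind
  `rescale = TRUE` as an extra column, since both conventions circulate
  in the literature. Targets with $r^2_{\text{pred}}$ below
  `min_r2pred` (default 0.3) are reported as `skipped` with no
  statistic: a low-information imputation is more misleading than a
  missing one. The threshold is recorded in the output header.
* **p↔Z conversion.** Files carrying two-sided p-values with an effect
  direction are converted by $Z = d\,\Phi^{-1}(1-p/2)$; only this
  two-sided normal conversion is implemented (a chi-square 1-df
  statistic should be converted upstream, as it carries no sign).
  p-values below ~1e-300 are clamped with a warning. When a file
  carries both and they disagree beyond 1e-3 relative, the Z is
  trusted (it carries the sign natively) and a warning is issued.

## Allele harmonization

Panel and summary records are matched by (chromosome, position) after
stripping any `chr` prefix; rsIDs are ignored because they drift across
builds. The effect allele is reconciled against the panel's alternate
allele: a swapped pair negates $Z$, a reverse-complement pair is
strand-flipped first, and A/T and C/G SNPs — whose strand cannot be
resolved from the alleles alone — are dropped unless `keep_ambiguous`
is set. Irreconcilable pairs are dropped with a warning, never silently
kept. After harmonization every statistic is oriented to the panel's
alternate allele, which is what makes $Z_t$ and the LD blocks coherent;
the whole pipeline is invariant to flipping the allele labels (and $Z$
sign) of the input records, a property the tests assert end to end.

## LD estimation and the cache

LD is the Pearson correlation of haplotype 0/1 allele indicators across
the panel's phased haplotypes. Haplotype indicators (rather than
diploid dosages) are the finer-grained estimator, and their correlation
equals the dosage correlation in expectation under Hardy–Weinberg
equilibrium. Sites with minor-allele frequency below `maf_min`
(default 0.005) are dropped at panel load: near-monomorphic sites give
unstable correlation estimates. Only biallelic SNVs are supported,
since a summary statistic carries a single effect allele.

For repeated runs against the same panel, the per-window blocks can be
precomputed with `save_corr_cache()`. The cache is an RDS file keyed by
a panel content checksum and the window parameters; a mismatch on
either refuses to load with instructions to recompute, and imputing
from a valid cache is bit-identical to imputing from the panel.

## The simulator

`simulate_gwas()` generates the full experiment the accuracy claims are
evaluated on, at desk scale:

1. **Panel.** Alternate-allele frequencies follow a U-shaped
   Beta(0.5, 0.5) law rescaled to (0.01, 0.5), made locally similar
   along the chromosome through a latent AR(1) copula
   (`freq_rho = 0.90`) — in real panels, SNPs in strong LD have similar
   frequencies. Founder haplotypes (default 16) are thresholded from
   latent Gaussian AR(1) processes (`founder_rho = 0.99`), and the
   remaining haplotypes are mosaics of the founders with per-site
   switch probability `ld_decay = 0.01`. A plain mosaic over founders
   with site-independent alleles cannot exceed adjacent-SNP
   correlations of order $1/\sqrt{n_\text{founder}}$, which is why the
   founders themselves carry autocorrelated alleles. The defaults were
   calibrated once so the mean adjacent-SNP $|r|$ is approximately 0.8,
   and the limits behave as expected: `ld_decay = 0` with two founders
   duplicates founders exactly, `ld_decay = 1` leaves only weak
   residual correlation of order $1/n_\text{founder}$.
2. **Study.** Each subject's genotype is the sum of two haplotypes
   drawn uniformly with replacement from the panel pool, so study and
   reference populations are matched *by construction*. This isolates
   imputation error from population mismatch; it is the regime in which
   the method's accuracy claim applies, and mismatch can be emulated by
   simulating the study from a different seed's panel.
3. **Phenotype.** `n_causal` SNPs (default 10) receive Gaussian
   effects rescaled so they explain `h2` (default 0.3) of the unit
   phenotypic variance.
4. **Association.** Per-SNP Z-scores come from the simple-regression
   Wald statistic mapped through the exact t-to-normal quantile
   correspondence, so null statistics are exactly standard normal at
   any sample size.
5. **Masking.** A fraction `mask_frac` (default 5%) of SNPs have their
   statistics withheld and become imputation targets. Optionally,
   masking is restricted to SNPs with a typed LD partner at
   $|r| \ge$ `mask_min_r` (searched within a 50-SNP band), with a
   greedy selection that never strips a previously masked SNP of its
   last typed partner — the regime mirroring imputation of
   known-associated SNPs that have good tag SNPs on arrays.

All randomness flows through `seed`, with fixed per-stage offsets so
each stage is individually reproducible; replicate $r$ of an experiment
uses `seed + r`.

**What the simulator does not emulate.** Mutation/genotyping error,
cryptic relatedness, population stratification between study and panel,
long-range LD (e.g. the MHC), strand errors, and indels/multiallelics
are all absent. Passing tests on these simulations therefore
demonstrate the correctness and calibration of the conditional-mean
machinery under a matched panel with strong local LD — not robustness
to panel mismatch, for which genotype-level imputation remains the
better tool and against which imputed signals should be followed up.

## Evaluation

`evaluate_accuracy()` scores imputed against held-out true Z-scores by
squared Pearson correlation — a tracking metric that deliberately
ignores additive bias (the tests pin this down with a shifted-truth
case). `run_accuracy_experiment()` pools pairs over seeded replicates.
The reference experiment the package ships in `scripts/acceptance.R`
uses a 1,000-haplotype panel over 2,000 drawn SNPs (about 1,450 remain
polymorphic given the 16-founder pool and the MAF floor), 2,000
subjects, 10 causal SNPs at $h^2 = 0.3$, 5% masking restricted to
$|r| \ge 0.8$ tags, pooled over 25 replicates; the suite's calibration
check uses 500 permutation replicates on a 600-haplotype, 250-SNP,
800-subject scene. These problem sizes were chosen so the full suite
runs in minutes on a laptop while leaving the pooled correlation
estimate with negligible Monte-Carlo error.

```{r example, eval = FALSE}
cfg <- sim_config(mask_min_r = 0.8, seed = 1)
sim <- simulate_gwas(cfg)
fit <- impute_sumstats(sim$observed, sim$panel)
glance(fit)
acc <- evaluate_accuracy(fit, sim$masked)
glance(acc)
autoplot(acc)
```

## Known limitations

* One reference population at a time; no cross-population LD mixing,
  no genome-build liftover, no frequency-based resolution of
  strand-ambiguous SNPs (they are simply dropped by default).
* The null MVN argument is asymptotic in the study sample size; with
  very small studies the t-to-normal mapping of the simulator is exact
  but real summary statistics may not be.
* Windows never span chromosome boundaries, and regions with LD longer
  than the extended window lose information; widening `flank_size` is
  the remedy at a quadratic cost in solve time.
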