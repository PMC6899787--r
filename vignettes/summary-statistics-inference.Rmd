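---
title: "Methods: summary-statistics inference from GWAS to causal estimates"
author: "gwasmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics inference from GWAS to causal estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasmr)
options(gwasmr.verbose = FALSE)
```

# Scope and assumptions

`gwasmr` implements the full chain of analyses that can be run on GWAS
*summary* statistics alone: multi-cohort meta-analysis of a standardized
quantitative trait (the motivating case is a circulating protein measured
in SD units across four cohorts), locus definition and an approximate
conditional scan, simplified LD-score regression, and two-sample Mendelian
randomization (MR) with colocalization against outcome traits measured in
other, non-overlapping samples.

The standing assumptions are the usual ones for this literature:

* Per-variant effects are small, so the sampling distribution of
  $\hat\beta_j$ is normal with known standard error, and two-sided
  p-values can be computed on the normal scale.
* All files report alleles on the forward strand and coordinates on a
  single genome build; the aligner therefore never attempts
  strand-complement rescue *across cohorts of the same trait*
  (ambiguous pairs are dropped and counted). The exposure–outcome
  harmonizer, which faces data from unrelated consortia, does try the
  complement before dropping a non-palindromic mismatch.
* Exposure and outcome samples do not overlap (two-sample MR), and the
  instruments act on the outcome only through the exposure except where
  pleiotropy is explicitly modelled (Egger) or detected (radial Q).

# Meta-analysis

Fixed-effects pooling uses inverse-variance weights $w_i = 1/se_i^2$;
random effects add the DerSimonian–Laird moment estimator
$\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i)\}$.
DerSimonian–Laird was chosen because it is the moment estimator virtually
every GWAS meta-analysis tool implements; with homogeneous inputs
($Q \le k-1$) it truncates to zero and reproduces the fixed-effects
answer, which is the behaviour reported for well-behaved protein loci.
Heterogeneity is summarised by Cochran's $Q$, its $\chi^2_{k-1}$ p-value
and $I^2 = \max\{0, (Q-(k-1))/Q\}$; a single study returns $Q = I^2 = 0$
rather than `NA` so downstream tables stay rectangular.

Per-variant variance explained uses
$r^2 = \beta^2 / (\beta^2 + N\,se^2)$, the identity that maps an
association z-score on a standardized phenotype to a squared semi-partial
correlation. It reproduces published per-locus values (e.g. a lead variant
with $\beta = 0.205$, $se = 0.014$, $N = 10{,}584$ explains 1.99% of the
phenotype) to the printed precision, which is how the formula was fixed.

The genomic inflation factor is
$\lambda = \mathrm{median}(\chi^2) / F^{-1}_{\chi^2_1}(0.5)$ with the
exact $\chi^2_1$ median `qchisq(0.5, 1)` $\approx 0.45494$. Extreme
associations are additionally reported as $\log_{10} p$ computed from the
normal log-tail, so nothing underflows below $p \approx 10^{-308}$.

**Loci.** Greedy clumping: repeatedly take the smallest-p unassigned
variant below the threshold (default $5\times10^{-8}$) and absorb every
significant variant within a window of it on the same chromosome. The
window default is $\pm 500$ kb — a conventional clumping radius; it is a
free parameter because locus architecture varies.

**Conditional scan.** On the standardized-genotype scale
($b^{std} = \beta\sqrt{2f(1-f)}$), conditioning variant $j$ on a lead with
LD correlation $r$ gives
$\beta_{j|lead} = (\beta_j - r\,\beta_{lead})/(1-r^2)$ and
$se_{j|lead} = se_j/\sqrt{1-r^2}$ — the two-variant normal-equations
solution using an external LD reference in place of genotypes. Variants
with $r^2 > 0.9$ to the lead are flagged `ignored` (the collinearity cutoff
used by the standard conditional-analysis software), and variants more
than 10 Mb away are assumed in linkage equilibrium and returned untouched.
The tests verify agreement with two-SNP OLS on simulated individual-level
data ($n = 5000$) within 2 standard errors for $r \in \{0, 0.3, 0.5, 0.8\}$.

# LD-score regression (simplified)

LD scores are $\ell_j = \sum_k r^2_{jk}$ over variants within a window
(self included, so $\ell_j \ge 1$). The regression model is
$E[\chi^2_j] = a + (N h^2 / M)\,\ell_j$: the intercept $a$ absorbs
confounding inflation, and the slope rescaled by $M/N$ is the SNP
heritability. Weights follow standard two-pass practice — a first
unweighted pass, then $1/(2(a + N h^2 \ell_j/M)^2)$, the inverse variance
of a scaled $\chi^2_1$ — with the fitted mean floored at 0.1 so a wildly
negative first pass cannot produce negative weights. An unweighted flag
exists because exact line-recovery tests are only exact without
heteroskedasticity weights. Standard errors come from a delete-one-block
jackknife over 200 contiguous blocks (jackknife because adjacent variants
are correlated through LD, so i.i.d. formulas understate the error).
Estimated $h^2$ outside $[0,1]$ is flagged, never clipped.

This is deliberately a *lite* implementation: no partitioned heritability,
no cross-trait genetic correlation, no reference-panel LD-score files —
the regression itself, which is what the inference chain needs, on LD
scores the caller supplies.

# Harmonization and Steiger filtering

Outcome records are rotated onto the exposure's effect allele (beta
negated, EAF complemented when the allele pair is swapped). Palindromic
variants (A/T, C/G) cannot be strand-resolved from alleles, so under the
default `infer` policy the orientation is chosen to put both EAFs on the
same side of 0.5 — unless either EAF falls inside the ambiguity band,
default $(0.42, 0.58)$, in which case the variant is dropped. The band is
configurable; 0.42–0.58 is the conventional compromise between losing
instruments and risking a silent strand flip.

Steiger filtering retains instruments explaining strictly more variance in
the exposure than in the outcome, with $r^2 = z^2/(z^2+n)$ per side and a
Fisher-z test for the difference. The default applies no p-value gate —
the retention rule is the pure $r^2$ comparison, with `alpha` available as
an optional gate — because directionality counts, not significance
thresholds, are what the filter is for.

LD proxies are selected as the candidate with maximal $r^2 \ge 0.8$, ties
broken by physical distance then rsid; a proxy's own alleles are used
as-is (no allele translation across proxies).

# MR estimator suite

With per-SNP Wald ratios $r_j = \beta_{out,j}/\beta_{exp,j}$ and
first-order ratio SEs $se_{out,j}/|\beta_{exp,j}|$:

* **IVW** is the zero-intercept weighted regression of outcome on exposure
  effects (weights $1/se_{out}^2$), algebraically the inverse-variance
  weighted mean of the ratios. The random-effects flavour uses the
  multiplicative over-dispersion model with the inflation
  $\sqrt{Q/(k-1)}$ floored at 1 — the standard two-sample convention; the
  floor makes it conservative (never anti-conservative) under homogeneity,
  which is visible in the type-I-error simulations (rejection rate ~0.04
  at nominal 0.05).
* **MR-Egger** re-orients every instrument to its exposure-increasing
  allele, then fits a weighted regression *with* intercept: the slope is
  the pleiotropy-adjusted causal effect, the intercept estimates mean
  directional pleiotropy. SE inflation uses $k-2$ degrees of freedom.
  Egger is only attempted with $\ge 3$ instruments.
* **Weighted median** interpolates the inverse-variance-weighted ordered
  ratios at cumulative weight 0.5; its SE is a parametric bootstrap
  (default 1000 draws, seed mandatory).
* **Radial outliers**: per-SNP contributions $q_j = w_j (r_j-\hat\theta)^2$
  with $w_j = \beta_{exp,j}^2/se_{out,j}^2$ sum exactly to the model's
  Cochran $Q$; SNPs with $\chi^2_1$ tail p below `alpha` (default 0.05)
  are flagged, and the orchestrator optionally re-fits IVW without them.

`run_mr_suite()` composes harmonization, optional Steiger filtering, every
estimator whose instrument-count precondition holds, and the outlier-removal
re-fit, and degrades explicitly: with two instruments it reports IVW and
per-SNP Wald ratios and marks the regression-based estimators "not
applicable", mirroring the real situation of a two-instrument protein
GWAS. Binary outcomes are analysed on the log-odds scale and exponentiated
only in the display table.

# Colocalization

Per-SNP Wakefield log approximate Bayes factors
$\mathrm{lABF} = \tfrac12[\ln(V/(V+W)) + z^2 W/(V+W)]$ feed the
five-hypothesis posterior under the single-causal-variant assumption.
Priors default to $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, the
conventional coloc defaults, and the colocalization call uses
PP4 $\ge 0.80$. Effect-size prior SDs default to 0.15 for quantitative
traits and 0.2 for case-control (log-odds) traits; the beta/se ABF input
was chosen over the frequency-based variant because it is self-contained —
no external allele-frequency panel enters the calculation.

All hypothesis sums run in log space. One numerical subtlety: the H3 term
sums $e^{l_{1i}+l_{2j}}$ over *distinct* pairs, and forming it as
"(sum over all pairs) minus (matched pairs)" cancels catastrophically
exactly when one SNP dominates both traits — the common colocalized case.
The implementation instead forms leave-one-out inner sums in max-scaled
linear space and re-evaluates the handful of dominant indices with an
explicit log-sum-exp over the remaining terms, which matches brute-force
enumeration to better than $10^{-10}$ in log posterior for small regions
and stays finite for $|z|$ up to 50.

# What the synthetic generator does and does not emulate

The generator reproduces the *structure* of the motivating study: four
exposure cohorts of 7292, 1041, 1316 and 935 participants (the last
emitted without an imputation-quality score, like a sequenced cohort);
LD as block-diagonal AR(1) correlation ($r_{jk} = \rho^{|j-k|}$ within a
block); one causal variant per sampled block with standardized joint
effects scaled to a target exposure $h^2$; marginal effects obtained as
$R b$; outcome effects $\theta \times$ exposure-marginals plus
LD-convolved pleiotropy plus sampling noise at a biobank-scale sample
size (default 426,824). Summary statistics are simulated directly — the
sampling model $\hat\beta_j \sim N(\beta_j^{marg}, 1/(2f_j(1-f_j)n))$ —
because that is orders of magnitude faster than genotype simulation and
exact for the quantities the estimators consume; a small-$n$
individual-level mode (multivariate-normal genotypes) exists solely as
the oracle for the conditional scan.

For instrument-level estimator studies, `simulate_mr_instruments()` draws
per-instrument variance contributions from an exponential distribution.
This heavy-tailed choice matters: with near-equal instrument strengths
MR-Egger is weakly identified (the regression has almost no spread in its
design variable — the low-$I^2_{GX}$ regime) and dilutes noticeably, which
is a property of the estimator, not a bug; GWAS hit lists in practice span
an order of magnitude in effect size, and the generator reflects that.
Instruments are oriented to the exposure-increasing allele, the standard
convention, so planted directional pleiotropy keeps a coherent sign.

Not emulated: realistic genome-wide LD from reference panels, population
structure, relatedness, covariates, sample overlap between exposure and
outcome, and INDELs. Passing recovery tests on this generator therefore
demonstrates the estimators' correctness under their own assumptions — it
does not certify robustness to confounding structures the generator never
produces.

# Numerical and policy choices

* QC filters are strict inequalities (MAF > 0.01, info > 0.8): boundary
  values are removed. Records with no imputation score survive only when
  `info_min = 0` (sequenced cohorts).
* Within-panel duplicate variant keys keep the smallest-SE record; keys
  prefer rsid and fall back to chrom:pos (1-based).
* Pooled EAF is the sample-size-weighted cohort mean.
* Wald-ratio SEs default to the first-order delta method; the
  second-order factor $\sqrt{1 + \beta_{out}^2 se_{exp}^2 /
  (\beta_{exp}^2 se_{out}^2)}$ is available by flag and is validated
  against a Monte-Carlo delta oracle in the tests.
* Every stochastic routine takes an explicit seed; generators are pure
  functions of (configuration, seed), with per-cohort streams derived by
  hashing the cohort label, and internal seeding restores the caller's
  RNG state.
* Test and acceptance problem sizes were chosen to make Monte-Carlo error
  a small fraction of each tolerance while keeping the default suite
  around a minute: LDSC recovery uses $M = 20{,}000$ SNPs,
  $N = 10{,}000$, 200 replicates; the estimator-recovery grid uses
  $n = 50{,}000$ per side with 40–60 replicates per cell; IVW type-I
  error uses 2000 null replicates; the conditional-scan oracle uses
  $n = 5000$ individuals.

# Known limitations

* The conditional scan conditions on a single lead (no stepwise joint
  model selection), and its SE ignores the uncertainty of the LD
  reference.
* DerSimonian–Laird $\tau^2$ is the only random-effects estimator
  offered; REML/Paule–Mandel variants are out of scope.
* LDSC-lite assumes the supplied LD scores are correct and complete; it
  does not filter to a HapMap-style SNP list or correct for attenuation.
* The weighted median's bootstrap SE is parametric (normal resampling of
  the summary effects), not a resampling of instruments.
* Colocalization assumes at most one causal variant per trait per region;
  multi-causal regions require conditioning before coloc, which this
  package supports only through the single-lead conditional scan.
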