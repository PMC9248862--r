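---
title: "Two-sample Mendelian randomization with mr2s: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mr2s}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mr2s)
```

## The causal model

Mendelian randomization treats genetic variants as instrumental variables
for an exposure. A variant $j$ is a valid instrument if it (i) associates
with the exposure, (ii) is independent of exposure–outcome confounders, and
(iii) affects the outcome only through the exposure. Under those assumptions
and an (approximately) linear causal model, the per-SNP summary statistics
from two non-overlapping GWAS — exposure effects $\hat\gamma_j$ with
standard errors $\sigma_{x,j}$ and outcome (log-odds) effects
$\hat\Gamma_j$ with standard errors $\sigma_{y,j}$ — identify the causal
effect $\theta$ through $\Gamma_j = \theta\,\gamma_j$, so each SNP
contributes a Wald ratio $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$.

The packaged worked example instruments circulating
25-hydroxyvitamin D (natural-log scale, unit SD) with six SNPs and asks
whether it causally affects atrial fibrillation; all estimates are log-odds
(reported as odds ratios) per unit increase in log 25(OH)D.

```{r}
tabs <- mr_example_tables()
h <- harmonize(tabs$exposure, tabs$outcome)
mr_fit(h, seed = 7)
```

## Harmonization

The two studies rarely code a variant on the same allele. `harmonize()`
aligns every outcome record to the exposure study's effect allele: a swapped
allele order negates the outcome beta and complements its frequency; a
strand-complemented coding (A$\leftrightarrow$T, C$\leftrightarrow$G) is
first complemented and then treated the same way. Palindromic variants
(A/T, C/G) are the hard case — their labels cannot distinguish a strand flip
from an allele swap — so orientation is inferred from allele-frequency
agreement, and only when both studies' frequencies are farther than
`palindromic_maf_limit` from 0.5. The default limit of 0.08 (EAF outside
[0.42, 0.58]) is the conventional compromise: tighter limits discard usable
variants, looser ones risk silent mis-orientation, and near 0.5 the data
simply do not carry the answer, so such SNPs are dropped with an explicit
reason rather than guessed at.

After alignment the two frequencies of the common allele should roughly
agree; `eaf_tolerance` (default 0.2) is deliberately warning-only — a large
discordance usually means mismatched genome builds or mislabeled alleles and
deserves a human look, but frequencies also genuinely differ between
cohorts, so the record is flagged, not deleted. In the packaged table the
harmonization is a real step: two of the six outcome records arrive coded on
the opposite allele and are flipped, and the C/G variant rs8018720 is
resolved by frequency (0.82 vs 0.81).

A SNP with a zero exposure beta has no Wald ratio and is dropped with a
reason instead of raising an error, so batch runs on synthetic data survive
degenerate draws.

## Instrument strength

For a unit-SD exposure, variant $j$ explains
$R^2_j = 2\,p_j(1-p_j)\,\hat\gamma_j^2$ of the exposure variance, and its
strength is $F_j = R^2_j (N-2)/(1-R^2_j)$ with $N$ the exposure-study size;
$F > 10$ is the conventional low-bias threshold. The trait SD is exposed as
a parameter but defaults to 1, the scale of the packaged exposure study.
Note that summary tables published by multi-stage meta-analyses can print
F-statistics computed at the larger combined-stage $N$; `instrument_strength()`
always evaluates the formula at the $N$ you give it, so such rows will not
reproduce a published column computed at another $N$.

`outcome_screen()` recomputes each SNP's outcome p-value from
`beta_out/se_out` (published p columns are rounded) and compares it to the
Bonferroni level $\alpha/L$: an instrument directly associated with the
outcome is a pleiotropy suspect.

## Estimators

**IVW.** The inverse-variance-weighted estimate is the weighted regression
of $\hat\Gamma$ on $\hat\gamma$ through the origin with weights
$1/\sigma_y^2$. The fixed-effect SE is $1/\sqrt{\sum\hat\gamma_j^2/\sigma_{y,j}^2}$;
the multiplicative random-effects model inflates it by
$\sqrt{Q/(L-1)}$, floored at 1 so that under-dispersion never shrinks the
CI below the fixed-effect one. The floor cannot be observed on the packaged
data (its scale is 1.302) and is the package's documented convention.

**MR-Egger.** Weighted least squares with an unconstrained intercept after
orienting all SNPs to positive exposure effects. The slope is consistent
under pleiotropy whose magnitude is independent of instrument strength; the
intercept estimates the average directional pleiotropy. SEs carry the same
floored multiplicative scale; p-values use $t_{L-2}$ (with six SNPs the
reference is $t_4$, and that choice — not the normal — reproduces the
published p-values), while 95% CIs use the normal 1.96 quantile for every
method, which is what the published intervals use.

**Median family.** The simple, weighted and penalized weighted medians
interpolate the sorted Wald ratios at standardized cumulative weight
position 0.5, with midpoint positions $p_j = (\mathrm{cum}_j - w_j/2)/\sum w$.
Weighted and penalized variants weight by the inverse delta-method variance
of the Wald ratio,
$w_j^{-1} = \sigma_{y,j}^2/\hat\gamma_j^2 + \hat\Gamma_j^2\sigma_{x,j}^2/\hat\gamma_j^4$;
the second-order term matters in the third decimal and is what the standard
implementations of these estimators use, so it is the default
(`weights = "first"` switches to the first-order weights
$\hat\gamma_j^2/\sigma_{y,j}^2$). The penalized variant multiplies each
weight by $\min(1, 20 q_j)$, where $q_j$ is the upper-tail $\chi^2_1$
probability of the SNP's heterogeneity contribution about the weighted
median — a soft outlier down-weighting that leaves homogeneous sets (like
the packaged one) untouched. Ties in the sorted ratios are broken by input
order, and a median position outside the interpolation range clamps to the
end ratio.

In contrast, the Wald-ratio and IVW standard errors are deliberately
first-order (exposure uncertainty ignored): that is the convention the
published intervals follow, and a second-order option would change them.

The median SEs have no closed form; they are the standard deviation of the
estimate over `n_boot` parametric-bootstrap replicates (default 1000), in
which both studies' betas are redrawn from $N(\hat\beta, \mathrm{se})$ and
all weights and penalties recomputed. The bootstrap redraws parametrically
rather than resampling SNPs because with typical instrument counts (here,
six) resampling would make the estimate jump between a handful of ratio
configurations. A seed is mandatory; the RNG state of the caller is saved
and restored, so fits are reproducible without side effects.

## Diagnostics

**Cochran's Q** about the fixed-effect IVW estimate, with weights
$\hat\gamma_j^2/\sigma_{y,j}^2$ and a $\chi^2_{L-1}$ reference, measures
whether the per-SNP ratios disagree more than sampling error allows — the
signature of heterogeneous (often pleiotropic) instruments. Its per-SNP
contributions are returned and sum exactly to Q.

**Outlier testing** follows the residual-sum-of-squares simulation scheme:
each SNP's standardized residual is taken about the leave-one-out IVW slope
(so a gross outlier cannot mask itself), the observed
$\mathrm{RSS} = \sum_j r_j^2$ is compared to replicates simulated under a
single causal effect and no pleiotropy, and the global p-value is the
add-one empirical tail $(1 + \#\{RSS^* \ge RSS\})/(n_{\mathrm{sim}}+1)$ —
never exactly zero, as a Monte-Carlo p-value should be. Per-SNP squared
residuals are compared to their own simulated distributions and
Bonferroni-multiplied by $L$. The default $n_{\mathrm{sim}} = 5000$ puts a
Monte-Carlo standard error of about $\pm 0.007$ on a p-value near 0.3,
tight enough to check a published value printed to three decimals to within
a few hundredths. When outliers are found the report directs the user to
remove them and rerun; no automatically "corrected" estimate is produced,
because the follow-up distortion assessment is out of scope here and a
silent correction invites misreading.

**Influence.** `mr_influence()` tabulates the random-effects IVW without
each SNP (leave-one-out) and each SNP's own Wald ratio, both plot-ready.

## Power

For a binary outcome with $n$ subjects, case fraction $K$, and instruments
explaining fraction $R^2$ of the exposure variance, the IVW test of
$\theta = 0$ has non-centrality $|\ln \mathrm{OR}|\sqrt{n R^2 K(1-K)}$, and
two-sided power
$\Phi(\mathrm{ncp} - z_{1-\alpha/2}) + \Phi(-\mathrm{ncp} - z_{1-\alpha/2})$.
Both tails are kept so that power at $\mathrm{OR} = 1$ equals $\alpha$
exactly; away from the null the far tail is negligible.
`mr_detectable_or()` inverts this: the closed form
$|\ln \mathrm{OR}| = (z_{1-\alpha/2} + z_{\mathrm{power}})/\sqrt{n R^2 K(1-K)}$
is refined by one root-solve against the two-tailed power so the round-trip
`mr_power(mr_detectable_or(...))` returns the target exactly even at low
powers. At the packaged design (n = 1,030,836, K = 0.0588, $R^2$ = 2.84%,
$\alpha$ = 0.05, 80% power) the minimal detectable protective OR is 0.933.
Published values computed with web power tools can differ in the third
decimal depending on the exact approximation variant; agreement to
$\pm 0.005$ is the realistic expectation.

Note the instrument $R^2$ is an explicit input everywhere: the per-SNP
$R^2$ column of a published table need not sum to the variance-explained
figure a power calculation quotes (composite scores and combined-stage
estimates differ), and the package never silently substitutes one for the
other.

## The synthetic-data generator

`simulate_two_sample()` draws two-sample summary statistics under the
linear causal model with known truth: allele frequencies uniform on
(0.1, 0.9); true per-SNP variance explained uniform on
$(5\times10^{-4}, 3\times10^{-3})$ — the range genome-wide-significant hits
of a study of this size occupy, since $p < 5\times10^{-8}$ implies roughly
$F > 30$, i.e. $R^2 \gtrsim 4\times10^{-4}$ at $n \approx 79{,}000$ — with
the effect allele defined as the exposure-increasing one; exposure sampling
SE $1/\sqrt{2p(1-p)n_{\mathrm{exp}}}$ for a unit-SD trait; outcome effects
$\theta\gamma_j + \alpha_j$ with the binary-trait SE
$1/\sqrt{2p(1-p)\,n_{\mathrm{out}}K(1-K)}$; optional pleiotropy
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$, where $\mu_\alpha \ne 0$ is
directional pleiotropy. The default study sizes are the worked example's
(79,366 / 1,030,836 at K = 0.0588). `scramble_alleles` randomly re-codes the
outcome records (allele swap and/or strand complement), which `harmonize()`
must undo exactly — a round-trip the test suite checks.

What the generator does **not** emulate: linkage disequilibrium between
instruments (draws are independent, as post-clumping instruments are
assumed to be), palindromic variants (allele pairs are drawn
non-palindromic so that label-based harmonization is always resolvable;
palindromic handling is exercised by dedicated unit tests instead), sample
overlap between the two studies, population stratification, and
winner's-curse inflation of the exposure betas. Passing tests on this
generator therefore validate the estimators' algebra and calibration under
clean two-sample assumptions — not robustness to those real-data
pathologies.

## Numerical and design choices

* P-values below double precision (a published $5\times10^{-343}$) are
  clamped to the smallest positive double on read rather than erroring.
* The loose consistency check between a published p-value and `beta/se` is
  restricted to $p > 10^{-10}$: multi-stage meta-analyses legitimately print
  tiny p-values whose z differs from the single-stage beta/se.
* Positions are carried as 1-based `"chrom:pos"` strings, informational
  only; nothing does coordinate arithmetic.
* All estimators are invariant to SNP order and to jointly flipping the
  sign of any SNP's exposure and outcome betas (checked by tests).
* Monte-Carlo sizes in the test suite: type-I error at 1000 replicates,
  effect recovery at 500, pleiotropy-intercept recovery at 200, all with 50
  instruments — large enough that binomial/Monte-Carlo error is well inside
  the asserted bands, small enough to run in seconds.
* `run_full_analysis()` derives all randomness from the single configured
  seed (bootstrap at `seed`, outlier simulation at `seed + 1`), so two runs
  with the same configuration are byte-identical.

## Known limitations

Only biallelic SNPs with A/C/G/T codings are supported (no indels or
multi-allelic sites); there is no LD-aware proxy lookup for SNPs missing
from the outcome study; non-linear causal models, multivariable MR,
mode-based estimators and the post-outlier distortion assessment are out of
scope. The harmonization EAF checks require frequencies — records lacking
EAF pass through only when their allele labels alone are decisive.
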