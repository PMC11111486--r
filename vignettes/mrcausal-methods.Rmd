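---
title: "Methods: two-sample Mendelian randomization in mrcausal"
author: "mrcausal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrcausal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcausal)
```

# The model

Two-sample Mendelian randomization estimates the causal effect $\beta$ of an
exposure on an outcome from per-SNP GWAS summary statistics. For instrument
$j$, let $\hat\gamma_j$ (SE $\sigma_{Xj}$) be its association with the
exposure in sample 1 and $\hat\Gamma_j$ (SE $\sigma_{Yj}$) its association
with the outcome in sample 2. Under the instrumental-variable assumptions —
the variant is associated with the exposure, independent of confounders, and
affects the outcome only through the exposure — each SNP supplies a Wald
ratio $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard
error $\sigma_{Yj}/|\hat\gamma_j|$. The package's estimators aggregate these
ratios under progressively weaker assumptions:

* **IVW**: the inverse-variance-weighted mean of the ratios, equivalently
  weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the origin
  with weights $w_j = \sigma_{Yj}^{-2}$. Efficient when *every* instrument
  is valid. The fixed-effect SE is $(\sum_j w_j\hat\gamma_j^2)^{-1/2}$; the
  default multiplicative random-effects SE multiplies it by
  $\sqrt{\max(1, Q/(k-1))}$, where $Q$ is Cochran's statistic, so
  heterogeneity widens but never narrows the interval, and the two variants
  coincide when $Q \le k-1$.
* **MR-Egger**: the same regression with a free intercept, after orienting
  every instrument to $\hat\gamma_j \ge 0$. Under the InSIDE assumption
  (instrument strength independent of direct effects) the slope is
  consistent even when all instruments are pleiotropic, and the intercept
  estimates the average directional pleiotropy — the basis of the intercept
  test. SEs carry the same multiplicative scale, floored at 1, on $k-2$
  degrees of freedom, and p-values use the $t_{k-2}$ distribution.
* **Weighted median**: the weighted median of the ratios (breakpoints
  $s_j = \sum_{i\le j} w'_i - w'_j/2$ on normalized inverse-variance
  weights, linear interpolation at $1/2$). Consistent while valid
  instruments hold more than half the total weight.
* **Simple and weighted mode**: the argmax of a normal-kernel density over
  the ratios, unweighted or inverse-variance weighted. Consistent when the
  largest group of instruments sharing one ratio is valid (the ZEMPA
  assumption).

Because the motivating exposure is a binary disease trait, slopes are on the
log-odds scale and are reported alongside $\mathrm{OR} = e^b$ with 95% CI
$\exp(b \mp 1.959964\,\mathrm{SE})$.

# Instrument selection

`selectInstruments()` applies five screens in a fixed order: exposure
p-value $< 5\times10^{-8}$ (genome-wide significance); minor-allele
frequency $\ge 0.01$; greedy LD clumping; harmonization against the
outcome; per-SNP instrument strength $F \ge 10$ where
$R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$ and
$F = R^2(N-2)/(1-R^2)$ with that SNP's own $N$; and the Steiger
directionality filter, which keeps a variant only when it explains strictly
more variance in the exposure than in the outcome (ties are dropped as
ambiguous). Clumping precedes harmonization because it is an exposure-only
operation; Steiger needs both sides, so it must come last. $F$ is a per-SNP
screen, not a joint statistic: each instrument is retained or dropped on its
own strength.

Two approximations are worth stating. First, the $2p(1-p)\beta^2$
variance-explained formula is exact for a standardized continuous trait and
is applied to the binary (log-odds) side as well, as a screening
approximation; `steigerFilter()` accepts externally computed $r^2$ columns
for users who prefer a liability-scale calculation. Second, the first-order
Wald SE ignores exposure-side noise; since instruments pass genome-wide
significance, that term is second-order, but `waldRatios(secondOrder =
TRUE)` provides the corrected version.

Clumping is the standard greedy algorithm: sort by p-value (ties: chromosome
label, then position), keep the best remaining variant, and remove every
remaining variant that is *both* within the distance window *and* correlated
at $r^2 \ge$ threshold with it. Either condition alone never removes a
variant, so a highly correlated pair farther apart than the window survives
— the window expresses that the supplied $r^2$ is only trusted locally.
Without an LD matrix all correlations are taken as zero, with a warning.

## Harmonization and palindromic variants

Outcome records are aligned to the exposure's effect allele: identical
pairs pass, swapped pairs negate the outcome beta and mirror its frequency,
strand-complement pairs are complemented first. A palindromic SNP (A/T or
G/C) cannot be strand-resolved from letters, so letters give only a nominal
alignment and the allele frequencies arbitrate: the variant is kept only
when both frequencies fall outside the ambiguity window (default
$(0.42, 0.58)$) on the same side; anything else — opposite sides, either
frequency inside the window, or a missing frequency — is dropped with a
logged reason rather than guessed. The window default follows common
two-sample MR practice; a strict mode drops all palindromic variants.
Frequencies are never used to *flip* a palindromic record: a variant whose
frequencies disagree is treated as unresolvable, trading a little power for
zero risk of a silently wrong sign. Indels and multi-base alleles are
rejected at read time since the palindrome logic is defined only for SNVs.

# Sensitivity analyses

Cochran's $Q = \sum_j w_j(\hat\Gamma_j - \widehat{\Gamma}_j^{fit})^2$ is
computed about the fixed-effect IVW line ($k-1$ df) and the Egger line
($k-2$ df), with upper-tail chi-square p-values. The pipeline's headline
estimate operationalizes the usual advice: IVW with the fixed-effect SE,
switching to the multiplicative random-effects SE when the IVW $Q$ is
significant at $\alpha = 0.05$. Leave-one-out re-fits the (same-variant)
IVW $k$ times with one instrument removed; a sign change against the full
estimate flags an influential variant. No multiplicity correction is
applied across analyses; each test is reported at $\alpha = 0.05$.

# The synthetic-data generator

`simulateTwoSample()` draws, per SNP: MAF $p_j \sim U(0.05, 0.5)$; a true
exposure effect of magnitude $U(0.05, 0.15)$ with a random sign (the sign
encodes which allele is effect-coded); with probability `propInvalid`, a
direct (pleiotropic) outcome effect $\alpha_j \sim N(\mu_\alpha,
\sigma_\alpha^2)$; the true outcome effect $\beta\gamma_j$ plus pleiotropy;
and independent sampling errors on the two sides with
$\mathrm{SE} = (2p_j(1-p_j)N)^{-1/2}$ — the standardized-scale formula, with
default sample sizes 40,585 (exposure) and 175,226 (outcome) mirroring the
scale of the motivating stroke and frailty-index GWAS. Effect magnitudes
are chosen so most instruments clear $5\times10^{-8}$ at the default
exposure size; the selection stage still always runs.

One deliberate convention: the pleiotropic effect is defined **on the
exposure-increasing allele** ($\Gamma_j = \beta\gamma_j +
\mathrm{sign}(\gamma_j)\,\alpha_j$). Allele coding is arbitrary, and every
estimator except MR-Egger is invariant to it; Egger first orients all
instruments to $\hat\gamma_j \ge 0$, so only pleiotropy expressed in that
oriented frame is "directional". Had $\alpha_j$ been attached to an
arbitrary allele, its oriented mean would be zero by symmetry and
`muAlpha` would not be an interpretable target for the intercept. This is
also how directional pleiotropy is simulated in the estimator-benchmarking
literature.

`ldBlockFixture()` adds correlated blocks for exercising the clumping
stage: within a block of size $m$ and correlation $r$, members share the
tag's MAF, true effects decay as $r^{d}$ with in-block distance $d$, and
estimation errors are drawn jointly with correlation $r^{|i-j|}$
(via `MASS::mvrnorm`); the emitted LD matrix holds the squared values and
block members sit within 50 kb, well inside the clumping window.

What the generator does **not** emulate: genotype-level data and
liability-scale binary traits (binary exposures are mimicked only through
effect scale), realistic allele-frequency spectra, sample overlap between
the two GWAS, population stratification, and winner's-curse-free discovery
(instruments are selected in the same simulated sample they are estimated
in, as in most real two-sample analyses). Passing tests therefore certify
the estimators and pipeline under the stated model, not robustness to
those real-data complications.

# Numerical choices

* **Weighted median**: breakpoint interpolation as defined above; if $1/2$
  falls outside the breakpoint range, the extreme ratio is returned.
* **Modes**: bandwidth $h = \phi \cdot 0.9\min(\mathrm{SD},
  \mathrm{MAD})k^{-1/5}$ (MAD scaled by 1.4826 to be normal-consistent);
  when that is zero (e.g. tied ratios), $h$ falls back to 1/100 of the ratio
  range, or a tiny positive value when the range is zero. The density is
  evaluated on a fixed 512-point grid spanning the ratios extended by $3h$;
  ties at the maximum resolve to the smallest grid value. Grid size and tie
  rule are fixed for bit-level determinism.
* **Bootstrap SEs** (median and modes): parametric — both sides' betas are
  re-drawn from normals with their reported SEs and the statistic is
  recomputed; default 1000 replicates; the seed is mandatory and recorded
  in `extras`. `runAllMethods()` offsets the seed per method so the whole
  report is reproducible bit for bit.
* **MR-Egger** is fitted by the centered weighted-least-squares closed form
  (weighted means and centered cross-products) rather than raw normal
  equations: the centered form stays accurate as the design approaches the
  collinear boundary, at which the estimator refuses to run
  (`CollinearDesign` when oriented exposure effects are constant).
* **Minimum instruments**: IVW 2; Egger, median and modes 3. Below the
  floor a typed error is raised, never a silent `NA`.
* **Degenerate inputs**: zero exposure effects are rejected
  (`ZeroExposureEffect`); empty selections report the stage that emptied
  the set; Q-based p-values are exactly 1 when $Q = 0$; an exactly fitting
  Egger line is flagged (`extras$exactFit`) since its residual scale is not
  estimable.
* **Seeding**: all seeded helpers save and restore the caller's RNG state,
  so a seeded call never perturbs an enclosing simulation. Replicate $r$ of
  a study uses `seed + r`.

# Problem sizes in the test suite

The suite's Monte-Carlo checks use sizes chosen to make their statistical
bands informative at interactive runtimes: parameter recovery and
pleiotropy recovery run 500 replicates at $k = 50$ instruments under the
default study-scale sample sizes; IVW type-I error uses 200 null
replicates; Cochran's-Q calibration uses 1000 homogeneous replicates at
$k = 30$; LD-block error correlation uses 300 replicates. Each stochastic
test states its seed and tolerance inline.

# Limitations

* The Steiger screen and the F-statistic use the standardized
  variance-explained approximation on binary traits; liability-scale users
  should supply their own $r^2$.
* LD must arrive as an $r^2$ matrix; the package never computes LD from
  genotype panels, and clumping without a matrix degrades to a pure
  distance filter.
* The Egger intercept targets mean directional pleiotropy only under
  InSIDE and with well-measured exposure effects; weak instruments
  attenuate the slope and leak bias into the intercept (no NOME
  correction such as SIMEX is implemented).
* Only the exposure→outcome direction is analyzed; no MR-PRESSO,
  multivariable or bidirectional MR.
* Odds-ratio CIs use the normal approximation on the log scale throughout.
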