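---
title: "Methods and design notes for mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# The model

mrscreen implements bidirectional two-sample Mendelian randomization (MR)
from GWAS summary statistics. For SNP $j$, let $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$) be its association with the exposure and $\hat\beta_{Yj}$
(SE $\sigma_{Yj}$) its association with the outcome, estimated in
non-overlapping samples. If the SNP is a valid instrument — associated
with the exposure, independent of confounders, and affecting the outcome
only through the exposure — then $\beta_{Yj} = \theta\,\beta_{Xj}$ for the
causal effect $\theta$, and each SNP supplies a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$.

The estimators combine these ratios:

* **IVW** is weighted least squares of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ through the origin with weights
  $w_j = \sigma_{Yj}^{-2}$. The default is the multiplicative
  random-effects variant: the fixed-effects SE is inflated by
  $\sqrt{\max(1, Q/(k-1))}$, where $Q$ is Cochran's statistic at the
  estimate. The paper trail for which IVW variant a given analysis used is
  often missing; this matches the dominant package convention and the
  `mode` argument exposes both.
* **MR-Egger** adds a free intercept; under the InSIDE assumption the
  slope remains consistent in the presence of *directional* pleiotropy
  and the intercept estimates its average. SNPs are re-oriented so
  $\hat\beta_{Xj} \ge 0$ before fitting (Egger is orientation-dependent
  and a fixed convention is needed for determinism). Residual dispersion
  $Q/(k-2)$ is floored at 1 and inference uses $t_{k-2}$, the small-$k$
  convention.
* **Weighted median** interpolates the weighted empirical distribution of
  the ratios at probability one half, with first-order inverse-variance
  weights $\hat\beta_{Xj}^2/\sigma_{Yj}^2$; it is consistent when valid
  instruments carry at least half the weight. Its SE is a parametric
  bootstrap (default 1000 resamples, mandatory seed); whether published
  analyses used a bootstrap or an analytic SE is rarely stated, and the
  bootstrap is the package norm.
* **Wald ratio** handles single-instrument pairs, with the first-order SE
  $\sigma_{Yj}/|\hat\beta_{Xj}|$ by default and the full delta-method SE
  as an option.

# Instrument selection

`select_instruments()` applies, in order: a significance threshold
(default $p < 5\times10^{-6}$, the conventional relaxed microbiome-GWAS
threshold; $5\times10^{-8}$ is the strict alternative), a minor-allele
frequency floor (0.01), greedy LD clumping ($r^2 < 0.001$ within 10,000
kb), and exclusion of weak instruments ($F = (\hat\beta/\sigma)^2 < 10$).
The published four-rule listing does not declare an execution order; this
order follows its numbering for the first three rules and defers the F
filter to the post-extraction check where it is described. Clumping ties
in $p$ are broken lexicographically by SNP id. Every candidate receives
exactly one audit disposition, so a selection can be reconstructed.

# Harmonization

Exposure and outcome records are aligned to the exposure's effect allele:
identical coding is kept, swapped alleles negate the outcome beta and
reflect its frequency, strand complements are complemented and
re-matched, and anything unresolvable is dropped. Palindromic (A/T, C/G)
SNPs are dropped under the default policy — the strict reading of
"remove palindromic variants" — with an optional frequency-inference mode
that aligns them by allele frequency and drops those inside the
ambiguity band [0.42, 0.58]. Matching is by SNP id; a strict mode also
requires position agreement. SNPs absent from the outcome are dropped
(no proxy search).

# Sensitivity suite

* **Cochran's Q** over the ratio estimates, with the explicit rule:
  heterogeneous when $Q > k-1$ (strictly) **or** $p < 0.05$. Note the
  first clause fires whenever $Q$ exceeds its null mean, i.e. roughly 40%
  of the time under perfect homogeneity — it is deliberately aggressive,
  and it is the rule as stated, so verdict-level tests in this package
  assert on p-values and ranks rather than on a single seed's verdict.
* **MR-PRESSO**: the global test compares the observed leave-one-out
  residual sum of squares with a parametric simulation under the
  no-pleiotropy model; the outlier test compares each SNP's weighted
  residual with its simulated distribution (Bonferroni-adjusted by $k$).
  The iterative loop removes the smallest-p outlier while the global test
  rejects, stopping when fewer than four SNPs would remain. Monte-Carlo
  p-values carry the $+1$ correction. Ties in the outlier p (common at
  the $1/(n_\mathrm{sim}+1)$ floor) are broken by the largest observed
  residual. The distortion test of the original method is omitted: only
  the global and outlier trials are in scope; the hook is
  `presso_global()`'s returned residuals.
* **Leave-one-out** recomputes IVW without each SNP and flags results
  whose full-set $p < 0.05$ collapses above 0.05 when any single SNP is
  removed.
* **Steiger directionality** sums per-SNP variance explained using the
  t-statistic form $r^2_j = t_j^2/(t_j^2+n-2)$ — chosen because it needs
  no allele frequencies and applies to binary traits on the observed
  log-odds scale (liability-scale conversion is out of scope) — and
  compares $\sqrt{r^2_X}$ with $\sqrt{r^2_Y}$ by a two-sided two-sample
  Fisher-z test.

# The synthetic world

`simulate_pair()` generates a stated, fully-known world: MAF $\sim$
U(0.05, 0.5); standardized-scale SEs $1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$
(exact, which is why even the "disease" trait is simulated on a
continuous scale — calibration targets need analytic truth); instruments
at the head of their own LD block with strength parameterized by the
expected association z-score, $z \sim z_\min + \mathrm{Exp}(\bar z -
z_\min)$, an L-shaped distribution like real GWAS effect sizes; marginal
effects $R\gamma$ under the block LD matrix, so LD partners carry
attenuated signals; sampling noise correlated within blocks at the LD
correlation and independent across traits (the two-sample assumption);
and optional palindromic alleles, planted outliers, and random re-coding
of outcome records (allele swaps and strand flips) so harmonization is
always exercised. Each LD block gets its own synthetic chromosome label:
inter-block LD is exactly zero, so clumping stays exact at any panel
size. Null-SNP p-values are uniform and the generator's LD matrix is the
one handed to clumping, so every selection decision is predictable.

**Directional pleiotropy** is applied relative to the exposure-increasing
allele: $\alpha_j = \mathrm{sign}(\gamma_j)(\mu_\alpha +
\sigma_\alpha\varepsilon_j)$. A constant shift on the raw coded alleles
(whose signs are arbitrary) would cancel under the $b_X \ge 0$
orientation and no estimator could register it as directional; this
definition matches the standard simulation designs for pleiotropy-robust
estimators. The InSIDE-violation knob correlates $|\alpha_j|$ with
instrument strength.

What a green test does **not** establish: the generator has no sample
overlap, no population stratification, no liability-scale binary traits,
no proxy-SNP ambiguity, and exact LD — real-data behaviour degrades with
all of these.

# Choices behind the acceptance worlds

* Calibration and recovery use the stated 30/50 instruments at
  $n = 20{,}000$; background null SNPs are omitted where a criterion
  addresses estimator behaviour on known instruments (they only matter to
  selection, which the bidirectional criterion and unit tests cover), and
  that is the only scaling-down applied.
* The pleiotropy world (30% invalid instruments, mean direct effect 0.02,
  InSIDE holding) does not state sample sizes, instrument count, or the
  strength distribution. These were fixed a priori by a power
  calculation: the Egger intercept SE scales like
  $\sigma_\mathrm{res}\sqrt{E[z^2]/(k\,\mathrm{Var}(z))}$, and with
  narrow-uniform strengths ($z \sim$ U(8, 15)) the leverage term leaves
  under 15% power at any $n$; the all-or-nothing pleiotropy mixture alone
  contributes $\sqrt{0.3\cdot0.7}\cdot0.02 \approx 0.009$ of residual
  dispersion. With 50 instruments, L-shaped strengths
  ($z \sim 3+\mathrm{Exp}(12)$), the exposure at the microbiome-GWAS
  scale ($n_X = 14{,}306$) and the outcome at case-control biobank scale
  ($n_Y = 462{,}933$), the predicted power is roughly 75%, and the
  measured value is about 0.8.
* The MR-PRESSO world uses 10 instruments (the screen's upper range) and
  a 10-SE displacement as stated; the bidirectional world uses the
  generator defaults, LD blocks and palindromes included, through the
  full selection-harmonization path.

# Numerical and degenerate-input conventions

Simulated p-values are floored at $10^{-300}$ so they stay inside (0, 1]
after underflow. Summary files are written with 10 significant digits and
round-trip exactly through their canonical form. Pairs with no
instruments, no overlap, or degenerate statistics yield
`skipped(<reason>)` verdicts, never exceptions, so a screen over
hundreds of taxa always completes. All Monte-Carlo procedures take
mandatory seeds and are bit-reproducible; the CLI is byte-deterministic
given identical inputs and `--seed`.

# Known limitations

No proxy-SNP search, no multi-allelic variants, no liability-scale
conversion, no sample-overlap correction, no multivariable MR, and no
LD-matrix estimation from genotypes (LD is an input). The headline screen
applies no multiple-testing correction — deliberately mirroring common
practice in per-taxon MR screens — but Bonferroni and Benjamini-Hochberg
columns are always reported alongside.
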