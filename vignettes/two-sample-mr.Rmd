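---
title: "Two-sample Mendelian randomization with mrkit: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The estimation problem

Two-sample Mendelian randomization (MR) asks whether an exposure causes an
outcome, using genetic variants as instruments and only *summary* GWAS
statistics from two (possibly non-overlapping) studies. For each SNP $j$ we
observe the exposure association $\hat\beta_{Xj}$ with standard error
$\sigma_{Xj}$, and the outcome association $\hat\beta_{Yj}$ with
$\sigma_{Yj}$ (log-odds for a case-control outcome). Under the three
instrumental-variable assumptions — relevance, independence from
confounders, and exclusion (no effect on the outcome except through the
exposure) — every valid instrument estimates the same causal effect
$\theta$ through its Wald ratio

$$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj},
\qquad \mathrm{se}(\hat\theta_j) \approx \sigma_{Yj}/|\hat\beta_{Xj}|.$$

The first-order (delta-method) standard error above ignores exposure-side
noise; it is the package default because instruments are conventionally
pre-filtered to be strong (F ≥ 10), where the neglected term
$\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$ is small. A
`second_order = TRUE` flag adds it for sensitivity checks.

The worked example throughout the package is the bundled table of 32
instruments for genetically proxied metformin use (a UK Biobank binary
trait scanned on the linear scale, n = 462,933) against rheumatoid
arthritis (case-control meta-analysis, n = 58,284), loaded by
`metformin_ra_instruments()`.

## The estimator battery

`mr_fit()` computes up to five estimators, all on the log-odds scale;
odds ratios are always derived by exponentiation at the end, never averaged
directly.

**IVW.** The fixed-effect inverse-variance-weighted estimate pools the
Wald ratios with weights $w_j = 1/\mathrm{se}(\hat\theta_j)^2$:
$\hat\theta = \sum w_j\hat\theta_j / \sum w_j$, with
$\mathrm{se}(\hat\theta) = (\sum w_j)^{-1/2}$. This is algebraically a
weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
origin — the tests exploit that identity as an independent oracle. The
multiplicative random-effects variant inflates the SE by
$\max\{1, \sqrt{Q/(J-1)}\}$ and leaves the point estimate unchanged.
Fixed-effect is the default; on the bundled table the two differ only in
the interval (the published interval and p = 0.006 correspond to the
random-effects variant, while the published forest plot is labelled
fixed-effect — the package reports whichever the caller picks, and the
odds ratio is identical).

**MR-Egger.** Instruments are first oriented so the exposure effect is
positive (the regression is only defined modulo allele relabelling), then
$\hat\beta_{Yj}$ is regressed on $\hat\beta_{Xj}$ with a free intercept and
weights $1/\sigma_{Yj}^2$. The slope is the causal estimate under the
InSIDE assumption; the intercept estimates average directional pleiotropy.
Coefficient SEs are divided by $\min(\hat\sigma, 1)$, where $\hat\sigma$ is
the weighted residual SD, so underdispersion is never credited; p-values
use $t_{J-2}$. On exactly affine data ($\hat\sigma = 0$) the coefficients
are reported error-free rather than dividing by zero.

**Weighted median.** Ratios are sorted; with normalized cumulative weights
$p_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k$, the estimate linearly
interpolates the ordered ratios at $p = 0.5$. Consistent when valid
instruments carry over half the weight.

**Mode estimators.** The simple and weighted modes locate the argmax of a
Gaussian kernel density over the ratios, with the modified Silverman
bandwidth $h = \phi\, 0.9 \min(\mathrm{sd}, \mathrm{MAD}) J^{-1/5}$
(MAD scaled 1.4826). Numerical conventions, fixed and documented because no
standard exists: a 512-point grid spanning the ratio range padded by $3h$
on both sides; $\phi = 1$ by default; when all ratios coincide ($h = 0$)
the common ratio is returned with the fixed-effect IVW standard error. Mode
point estimates are reproducible; their published counterparts are matched
to one significant figure since bandwidth/grid conventions differ across
implementations.

Median and mode standard errors come from a parametric bootstrap (default
1000 draws, mandatory seed): each $\hat\beta_{Xj},\hat\beta_{Yj}$ is
redrawn from a normal with its observed SE and the estimator recomputed;
the SE is the SD over draws. Bootstrap draws restore the caller's RNG
state, so package calls never disturb the session stream.

## Instrument processing

`read_sumstats()` accepts the plain beta/se/pval summary-statistics dialect
(tab or comma separated), validates every row (alleles in A/C/G/T, se > 0,
p in (0,1], frequency in (0,1)), and reports each rejected row with its
number and reason — conversion is total: converted + rejected = input rows.

`harmonize()` aligns each outcome record to the exposure's effect allele:
copy when alleles match, negate the outcome beta (and complement its
frequency) when they are swapped, and resolve strand flips through A↔T/C↔G
complements. Palindromic SNPs (A/T, C/G) carry no strand information in
their letters, so orientation falls back on allele-frequency agreement;
when the exposure effect-allele frequency lies in the intermediate window
— default [0.42, 0.58], a symmetric convention exposed in
`harmonize_config()` because the source analyses say only "intermediate" —
or when either frequency is missing, the SNP is dropped with reason
`palindromic_intermediate`. Every drop lands exactly once in the returned
set's provenance table with a machine-readable reason code.

Selection and QC mirror common practice: strict genome-wide significance
(`select_significant()`, p < 5e-8), greedy LD clumping in p-order with a
lexicographic rsID tie-break for determinism (`ld_clump()`; pairwise r²
from a pluggable provider such as `ld_matrix_provider()`, or a
distance-only fallback of 5000 kb when no LD source exists — reference-
panel LD computation is out of scope), the instrument-strength F statistic
(`f_statistic()`), the F ≥ 10 weak-instrument filter (`filter_weak()`),
and Steiger directionality filtering (`steiger_filter()`). The pipeline
order used in examples is significance → clump → harmonize → Steiger → F.

Two F conventions exist: $F = z^2$ with $z$ recovered from the exposure
p-value by high-precision normal tail inversion (default; works to
p ≈ 1e-300), or $(\hat\beta_X/\sigma_X)^2$. On unrounded data they agree to
six significant figures; on published tables rounded to a few digits they
can differ by more than the rounding of either column, because the
table's F was typically computed upstream from unrounded values — the
bundled table shows exactly this, with recomputed F within ~0.1% but not
within 0.01 of the printed column.

Steiger filtering uses the z-and-n approximation
$r^2 = z^2/(z^2 + n - 2)$ per trait, keeping a SNP iff it explains strictly
more variance in the exposure; EAF-based variance formulas are out of
scope. On rounded published tables this approximation is conservative:
with the study-level sample sizes it flags two of the 32 bundled
instruments whose outcome z approaches their exposure z at the much
smaller outcome n, whereas the original analysis (unrounded data,
EAF-based r²) removed none. Because the bundled table lacks per-SNP sample
sizes, the filter warns and skips there unless sizes are supplied.

## Sensitivity battery

`mr_sensitivity()` bundles: Cochran's Q about the fixed-effect IVW centre
(the same Q that scales the random-effects SE — a single source of truth,
asserted in tests); the MR-Egger intercept test; MR-PRESSO; a leave-one-out
table where row $j$ is computed on the set literally excluding SNP $j$; and
plot-ready scatter/funnel/forest tables written by `export_plot_tables()`
(the package emits tables, not figures).

MR-PRESSO simulates the leave-one-out weighted residual sum of squares:
observed residuals $d_j = \hat\beta_{Yj} - \hat\theta_{-j}\hat\beta_{Xj}$
with weights $1/\sigma_{Yj}^2$ give RSS\(_{obs}\); `n_sim` replicates redraw
$\hat\beta^*_{Xj} \sim N(\hat\beta_{Xj}, \sigma_{Xj})$ and
$\hat\beta^*_{Yj} \sim N(\hat\theta_{-j}\hat\beta_{Xj}, \sigma_{Yj})$ and
recompute the statistic. All Monte-Carlo p-values use the
$(1 + \#\{\cdot\})/(1 + n)$ estimator so an empirical p is never zero.
Per-SNP outlier tests are Bonferroni-corrected at $0.05/J$ (the source
analyses report only the global test; the threshold is exposed). The
distortion test, run only when outliers are flagged, compares the estimate
shift after removing them against shifts from random same-size removals.
Randomness comes from per-SNP substreams keyed by rsID rank under one root
seed, making results bit-reproducible and invariant to instrument order.

## The synthetic-data generator

`sim_scenario()`/`simulate_pair()` generate paired summary statistics with
known truth so that every pipeline stage is testable without downloads.
Defaults are the study conditions of the worked example, fixed once:
462,933 exposure samples (binary trait, prevalence 11552/462933, scanned
on the linear scale so betas are tiny), 58,284 outcome samples (case
fraction 14361/58284 entering the log-odds SE approximation
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n\,u(1-u)}$), 32 instruments,
$\theta = -3.76$, MAF uniform on (0.05, 0.5), per-SNP exposure variance
explained 7e-5 (at this n, significance selection then yields F between
roughly 30 and 600 with mean near 60, matching the observed instrument
strength), and a 6% palindromic fraction (2 of 34 candidate instruments in
the worked example were palindromic). Pleiotropy laws: `none`, `balanced`
(zero-mean), `directional` (nonzero mean), and `correlated` (direct
effects proportional to instrument strength, violating InSIDE). Direct
effects are defined in the exposure-increasing allele frame — the frame in
which directional pleiotropy and the Egger intercept are meaningful — and
mapped through the SNP's random allele labelling. Planted outliers receive
a gross direct effect of `outlier_scale` outcome SEs with random sign.

`simulate_significant_instruments()` rejection-samples SNPs until the
requested number pass p < 5e-8 on the *observed* exposure association,
as a real instrument search does. This carries mild winner's curse
(a few percent attenuation at these scales), which is a property of the
emulated procedure, not a bug; calibration experiments that need unbiased
panels use `simulate_pair()` directly.

What the generator does *not* emulate: LD between instruments (clumping is
exercised through explicit r² matrices), allele-frequency differences
between studies, sample overlap, population stratification, and winner's
curse beyond the selection step. Passing tests therefore demonstrate
correctness of the estimators and procedures under the stated generative
model, not robustness to those real-data complications.

## Numerical and design choices, in one place

- CI multiplier fixed at 1.959964; all intervals are Wald intervals on the
  log scale.
- Monte-Carlo p floor $(1+k)/(1+n)$; MR-PRESSO substreams keyed by rsID
  rank; bootstrap and simulation seeds are explicit arguments, and RNG
  state is always restored.
- Clumping tie-break at equal p: lexicographic rsID. Unknown pairwise r² is
  treated as unlinked (the provider contract allows "unknown").
- Degenerate inputs: `beta_exp == 0` raises a degenerate-instrument error;
  single-instrument sets fall back to the Wald ratio in `mr_fit()`;
  identical ratios give Q = 0, p = 1 and the degenerate mode path.
- Instrument tables serialise with a fixed column order and 12 significant
  digits, so files diff cleanly and round-trip exactly; missing optional
  fields are written as `NA`.
- Test problem sizes, chosen to make Monte-Carlo assertions sharp at
  desk scale: 400 null replicates for IVW type-I error, 200 replicates for
  Egger-intercept recovery and for IVW parameter recovery, 100 replicates
  for MR-PRESSO planted-outlier detection (1000 simulations each).

## Known limitations

- No proxy-SNP lookup for instruments absent from the outcome study; no
  multivariable MR, MR-RAPS, contamination-mixture or Radial-MR variants.
- First-order Wald SEs understate uncertainty for marginal instruments;
  the second-order option exists but is not the default.
- The Steiger z-approximation depends on reported sample sizes and is
  sensitive to rounding in published tables (see above).
- Published mode estimates are only reproducible up to KDE conventions.
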