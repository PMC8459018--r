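---
title: "NIR hyperspectral screening of fat and fatty acids in walnut kernels: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIR hyperspectral screening of fat and fatty acids in walnut kernels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walnutnir)
```

## The problem

Gas chromatography gives precise fatty-acid profiles of walnut oil but is
destructive, slow and reagent-hungry. Near-infrared hyperspectral imaging
offers a non-destructive alternative: a camera records a reflectance
spectrum (900–1700 nm) at every pixel of a tray of intact kernels, and a
chemometric calibration maps per-kernel mean absorbance spectra to total
fat (% by weight) and to the fatty-acid families — saturated (SFA),
monounsaturated (MUFA) and polyunsaturated (PUFA) acids, expressed as
relative % of total fatty acids. `walnutnir` implements the complete
screening chain for this problem: radiometric calibration, pixel
segmentation, spectral pretreatment, Mahalanobis sample selection, modified
partial least squares (MPLS) calibration, external validation statistics,
and variety-level composition statistics.

Because no per-kernel dataset of this kind is openly deposited, the package
ships a synthetic-data generator as a first-class, tested module. The
generator's defaults define the study conditions used throughout the test
suite; everything downstream is exercised against its known ground truth.

## The measurement model

### From counts to absorbance

Raw sensor counts are converted to reflectance by two-point calibration
against a dark-current frame and a white-reference (PTFE tile) frame,

$$R = \frac{\mathrm{raw} - \mathrm{dark}}{\mathrm{white} - \mathrm{dark}},$$

per pixel column and band. Both reference frames are reduced to
per-pixel-column medians across scan lines before use; single acquired
frames carry shot noise and the median suppresses it without biasing a
constant frame. Reflectance is clipped to $[10^{-4}, 1.5]$ — the lower
bound prevents infinities in the log transform for dead pixels, the upper
bound keeps moderate glints. Absorbance is $A = \log_{10}(1/R)$, and only
the 950–1650 nm subrange is kept (both ends inclusive); the spectral
extremes of the instrument are noise-dominated.

### Pixel segmentation

Kernel pixels are separated from the background by a stepwise linear
discriminant: forward selection of bands minimizing Wilks' $\Lambda$, a
band entering at partial $F \ge 3.84$ and leaving below $2.71$ (the classic
stepwise defaults; the method itself is threshold-agnostic), followed by a
Fisher discriminant on the selected bands with equal priors and the
decision threshold at the midpoint of the projected class means. Individual
kernels are 4-connected components of the resulting mask; components under
50 px are discarded as classifier speckle. Each kernel's spectrum is the
arithmetic mean over its ROI pixels, and the two acquisitions of each tray
(the second with the tray rotated 180°) are averaged per kernel —
averaging, rather than concatenation, was chosen because the two
acquisitions estimate the same quantity under independent scatter;
the choice is configurable at the `merge_acquisitions()` level by the
caller.

A note on stepwise thresholds: the entry test is repeated over every
candidate band, so at $F = 3.84$ (per-test $\alpha \approx 5\%$) the
family-wise false-entry rate grows with the band count. The package keeps
the classic defaults, and the test suite verifies the no-false-entry
property at the multiplicity-corrected threshold
$F_{1-\alpha/B}(1, n-2)$, where it holds by construction.

### Spectral pretreatment

The WinISI-style code vocabulary is implemented exactly as printed in
calibration reports, e.g. `"SNV+detrend 2,5,5,1"`: a scatter-correction
stage (SNV, detrend, MSC, or none) followed by a gap–segment derivative
stage `d,g,s1,s2` — derivative order, gap in bands, first and second
running-mean widths. Conventions fixed here (the sources of ambiguity in
the code vocabulary):

* scatter correction is applied before the derivative (a
  `derivative_first` flag reverses this);
* the gap derivative uses a central stencil, $D_i = s_{i+g} - s_{i-g}$ for
  $d = 1$ and $D_i = s_{i-g} - 2 s_i + s_{i+g}$ for $d = 2$; edge bands
  without full support are dropped, never padded, and the surviving
  wavelength grid travels with the result;
* a smoothing width of 1 means no smoothing; even widths round up to odd
  with a warning;
* the MSC reference (the calibration-set mean spectrum) is recorded at fit
  time and reused verbatim at prediction time.

### Sample selection

A PCA on pretreated spectra (default `"SNV 2,5,5,1"`) retains the smallest
number of components explaining 99 % of variance. The standardized global
Mahalanobis distance

$$H_i = \frac{1}{k} \sum_{j=1}^{k} \left(\frac{t_{ij}}{s_j}\right)^2$$

has training mean exactly $(N-1)/N$, which makes the conventional outlier
cut $H > 3$ meaningful on this scale; the pairwise version (NH) with the
same standardization defines spectral equivalence at $\mathrm{NH} < 0.9$.
Groups are formed greedily — the unassigned sample with the most unassigned
neighbours seeds a group and absorbs them, ties broken by lowest index —
which is deterministic and testable against brute force at small N. The
calibration set takes each group seed; the validation set takes the member
closest to its seed where one exists; everything else is predicted only.
Whether the underlying convention uses squared or root distances is not
documented anywhere authoritative; the squared form with mean-1 scaling is
fixed here and stated.

### Modified PLS

MPLS is single-response PLS with one modification: after each factor is
extracted (weight $w \propto X^\top y$, scores $t = Xw$, loadings
$p = X^\top t / t^\top t$, $q = y^\top t / t^\top t$, deflation), every
spectral residual column and the chemistry residual are divided by their
standard deviations before the next factor. The per-factor scalings are
stored so that prediction replays the exact deflate-then-rescale sequence;
with all scalings forced to one the algorithm is standard PLS, which is the
package's cross-check (an independently written PLS oracle must agree to
$10^{-8}$).

The factor count minimizes SECV over contiguous-after-shuffle
cross-validation folds (6 by default — the 4–6 segment convention of
NIR calibration software; 6 keeps segment sizes reasonable at
calibration-set sizes around 40–50). No parsimony rule (1-SE or similar) is
applied, matching the plain "establish the number of PLS factors"
formulation. $F_{\max} = \min(15, \lfloor N/3 \rfloor)$ caps the search.
Chemistry outliers are removed iteratively: $T_i = |y_i - \hat
y_{cv,i}|/\mathrm{SECV}$, samples with $T > 2.5$ dropped (strict
inequality), model refit, at most two passes, never below 10 samples. The
denominator uses cross-validated residuals and SECV — the statistic's exact
denominator is not documented in the originating software; this choice is
flagged and the threshold configurable.

### Validation statistics

$\mathrm{SEC} = \sqrt{\mathrm{SSE}/(n-f-1)}$,
$\mathrm{SECV} = \sqrt{\sum e_{cv}^2 / n}$, calibration
$\mathrm{RSQ} = 1 - \mathrm{SSE}/\mathrm{SST}$, bias-corrected
$\mathrm{SEP} = \sqrt{\sum (e - \bar e)^2/(n-1)}$ (RMSEP reported
alongside, since report conventions differ on bias correction), the
applicability range $\mathrm{Est.Min/Max} = \bar y \mp 3\,\mathrm{SD}$, and
percent errors relative to the range midpoint,
$100\,\mathrm{err} / ((\mathrm{Est.Min} + \mathrm{Est.Max})/2)$, rounded
half-even to 3 decimals in reports.

### Composition statistics

Family totals are fixed sums (4 SFA, 8 MUFA, 4 PUFA acids). Variety
summaries are mean ± SE; grand means are **unweighted** averages of variety
means — the convention under which the package's worked summary numbers
(family grand means near 9.4/14.4/76.2, the oleic ≈ 90 %-of-MUFA share, the
Franquette MUFA/PUFA ratio ≈ 0.23) are reproducible; sample-weighted means
would not be. Variety comparisons use one-way ANOVA with Tukey–Kramer
pairwise tests (valid under unequal group sizes) and a compact letter
display computed exactly as the maximal cliques of the non-significance
graph, so two varieties share a letter if and only if they are not
significantly different at $\alpha = 0.05$.

## The synthetic-data generator

### Chemistry

Each variety profile carries the analyte means and standard errors of a
GC-FID/Soxhlet reference survey of five commercial varieties (Chandler,
Franquette, Howard, Lara, Tulare) plus `n_ref`, the kernel count behind the
SEs. A sample draws each of the 16 acids independently from
$N(\mu, \sqrt{n_{ref}}\,\mathrm{SE})$ — the per-sample SD the printed SE
implies — truncates at zero and renormalizes the acids to sum exactly to
100. The closure induces the compositional negative correlation between
acids (and necessarily shrinks the spread of high-share acids such as
linoleic; the generator's calibration tests account for this). No further
within-variety correlation between acids is imposed: nothing authoritative
quantifies it, and assuming none is the declared, weaker choice.

### Optics

Kernel absorbance follows Beer–Lambert mixing over five components (fat,
SFA, MUFA, PUFA, moisture), each a sum of 2–3 Gaussian absorptivity bands
placed in the 1150–1500 nm first-overtone region with heights putting
typical kernel absorbance in $[0.1, 1.2]$. Noise terms, all configurable in
`noise_config()` and chosen as realistic bench-top values:

| term | default | acts as |
|---|---|---|
| `sensor_sd` | 0.005 AU | per-pixel additive noise |
| `scatter_sd` | 0.05 | per-kernel multiplicative factor |
| `baseline_sd` | 0.01 AU | per-kernel additive offset |
| `jitter_sd` | 0.01 | per-pixel path-length factor |
| `structured_sd` | 0.006 AU | smooth per-kernel spectral deviations |
| `reference_sd` | 0.5 (analyte units) | chemistry measurement error |

The `structured_sd` term (a handful of random Gaussian bumps per kernel)
deserves a note: without it the five-component mixing model produces
spectra of intrinsic dimension ~3, unlike real kernel spectra, whose
heterogeneity needs on the order of a dozen principal components for 99 %
of variance. Its default amplitude was set once so that the selection stage
reproduces that reported granularity — about 12 PCs, about 43 NH groups and
about 100 non-selected samples from 165 kernels — and is not otherwise
tuned. `reference_sd` separates the reported chemistry from the composition
the spectra encode; it is the noise floor that external prediction errors
are compared against in the recovery tests.

Scenes render kernels as irregular ellipses (300–900 px on the default
320×256 scene) on a flat 0.85-reflectance background, wrap reflectance into
raw counts as $\mathrm{raw} = \mathrm{dark} + R(\mathrm{white} -
\mathrm{dark})$ — making two-point calibration exactly invertible when
noise is off — and re-render the same kernels at 180°-rotated positions
with fresh noise for the second acquisition. Layout and noise draw from
separate seed streams so layout can be held fixed while noise varies.

### What passing tests do and do not show

The generator is linear by construction, so PLS-family models are correctly
specified; parameter recovery demonstrates that the chain is implemented
correctly, not that walnut spectra are linear. It does not emulate
instrument line-spread, detector nonlinearity, moisture-temperature
interactions, or biologically realistic acid-acid correlation beyond
closure. Headline prediction errors from the original walnut study are not
reproducible without its (undeposited) data; the package's recovery
criteria are therefore stated against the generator's own noise floor.

## Problem sizes and numerical choices

The test suite runs the imaging chain on 140×120-px scenes over a 29-band
grid (950–1650 nm in 25 nm steps) and the recovery suite on kernel-mean
spectra simulated directly from the optical model (165 samples × 216
bands), sizes chosen to keep the full suite fast while exercising every
code path; the package defaults remain full-scale. Degenerate inputs are
contracts, not surprises: zero-variance spectra fail SNV loudly with sample
names, MSC slopes below $10^{-8}$ fail, exhausted band support in the
derivative fails, empty analyte lists fail validation, and sub-3-sample
validation sets yield `NA` SEP columns with a warning rather than silent
numbers. Model serialization writes JSON at 17 significant digits so
reloaded models predict bitwise-identically.

## Known limitations

* The NH grouping is greedy; it is deterministic and near-minimal but not
  provably minimal, and permuting input order can change tie-broken seeds.
* The T-statistic denominator (SECV) and the bias-corrected SEP are
  conventions chosen among undocumented alternatives; both are flagged and
  the alternative (RMSEP) reported.
* Band selection for segmentation inherits the multiplicity behaviour of
  stepwise testing at fixed F thresholds; with many uninformative bands a
  few false entries are expected at the 3.84 default.
* `anova_tukey()`'s letter display enumerates subsets and is exact only up
  to ~12 groups — ample for variety comparisons, not for large designs.
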