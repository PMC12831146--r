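---
title: "Quantifying choriocapillaris flow deficits at perforating scleral vessel sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow deficits at perforating scleral vessel sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The choriocapillaris (CC) is the capillary bed immediately beneath Bruch's
membrane; on en-face OCT angiography its perfusion is summarized as the
flow-deficit percentage (CCFD%): the fraction of evaluable area whose flow
signal falls below a local threshold. Perforating scleral vessels (PSVs) —
presumed short posterior ciliary arteries — enter the choroid at discrete
sites, and the perfusion immediately at and around those entry sites
(FDPSV within the traced entry ROI, FD250 within a concentric 250-µm ring)
may behave differently from the global CC, especially in axially elongated
(myopic) eyes. `psvcc` implements the full measurement chain from an
en-face slab pair to those quantities, plus the mixed-model statistics
used to relate them to ocular covariates, and a synthetic-scene generator
that provides ground truth for every stage.

## The quantification chain

**Compensation.** Signal attenuation (media opacity, vignetting, shadow)
multiplies the OCTA flow slab and the structural OCT slab of the same
anatomy by the same local factor. `compensate()` therefore divides the
flow image pixel-wise by the structural image (equivalently, multiplies by
its inverse), floors the divisor at `eps_frac` (default 1%) of the
structural maximum to keep near-zero pixels finite, and rescales the
result so its maximum is 1 (the minimum is left anchored, preserving
proportionality). For a noise-free pair sharing one attenuation field the
ratio is attenuation-free up to the epsilon floor.

**Binarization.** `phansalkar_binarize()` applies the Phansalkar local
threshold, designed for low-contrast images: over a circular window of
physical radius `radius_um` (default 23.4 µm) around each pixel,

$$ t = \mu_w \left(1 + p\,e^{-q\mu_w} + k\left(\frac{\sigma_w}{r} - 1\right)\right), $$

with window mean $\mu_w$ and population SD $\sigma_w$, and constants
$k = 0.25$, $r = 0.5$, $p = 2$, $q = 10$ on $[0,1]$-scaled images — the
parameterization in common use by auto-local-threshold implementations.
Pixels with intensity $\le t$ are flow deficits ("dark pixels"); the tie
goes to deficit so that an all-zero image is all-deficit. Borders are
handled by symmetric (edge-repeating) reflection. The window radius is
converted to pixels by rounding; the default 6-mm / 1024-px geometry has a
5.859-µm pitch, making 23.4 µm exactly 4 px, which is why that raster is
the default. A radius below one pixel is an error rather than a silent
global threshold.

The implementation accumulates window sums and sums of squares over the
shifted-copy stack of the disc offsets, which is algebraically the
explicit per-pixel definition; the test suite verifies exact mask equality
against an independent sliding-window loop on random images.

**Vessel exclusion.** CC signal under large retinal vessels is shadow, not
perfusion. `vessel_exclusion_mask()` binarizes the superficial-plexus
image by Otsu's global threshold, removes sub-caliber specks with a
Euclidean morphological opening (default radius 10 µm), and dilates the
result isotropically by `dilation_um` (pipeline default 50 µm) to buffer
shadow margins. The source study masked "large" vessels without stating a
recipe, so this is a stated package default, not a reproduction; both
radii are configurable. A featureless image yields an empty mask.

**Flow-deficit metrics.** `fd_percent()` computes
$100\,|D \cap R \setminus E| / |R \setminus E|$ for deficit mask $D$, ROI
$R$ and exclusion $E$; an empty evaluable area raises an error rather than
returning 0. `fd_psv_metrics()` evaluates this within the PSV ROI (FDPSV)
and within `ring_mask()`, the set of pixels whose Euclidean distance to
the ROI is in `(0, width]` with `width = 250` µm by default. The ring is
built from an exact squared Euclidean distance transform
(Felzenszwalb–Huttenlocher two-pass, implemented in C++), so the ring
width is isotropic in physical units and the membership test compares
exact integer squared distances — iterated structuring-element dilation
would make the width direction-dependent. Rings clipped by the image
border are flagged.

**Vessel-to-fovea distance.** `vfd()` overlays a square grid of cells of
area `unit_area_mm2` (default 0.1 mm²) anchored at the fovea, computes the
centroid $(X_i, Y_i)$ of the ROI's intersection with every cell it meets,
and returns the mean of $d_i = \sqrt{(X_i - X_0)^2 + (Y_i - Y_0)^2}$
together with the mean X and Y offsets. Two open choices were resolved as
follows. First, "0.1 mm² units" is read literally as a cell *area*
(side ≈ 0.316 mm) even though typical PSV ROIs (≈ 0.05 mm²) are smaller
than one cell; ROIs smaller than a cell fall back to the single whole-ROI
centroid ($N = 1$) and are flagged, and `unit_area_mm2` is configurable
for the side-length reading. Second, the grid is anchored at the fovea,
which makes the measure exactly translation-equivariant (shifting ROI and
fovea together changes nothing) and reduces to the per-pixel mean distance
when the cell area equals the pixel area. The fovea defaults to the frame
centre (scans are fovea-centred) and can be overridden.

**Magnification correction.** Device measurements assume a nominal eye;
axial elongation magnifies the retinal image. The abbreviated
Bennett–Littmann factor $F = 3.48 \times 0.01306 \times (AXL - 1.82)$
converts nominal to true dimensions: distances scale by $F$, areas by
$F^2$, and dimensionless percentages are unchanged. Correction is applied
*post hoc* — metrics are computed in nominal units and then scaled — and
$AXL \le 1.82$ mm is a domain error. The choroidal-thickness index CT/AXL
(µm/mm) is carried as a covariate.

## The statistical stage

One eye contributes several PSVs and one subject up to two eyes, so
observations are not independent. `fit_mixed()` fits
`response ~ fixed terms + (1|subject) + (1|subject:eye)` by maximum
likelihood (lme4), reporting Wald estimates, 95% CIs and z-based p-values,
the three variance components, and a marginal R² (fixed-effect variance
over total). The ML/Wald choice mirrors the convention of reporting
per-term p-values from ML fits that also support likelihood-ratio testing;
profile or Kenward–Roger intervals were evaluated during development and
changed intervals negligibly at the cohort sizes involved. Singular
(boundary) fits are flagged in the result, not raised: a zero variance
estimate is a legitimate outcome. When no cluster contains more than one
observation the marginal covariance is proportional to the identity for
any variance split, so fixed effects then equal ordinary least squares
exactly — the degenerate case the tests pin down.

`spearman_screen()` (tie-corrected rank correlations), `vif()`
($1/(1-R_j^2)$, with ∞ for perfect collinearity), `icc_repeatability()`
and `posthoc_power()` complete the stage. The ICC form is two-way
mixed-effects, absolute-agreement, single-measurement — the standard
choice for intra-grader repeatability when the grader is fixed — with the
McGraw–Wong F-based confidence interval; duplicated sessions give exactly
1, and zero variance everywhere is undefined (`NA`). Post hoc power uses
the noncentral t-distribution with noncentrality $\hat\beta/SE$, degrees
of freedom $n_{\mathrm{eff}} - k - 1$ where $n_{\mathrm{eff}}$ defaults to
the subject count (the subject-level effective sample size), and two-sided
$\alpha$; at $\hat\beta = 0$ the power equals $\alpha$ exactly.

## What the synthetic scenes emulate — and what they do not

`generate_cc_scene()` builds a matched flow/structure/superficial triple
with ground truth:

- **CC texture**: white noise band-passed at `texture_scale_um` (default
  94 µm, giving deficit patches of roughly 200–400 µm) and thresholded at
  the `deficit_fraction_target` quantile (default 0.18, a healthy-myopic
  global CCFD burden), so truth deficits are contiguous blobs realizing
  the target fraction almost exactly. Flow is bimodal — deficit floor 0.08,
  perfused plateau 0.70 — with a logistic transition of width 0.05 texture
  SDs (≈ 1 px, emulating ~20-µm optical resolution).
- **Attenuation**: one smooth multiplicative field (sum of three Gaussians
  of 1.5–3 mm width, normalized, scaled to `attenuation_amplitude`,
  default 0.3) applied identically to flow and structure — exactly the
  artifact class compensation targets. The field's random draws are
  consumed even at amplitude 0, so scenes with the same seed differ only
  in attenuation.
- **Superficial plexus**: a procedural branching tree of 60–120-µm-caliber
  vessels, bright over a dim background, with the rasterized truth mask
  returned for Dice-style checks.
- **PSV ROIs**: disjoint ellipses (semi-axes 60–220 µm, giving areas near
  the 0.05-mm² cohort scale) placed uniformly in an 0.8–2.5-mm annulus
  around the fovea — matching a 1.50 ± 0.69 mm VFD scale — rejecting
  positions on the vessel tree, with a bounded-retry packing error.
- Pixels are snapped to the 16-bit grid, so file round trips are
  bit-identical and generation is exactly reproducible by seed.

Not emulated: OCT speckle statistics, projection artifacts, B-scan
geometry, staphyloma or tilt, and any dependence of the CC texture on the
vessel tree or the PSVs themselves. Passing recovery tests on these
scenes therefore demonstrates that the measurement chain is correct and
attenuation-invariant, not that the specific Phansalkar constants are
optimal for any particular device.

`generate_cohort()` simulates the tabular side: subject-level age
(28.3 ± 7.0 y), eye-level axial length (25.28 ± 1.09 mm), spherical
equivalent (−4.03 ± 1.71 D), choroidal thickness (187 ± 60 µm) and global
CCFD% (17.86 ± 10.58), PSV-level area (lognormal, mean 0.052 mm²) and VFD
(1.50 ± 0.69 mm), with 1 + Poisson(1.3) PSVs per eye and both eyes present
with probability 0.68. The response adds the configured fixed effects to
nested Gaussian intercepts (subject SD 4, eye SD 2.5, residual SD 5 —
chosen so the marginal response SD lands near the observed 12%-point FDPSV
spread) and is deliberately not clipped to [0, 100], keeping refits
unbiased. Axial length and global CCFD are drawn jointly at correlation
`confound_axl_ccfd` (default 0.47). The default fixed effects are
adjusted-scale coefficients (age 0.230, AXL −2.372, SE −0.434, CT 0.013,
CCFD 1.022, area 16.518, VFD −1.153, intercept 48.529), which reproduce a
mean FDPSV of ≈ 16.5% at the covariate means; with the confound raised
toward 0.8 the cohort exhibits the signature behavior of collinear
predictors — a positive *marginal* (univariable) AXL association with a
negative *adjusted* (multivariable) AXL coefficient — which the test suite
demonstrates end-to-end.

## Numerical choices and degenerate inputs

- Deficit polarity is `intensity <= threshold`; ties count as deficit.
- Window sums use shifted-copy accumulation; variance is floored at 0
  before the square root.
- The compensation floor is 1% of the structural maximum; an all-zero
  structural image is an error.
- Ring membership compares exact integer squared pixel distances against
  `(width/pitch)^2`; ROI pixels themselves are never ring pixels.
- The VFD grid cell index is `floor((x - x_fovea)/side)`; a pixel centre
  exactly on a cell boundary belongs to the upper cell.
- Quantile thresholding of the texture field makes the realized deficit
  fraction exact up to ties; targets of exactly 0 or 1 bypass the texture
  and produce uniform scenes.
- `fd_percent` on an empty evaluable region, an empty `psv_roi`, a
  sub-pixel threshold radius, axial length ≤ 1.82 mm, and infeasible ROI
  packing all raise informative errors rather than degrade silently.

## Problem sizes used by the test suite

The recovery and invariance properties are exercised at the default
1024-px scan raster over 20 seeds; binarization/ring/VFD oracle
equivalence uses 64–128-px rasters where brute-force loops are exact and
fast; mixed-model calibration uses 200 simulated cohorts of 400 subjects
and the confounding demonstration 100 cohorts of 150 subjects. These
sizes were chosen so each property is measured with useful precision while
the whole suite stays interactive. One calibration note: the per-term CI
coverage of a 200-replicate experiment has a binomial SD of about 1.5
percentage points, so individual observed coverages scatter a few points
around their true values even for an exactly nominal interval;
conditional Wald intervals themselves are known to be mildly
anticonservative for cluster-level covariates.

## Known limitations

- The Phansalkar constants, the Otsu-based vessel recipe and the 50-µm
  dilation are field-standard defaults, not device-validated settings;
  real slabs may need tuning, and the package deliberately exposes every
  constant in the pipeline configuration.
- Slab segmentation, projection-artifact removal and PSV detection are
  out of scope: ROIs and slabs are inputs.
- The generator's attenuation is smooth and multiplicative; additive noise
  floors (low signal strength) violate the compensation model and are only
  represented by the small additive `noise_sd`.
- Magnification correction uses the abbreviated Bennett–Littmann formula;
  eyes outside its intended range (extreme ametropia, post-surgical) need
  a different model.
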