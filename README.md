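# psvcc

Quantification of choriocapillaris (CC) flow deficits at perforating
scleral vessel (PSV) entry sites from en-face swept-source OCTA slabs,
with the downstream statistics for myopic-eye cohorts — and a synthetic
scene/cohort generator with known ground truth so the whole chain is
testable without patient data.

**Who it is for.** Researchers quantifying CC perfusion on en-face OCTA:
the package turns a (flow, structure, superficial) slab triple plus traced
PSV ROIs into global CCFD%, per-PSV FDPSV / FD250, magnification-corrected
areas and vessel-to-fovea distances, and fits the nested mixed-effects
models that respect the PSV-within-eye-within-subject structure.

## The measurement chain

1. **Compensation** — the flow slab is multiplied pixel-wise by the
   inverse of the structural slab of the same layer (floored at 1% of its
   maximum), cancelling shared multiplicative attenuation.
2. **Binarization** — Phansalkar local thresholding over a circular
   window of radius 23.4 µm:
   `t = mu_w * (1 + p*exp(-q*mu_w) + k*(sigma_w/r - 1))`
   with k = 0.25, r = 0.5, p = 2, q = 10 on [0, 1] images; pixels ≤ t are
   flow deficits.
3. **Vessel exclusion** — Otsu binarization of the superficial plexus,
   morphological opening, isotropic dilation (default 50 µm); CC under
   large retinal vessels is shadow and is excluded from every metric.
4. **Metrics** — CCFD% = dark fraction of evaluable area; FDPSV within
   the PSV ROI; FD250 within an exact-Euclidean 250-µm ring around it;
   PSV area; VFD = mean distance of 0.1-mm² grid-cell centroids of the
   ROI to the fovea, decomposed into X/Y offsets.
5. **Magnification** — Bennett–Littmann factor
   `F = 3.48 * 0.01306 * (AXL - 1.82)`: distances scale by F, areas by
   F², percentages are invariant.
6. **Statistics** — Spearman screens; linear mixed models with nested
   random intercepts `(1|subject) + (1|subject:eye)` fitted by maximum
   likelihood; VIFs; ICC(A,1) repeatability; noncentral-t post hoc power.

See `vignettes/psv-flow-deficits.Rmd` for the full methods account.

## Worked example

```r
library(psvcc)

# a 6 x 6 mm, 1024-px synthetic scene with 18% true deficit burden
sc <- generate_cc_scene(scene_params(seed = 7))

comp    <- compensate(sc$flow, sc$structure)
deficit <- phansalkar_binarize(comp)
excl    <- vessel_exclusion_mask(sc$superficial, dilation_um = 50)

fd_percent(deficit, excl)
#> <fd_result> CCFD 17.164% over 940943 evaluable px (107633 excluded)

m <- fd_psv_metrics(deficit, excl, sc$psv_rois[[1]], geom = sc$geometry)
v <- vfd(sc$psv_rois[[1]], fovea_xy = sc$fovea_xy, geom = sc$geometry)
# FDPSV 17.41%  FD250 19.82%   area 0.0469 mm2   VFD 2.31 mm

d   <- generate_cohort(cohort_params(seed = 7))
fit <- fit_mixed(d, "fd_psv", c("age_y", "axl_mm", "global_ccfd_pct"))
fit
#> <psv_model> 104 PSVs, 48 eyes, 31 subjects; R2 = 0.730
#>              term estimate      se  ci_low ci_high   p_value
#> 1     (Intercept)  38.3232 24.6106 -9.9128 86.5592 1.194e-01
#> 2           age_y   0.3354  0.1143  0.1114  0.5595 3.338e-03
#> 3          axl_mm  -1.8843  1.0132 -3.8702  0.1016 6.293e-02
#> 4 global_ccfd_pct   0.9555  0.0843  0.7903  1.1207 8.863e-30
#> variance components: subject 7.84, eye 10.7, residual 26.5
```

The recovered global CCFD of 17.2% estimates the generator's 18% truth on
the vessel-excluded area; the mixed model attributes the response variance
to subject, eye-within-subject and residual components while estimating
the fixed effects on their clinical scales (%-points per year, per mm of
axial length, per %-point of global CCFD).

A thin command-line wrapper over the same functions is installed at
`inst/cli/psvcc.R` with subcommands `simulate`, `quantify`, `stats`,
`all`.

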