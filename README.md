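# cardiodti

Analysis pipeline for **multi-phase in vivo cardiac diffusion tensor MRI**
of the left ventricle. Cardiac DTI maps the local orientation of
cardiomyocyte aggregates and their laminar sheetlets from the eigenvectors
of the voxelwise diffusion tensor; imaging the same mid-ventricular slice at
several cardiac phases (early systole, late systole, diastasis) turns those
maps into *mobility* measures of the contracting myocardium. The package is
aimed at cardiac MR physicists and image-analysis researchers who need a
tested, scriptable implementation of this analysis chain, together with a
synthetic phantom for validation when volunteer data are not at hand.

## What it computes

For the diffusion signal `S(g, b) = S0 exp(-b gᵀ D g)`:

* **Encoding waveform audit** — gradient moments
  `M_k = ∫ G_eff(t) t^k dt` and `b = γ² ∫ q(t)² dt` of the symmetric
  second-order motion-compensated trapezoid train, with exact analytic
  integration and amplitude solving via `b(G) = G² b(1)`.
* **Preprocessing** — phase-correlation rigid registration (translation,
  1/200 px refinement), repetition averaging, k-space zero-fill
  interpolation (1.6 → 0.8 mm).
* **Tensor fit** — log-linear initialization + per-voxel
  Levenberg–Marquardt NLLS; eigenvalues λ1 ≥ λ2 ≥ λ3, MD, FA, λ2/λ1.
* **Microstructure angles** — helix angle
  `HA = ∠(proj_tangent E1, c)`, transverse angle
  `TA = ∠(proj_horizontal E1, c)`, sheetlet angle E2A (|angle| of E2's
  projection in the cross-myocyte plane), the one-SD linear-model 180°
  unwrap filter, nine-node transmural profiles,
  `HAR = HA_endo − HA_epi` and ΔHAR between phases, per AHA mid-cavity
  segment and globally.
* **TD-scout analysis** — trace-signal means in a 48 mm central disk per
  trigger delay, normalization, and acquisition-window suggestions.
* **Group statistics** — median [Q1, Q3], Kruskal–Wallis with
  Bonferroni-corrected Dunn post hocs, ICC(2,1) reproducibility.
* **Synthetic LV phantom** — annular slices with prescribed transmural HA
  law, E2A, eigenvalues, per-phase contraction geometry, repetitions with
  misregistration shifts and Rician noise; ground truth returned alongside.

All tabular results are tibbles; fitted/statistical objects have `tidy()`
and `glance()` methods; result types have `autoplot()`/`plot_*()` figures.
Images travel as NIfTI with FSL-style `.bval`/`.bvec` sidecars (directions
in the image frame; no scanner-frame rotation), contours and tables as CSV.

## Worked example

```r
library(cardiodti)

# 1. the protocol's encoding waveform: amplitude for b = 350 s/mm^2
G <- solve_amplitude_for_b(target_b = 350)
waveform_report(build_symmetric_waveform(amplitude = G))
#> amplitude 71.67 mT/m, b = 350 s/mm^2, M0 = 0 mT/m ms, TE = 61.6 ms

# 2. simulate and analyse one late-systolic acquisition
#    (12 directions x 8 repetitions + b0/rep = 104 images, SNR(b0) = 20)
cfg <- pipeline_config(phases = "late_systole", seed = 42)
run <- run_pipeline(cfg)
run$har[run$har$segment == "global", ]
#> # A tibble: 1 × 3
#>   phase        segment   har
#>   <chr>        <chr>   <dbl>
#> 1 late_systole global   89.4
```

The phantom prescribes a 53.3° → −41.3° transmural helix-angle span
(HAR = 94.6°); the recovered global HAR of ≈ 89.4° shows the noisy
protocol run recovering myofiber geometry to within a few degrees.
`run$phases$late_systole$maps` holds the HA/TA/E2A/MD/FA maps
(`plot_angle_map(run$phases$late_systole$maps$ha, limits = c(-90, 90))`),
`$profile` the nine-node transmural profile, and `run$delta_har` the
phase-pair mobility table when several phases are configured.

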