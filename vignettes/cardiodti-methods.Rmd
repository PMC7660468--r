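---
title: "Methods: multi-phase cardiac DTI analysis with cardiodti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-phase cardiac DTI analysis with cardiodti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiodti)
```

## Scope and model

`cardiodti` analyses diffusion-weighted short-axis images of the left
ventricle (LV) acquired at several cardiac phases and reduces them to the
microstructural quantities used to describe cardiomyocyte and sheetlet
mobility:

* voxelwise diffusion tensors `D` from the signal model
  `S(g, b) = S0 exp(-b g' D g)`;
* helix angle (HA), transverse angle (TA) and sheetlet angle (E2A) from the
  projections of the first two tensor eigenvectors onto local cardiac axes;
* nine-node transmural HA profiles, the helix angle range
  `HAR = HA(endo) - HA(epi)`, and its change between phases (ΔHAR);
* non-parametric group statistics (median [Q1, Q3], Kruskal–Wallis with
  Bonferroni-corrected Dunn post hocs) and ICC reproducibility measures.

Because volunteer acquisitions are external data, the package ships a
synthetic LV phantom that reproduces the statistical structure the analysis
assumes, and every stage is validated against it.

## Diffusion encoding waveform

The spin-echo diffusion module uses a symmetric second-order
motion-compensated waveform: two trapezoidal lobe pairs with total durations
7.2/12.6 ms (ramp 1.52 ms) on either side of the refocusing pulse, physical
polarities (+,−,−,+), so the effective pattern after the 180° inversion is
(+,−,+,−) and the zeroth moment cancels exactly, desensitising the echo to
bulk displacement; the short lobes and alternating signs strongly reduce the
velocity (M1) and acceleration (M2) moments relative to a monopolar design.
Moments are integrated analytically per trapezoid segment (reference time =
excitation pulse centre), and the b-value is the exact piecewise-quartic
integral of `q(t)^2`; a fine-grid numeric quadrature serves as cross-check
in the tests.

**Timing reconstruction.** The sequence diagram leaves the exact placement
of the encoding-free interval between the lobe pairs open. The package's
default timing set (`cdti_timings()`) packs the lobes against the excitation
side and inserts a 16 ms interval between the pairs, composed of the
navigator interval (8 ms), the refocusing pulse (4 ms) and the residual
dead time (4 ms). Two observations support this reading: the spin-echo
condition then puts the echo at 61.6 ms, matching the protocol TE of 61 ms,
and solving the amplitude for b = 350 s/mm² returns 71.67 mT/m, within 0.5%
of the protocol's 71.3 mT/m. Under this reconstruction the residual M1/M2
are larger than the scanner's printed in-line values (which correspond to a
shorter interval at which the chosen lobe durations null M1 almost exactly,
but which is not compatible with the printed amplitude); we therefore treat
residual moments as magnitude checks against the monopolar reference rather
than as exact targets. `b(G) = G² b(1)` holds to machine precision, so the
amplitude solve is a single unit-amplitude evaluation.

## Synthetic phantom: what it emulates, and what it does not

`make_phantom()` builds an annular mid-ventricular slice per cardiac phase:

* **Geometry.** Concentric endo/epi circles; contraction is modelled purely
  geometrically (late systole: smaller cavity, thicker wall; diastasis:
  larger cavity, thinner wall). Defaults: endo/epi radii 18/31 mm (early
  systole), 14/32 mm (late systole), 22/32 mm (diastasis) on a 72×72 grid at
  1.6 mm — wall thicknesses and cavity sizes typical of a healthy
  mid-ventricular slice.
* **Microstructure.** HA is linear in normalized transmural depth between
  the per-phase endo/epi values (44.4/−33.8°, 53.3/−41.3°, 55.0/−33.8°),
  matching the linear model the unwrap filter assumes; TA = 0 (healthy
  medians are near zero; no per-segment truth law is available, so this is
  a package choice); E2A is spatially constant per phase (27.7/45.2/20.7°),
  because one median per phase is the reported quantity. Eigenvalues come
  from the healthy medians (λ1/λ2 2.52/1.68 and 2.08/1.45 ×10⁻³ mm²/s for
  early/late systole, λ3 chosen so MD matches 1.79/1.53 ×10⁻³ mm²/s); the
  diastasis set (2.30/1.587/1.033 ×10⁻³) is derived from the reported MD
  1.64 ×10⁻³ mm²/s and λ2/λ1 ≈ 0.69, since its eigenvalues are not printed
  individually.
* **Acquisition.** One b = 0 plus twelve diffusion directions (deterministic
  spherical-Fibonacci hemisphere set), eight repetitions, per-repetition
  in-plane translations ~ N(0, 0.8 px), and Rician noise
  (`|S + n1 + i n2|`). The default channel SD of 0.05 with `s0 = 1` gives
  SNR(b0) = 20 per repetition. All randomness flows through one seed
  recorded in the phantom spec and the run manifest.

The phantom deliberately omits EPI distortion, fat shift, off-resonance,
through-plane motion, wall-thickness variation around the circumference,
per-segment HA laws, and partial-volume blood signal. Passing recovery tests
therefore demonstrates that the *analysis chain* is unbiased under its own
assumptions — not that real acquisitions are free of these confounds.

## Preprocessing

Registration is translation-only phase correlation (cross-power spectrum,
two-stage upsampled-DFT refinement to 1/200 px) with Fourier-shift
resampling, chosen because residual bulk motion in a breath-gated single
slice is dominantly translational; the rotation-free choice is swappable.
b = 0 images are registered to the first b = 0; everything else is
registered to the mean registered b0 (highest-SNR anchor). Because the
reference image's own displacement defines the output frame, the pipeline
re-centres the registered stack on the contour centroid using the b0
intensity centroid — the phantom-study analogue of drawing contours on the
registered data. Correlation peaks below 0.1 flag low-confidence estimates.
Averaging is the arithmetic mean of magnitudes per (b, direction).
Zero-fill interpolation pads k-space symmetrically (Nyquist bin split for
even sizes, DC preserved), doubling the matrix (1.6 → 0.8 mm) while leaving
the original samples bit-identical on the aligned sub-grid.

The order register → average → zero-fill is a package decision; the
registration estimate is resolution-independent (sub-pixel in the original
grid), so interpolating first would only add cost.

## Tensor fit

The log-linear fit (OLS of `ln S` on `[1, -b g⊗g]`) initializes a per-voxel
Levenberg–Marquardt nonlinear least-squares fit of
`S0 exp(-b g' D g)` (analytic Jacobian, 100 iterations max, cost tolerance
1e-10, via minpack.lm). On noiseless data the two agree to < 1e-8 mm²/s per
component, which is the tested oracle equivalence. Voxels with non-positive
or non-finite signals are flagged and excluded; non-converged voxels fall
back to the initializer and are flagged. Negative eigenvalues (rare at
b = 350) are clipped to 1e-7 with a flag rather than refit under
constraints. All b = 0 signal enters the fit as an S0 observation, not as a
fixed normalizer.

## Geometry and angle conventions

Depth is `d_endo / (d_endo + d_epi)` with exact point-to-segment distances
(0 = endo, 1 = epi). The radial axis is the in-plane unit gradient of depth
(central differences of the continuous depth function, h = 0.05 mm), the
longitudinal axis is the slice normal pointing base-ward, and the
circumferential axis completes a right-handed triad (`l = c × r`),
counterclockwise when viewed from the apex — the sign convention that makes
endocardial HA positive. HA/TA are signed angles of the E1 projections in
the tangent and horizontal planes, reduced to (−90, 90] (axial symmetry).
E2A is measured inside the cross-myocyte plane (normal to E1's tangent
projection) against that plane's wall-tangent direction, reported as an
absolute value in [0, 90]: 0 = sheetlet lying in the wall, 90 = radial.
AHA mid-cavity segments are six 60° sectors about the epicardial centroid,
ordered anterior → anteroseptal counterclockwise; the anterior reference
must be supplied (phantom: configuration; real data: RV insertion).

## Unwrap filter and transmural profiles

The unwrap filter fits `HA = a·depth + b`, flags residuals beyond one SD,
and shifts by 180° only the flagged points that are negative on the
endocardial half or positive on the epicardial half — a single pass, applied
per segment (and globally for the global profile) before profiling. Flips
are one-directional, so re-application cannot undo them; idempotence is
tested on wrapped noisy profiles.

Profiles assign each voxel to the nearest of nine equally spaced depth
nodes and report a per-node median. The two boundary bins are one-sided
(the depth-0 node only sees voxels at depths 0–1/16), so a plain median
there reports the helix angle of the bin centroid, biasing HAR low by about
`slope/16` (≈ 6° for a 95° transmural span). The default therefore
evaluates the node median with the fitted linear slope removed within the
bin (`median(ha - a (depth - node))`): exact at every node for a linear
profile and numerically indistinguishable from the plain median at interior
nodes; `detrend = FALSE` restores the plain median. HAR is the node-1 minus
node-9 median; ΔHAR is computed per subject before any group summary.

## Scout analysis

Trace images (mean over three orthogonal directions) are cropped to a
48 mm-radius disk about the LV centre; per-TD means are normalized by the
maximum across phases. `suggest_windows()` reports, within the nominal TD
ranges (early systole 150–200 ms, late systole 250–350 ms, diastasis
700–900 ms), the best TD and a pass flag at a configurable threshold
(default 0.7). The threshold is a tool default with no published
counterpart — the selection it mimics was visual — so the function flags and
never drops phases.

## Statistics

Group summaries are median [Q1, Q3] with interpolated quartiles
(`quantile` type 7). Phases are compared as independent groups (the study
design is unbalanced) with a tie-corrected Kruskal–Wallis omnibus; when it
rejects at 0.05, Dunn z-tests on the pooled ranks follow with Bonferroni
adjustment over the three pairs. ICC uses the two-way random-effects,
absolute-agreement, single-measure form ICC(2,1) with F-based confidence
bounds — the model is a documented choice (none is named in the source
material) and is evaluated on the observation subsets corresponding to
overall, inter-observer and per-observer intra-observer designs.

## Problem sizes, tolerances and degenerate inputs

Test and acceptance runs use the 72×72 (1.6 mm) phantom for single-run
checks and a 48×48 (2.4 mm) phantom for the 100-replicate ordering study;
these sizes keep the annulus ≈ 6–11 voxels thick, enough for nine-node
profiling, and were chosen as the package's standard simulation sizes.
Key numeric choices: waveform moments analytic vs 1 µs quadrature < 1e-6
relative; NLLS vs log-linear oracle < 1e-8 mm²/s; angle round trips
< 1e-6°; registration refinement to 1/200 px; eigenvalue clip at 1e-7.
Degenerate inputs (all-zero images, radial fibers with undefined HA,
constant-depth unwrap fits, empty profile nodes, zero between-subject ICC
variance) are flagged or warned about, never silently imputed.

## Known limitations

Rotation and non-rigid motion are not corrected; the Rician noise floor is
not modelled in the fit (no Rician-likelihood option); the phantom's
circular symmetry makes AHA segments statistically identical by
construction, so per-segment heterogeneity is exercised only through the
angle prescriptions; and the TD-scout simulator parameterizes signal
dropout directly rather than modelling intra-voxel dephasing.
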