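---
title: "Cardiac DTI postprocessing: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac DTI postprocessing: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtikit)
```

## The signal model and what the pipeline estimates

Diffusion-weighted cardiovascular MR sensitizes the signal of a voxel to the
self-diffusion of water. For a single encoding direction the magnitude signal
follows the mono-exponential model

$$ S = S_0 \, e^{-b D}, $$

where $b$ (s·mm⁻²) summarizes the strength and timing of the encoding
gradients and $D$ (mm²·s⁻¹) is the apparent diffusivity along the encoding
direction. In anisotropic myocardium $D$ generalizes to a symmetric,
positive-semi-definite $3\times3$ tensor and the exponent becomes
$-b\,\mathbf{g}^\mathsf{T} \mathbf{D} \mathbf{g}$ for unit direction
$\mathbf{g}$. Taking logarithms makes the model linear in the six distinct
tensor components plus one intercept ($\log S_\mathrm{ref}$), which
`fit_tensor()` solves per voxel by least squares over all frames.

Three conventions matter and are fixed package-wide:

* **Units.** $b$ in s·mm⁻², diffusivity in mm²·s⁻¹ (myocardium ≈ 1×10⁻³,
  free water at 37 °C ≈ 3×10⁻³). Reports display ×10⁻³ mm²·s⁻¹. Keeping one
  internal unit system avoids silent factor-10³ errors.
* **The intercept is estimated, not fixed.** Stimulated-echo (STEAM)
  acquisitions have no true $b=0$ image — the reference frame is acquired at
  a low but non-zero $b$ (≈50 s·mm⁻², which also suppresses perfusion
  contamination) — so the reference frame enters the fit as an ordinary
  observation at its actual $b$-value.
* **Repetitions are never averaged.** Repeats enter as extra rows of the
  overdetermined system. This preserves per-frame information, which is what
  makes per-beat $b$-value correction possible at all.

### STEAM b-values and per-beat correction

For the monopolar stimulated-echo experiment the diffusion weighting is

$$ b = \gamma^2 \delta^2 G^2 \left( \Delta - \tfrac{\delta}{3} \right), $$

with $\gamma$ the gyromagnetic ratio, $\delta$ the encoding-gradient
duration, $G$ its amplitude and $\Delta$ the time between the paired
gradients — one RR interval for STEAM, so the *actual* diffusion time of
frame $i$ is that beat's RR. With $\gamma$, $\delta$, $G$ fixed, the stated
nominal $b$ rescales per frame as
$b_i = b_\mathrm{nom}\,(RR_i - \delta/3)/(\Delta_\mathrm{nom} - \delta/3)$;
`effective_bvalues()` applies this whenever a STEAM gradient table carries
per-frame RR intervals, both in the simulator and before the fit. The
expression holds only for the monopolar experiment: moment-compensated
spin-echo (MCSE) b-values are taken as given and never rescaled. The proton
$\gamma$ (2.6752×10⁸ rad·s⁻¹·T⁻¹) is the default and overridable, since
consensus documents state timings but not $\gamma$.

## The synthetic phantom: what it emulates, and what it does not

`phantom_spec()` describes an annular mid-ventricular short-axis
cross-section with:

* a **linear transmural helix-angle profile** HA$(d)$ from `ha_endo` (+50°
  default) at the endocardium to `ha_epi` (−50°) at the epicardium — the
  consensus-normal transmural pattern whose fitted slope (HAT) is ≈ −1 °/%
  and whose surface-to-surface range is ≈ 100°;
* a prescribed **transverse angle** (0° default — healthy myocytes run
  essentially circumferentially) and **absolute sheetlet angle E2A** (62°
  default, the end-systolic normal mean; 13° models diastole);
* prescribed **eigenvalues**; the default triple is solved by
  `eigenvalues_from_md_fa()` so that MD = 1.03×10⁻³ mm²·s⁻¹ and FA = 0.47,
  the STEAM systolic normal means, with the shape closed by the ratio
  λ₂/λ₃ = 1.5 typical of in-vivo triples;
* the forward model above, with optional **Rician noise** (two independent
  Gaussian channels of width $\sigma = S_0/\mathrm{SNR}$ under the
  magnitude), injected **signal-dropout frames**, per-beat **RR
  variability**, and optional **trabeculation blobs** flagged in the truth
  for exclusion tests.

Geometry defaults are a 48×48 matrix at 1 mm pixels, radii 10/17 mm (7 mm
wall) and 8 mm slice thickness. One millimetre is finer than the 2.5–3 mm
acquisitions typical in vivo; it is chosen so that the 7 mm wall spans
enough voxels for a 10-bin transmural profile, which is the phantom's job as
a test surface. The default encoding scheme is 12 directions at
b = 450 s·mm⁻² plus one reference at b = 50 (within the typical protocol
values of 450–500 and 50–100).

The eigenvector frame is constructed so that the *projection definitions* of
the angles recover the prescription exactly:
$\mathbf{e}_1 \propto \mathbf{C} + \tan(\mathrm{HA})\,\mathbf{L} +
\tan(\mathrm{TA})\,\mathbf{R}$, whose tangent-plane projection makes exactly
HA with $\mathbf{C}$ and whose short-axis projection makes exactly TA.
$\mathbf{e}_2$ makes the prescribed E2A with the cross-myocyte direction and
is re-orthogonalized against $\mathbf{e}_1$; with TA ≠ 0 this
re-orthogonalization perturbs the recovered E2A by $O(\sin^2 \mathrm{TA})$,
so exact-recovery tests prescribe TA = 0 (the default, and the physiological
expectation).

The phantom does **not** simulate EPI distortion, fat ghosts, perfusion,
partial volume at the blood pool, myocardial strain during the mixing time,
through-plane motion, or multiple interpenetrating sheetlet families.
Passing tests therefore demonstrate that the *postprocessing mathematics* is
correct and that the pipeline's statistical behaviour under Rician noise,
dropout and RR jitter is as documented — not that any given scanner
protocol will achieve these numbers in vivo.

## Angle definitions and the local wall frame

Per voxel the wall frame is radial $\mathbf{R}$ (endocardium → epicardium),
circumferential $\mathbf{C}$, longitudinal $\mathbf{L}$ (slice normal,
apex → base), right-handed with $\mathbf{C} = \mathbf{L} \times \mathbf{R}$.
Transmural depth is $d = 100\,d_\mathrm{endo}/(d_\mathrm{endo} +
d_\mathrm{epi})$ from *signed* distances to the two contours — signedness
keeps the depth field differentiable across the contours, so its
finite-difference gradient (which defines $\mathbf{R}$) is stable for
voxels hugging a contour. With polygonal contours the gradient direction
carries a faceting error of order $2\pi/n_\mathrm{points}$ (≈0.013 rad at
180 contour points), which is negligible for the binned transmural
statistics but is the reason exact-recovery tests use the analytic truth
frames rather than contour-derived ones.

All three angles use projections, with eigenvector sign ambiguity removed
by orienting each projection along $+\mathbf{C}$ (or $+\mathbf{x}$):

* **HA**: angle of $\mathbf{e}_1$ projected onto the epicardial tangent
  (L–C) plane, out of the short-axis plane; range [−90°, 90°), positive =
  right-handed (subendocardial-type) helix, so the healthy slope endo → epi
  is negative.
* **TA**: angle of $\mathbf{e}_1$ projected onto the short-axis (R–C)
  plane, from $\mathbf{C}$ toward $\mathbf{R}$; normally ≈0°.
* **E2A**: angle of $\mathbf{e}_2$, projected into the radial/cross-myocyte
  plane, against the cross-myocyte direction
  $\mathbf{x} = \mathbf{R} \times \mathbf{e}_{1,\mathrm{proj}}$; folded to
  [0°, 90°] absolute by default (signed variant behind a flag).

Degenerate projections ($\mathbf{e}_1 \parallel \mathbf{R}$, or
$\mathbf{e}_2$ projecting to zero) return `NA` with a flag. Voxels whose
λ₂ and λ₃ agree within 2 % are flagged *low confidence* for E2A — the
sheetlet plane is then numerically unstable — and no eigenvector-swapping
heuristic is attempted, because silent swaps corrupt summary statistics in
ways that are hard to audit.

## Quantification choices

**Transmural profile.** ROI voxels are binned by depth (10 bins by
default, ≥5 populated required). Helix angles are averaged *axially* — on
the doubled angle, period 180° — so values just below +90° and just above
−90° are treated as near neighbors; the endo → epi bin sequence is then
unwrapped to remove residual 180° jumps.

**HAT and HA range.** HAT is the OLS slope of bin-mean HA versus depth, in
°/% and (×100 / mean wall thickness) in °/mm. The reported HA range is the
endo-to-epi extent of the fitted line evaluated at 0 % and 100 % depth.
This was a genuinely open choice: the max-minus-min of raw bin means
systematically understates the surface-to-surface range by half a bin width
at each end (90° instead of 100° at 10 bins on the ±50° phantom), whereas
the fitted-endpoint definition matches the "≈+50° to ≈−50°" reading of the
consensus normal range. Both values are reported (`ha_range`,
`ha_range_bins`).

**E2A mobility** is the median absolute systolic E2A minus the median
absolute diastolic E2A over the same ROI definition. Medians are used
because absolute-angle distributions are skewed near the 0°/90° folds; the
summary statistic is configurable. Negative mobility is reported as-is with
a reduced-mobility flag.

**Septal ROI.** The ROI spans the arc (<180°) between the two RV-insertion
landmarks about the LV centroid, over the full wall thickness — full-wall
is the default and narrower ROIs need an explicit override. Trabeculation
regions are excluded. ROIs below 50 voxels are refused (small-ROI sampling
error); a 6-segment equal-angle partition referenced to the anterior
insertion is provided, with the full 16-segment model out of scope for a
single-slice tool.

**Normal-range QC.** Each summarized metric is checked against the
reference entry for its sequence kind and cardiac phase; STEAM and MCSE
are never compared against each other's rows. Published typical ranges are
used where available, mean ± 2 SD otherwise, and the rule that fired is
recorded — the two are not equivalent and the reference literature is
heterogeneous. Any MD above 3×10⁻³ mm²·s⁻¹ (free water at body
temperature) is hard-flagged unconditionally.

## Data curation and registration

**Corrupted-frame rejection** scores each frame's masked mean signal
against the median of its b-shell in robust (MAD) units; frames below
−3 robust SDs or below 0.7× the shell median are rejected. A
median/MAD rule was chosen over model-residual methods because no single
curation approach is established as superior and the rule is deterministic
and explainable frame by frame. Shells with fewer than three frames cannot
form a robust reference and are never rejected from. A hard floor stops
rejection that would leave fewer than six non-collinear directions plus a
reference frame — how many frames can safely be removed is an open question
in the field, and the floor is deliberately conservative.

**Registration** is translation-only normalized cross-correlation within a
±10-pixel window (integer search, parabolic subpixel refinement), which
matches the dominant motion of breath-hold single-slice short-axis data; a
rotation option is out of scope. An optimum on the window boundary is
flagged and *not* applied rather than silently clipped. A no-op denoising
hook marks where PCA/learning-based denoisers would slot in; they are
deliberately excluded.

## Numerical behaviour under noise

Two competing noise effects act on tensor summaries, and they pull FA in
opposite directions:

* **Eigenvalue-sorting (repulsion) bias**: with few repetitions, noise in
  the tensor components spreads the *sorted* eigenvalues apart and inflates
  FA. At SNR 5 with a single average this dominates (FA biased high by
  ≈+0.28 on the default phantom).
* **Rician floor bias**: the magnitude floor compresses attenuation, so
  apparent diffusivities — and through them MD and FA — are biased *low*.
  Unlike sorting variance, this mean shift does not average away.

The documented underestimation of MD and FA near the noise floor is
therefore tested where it is observable: SNR 5 and b = 450 with a heavily
averaged protocol (32 averages) and the signal-magnitude-weighted fit,
over 10 seeds. At low averaging the sorting bias masks it; both regimes
are real, and users comparing low-SNR studies should be aware of which one
their protocol sits in.

Other numerical conventions: negative eigenvalues are flagged, never
clamped; non-positive signals (possible under heavy noise) are clamped to a
tiny positive floor for the log transform with the count recorded per
voxel; isotropic tensors return mode 0 with a flag; the weighted fit uses
weights ∝ signal², the first-order noise propagation of the log transform.

## Problem sizes

The default phantom (48×48, 596 myocardial voxels, 13 frames) runs the
full pipeline in well under a second; the noise-bias studies (10 seeds ×
416 frames) and the whole test suite complete in under a minute. These
sizes were chosen as the smallest that leave every stage statistically
meaningful (≥5 populated transmural bins, ≥50-voxel ROIs).

## Known limitations

* Single-slice 2-D: the longitudinal direction is assumed normal to the
  slice; no 3-D tractography or propagation metrics.
* No strain correction of STEAM tensors; no IVIM/perfusion compartment; no
  EPI distortion correction; non-rigid registration out of scope.
* The positive-circumferential convention (and hence the HA sign) is fixed
  by the package's right-handed frame; validate the sign against a known
  dataset before comparing HA values across tools.
* The phantom prescribes a single sheetlet family per voxel; interpenetrating
  families are not simulated.

## A worked example

```{r example, eval = FALSE}
ph <- build_phantom()                       # consensus-normal systolic phantom
res <- run_pipeline(ph$stack, ph$contours)  # reject / fit / maps / summary
res$summary
res$qc_flags
```
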