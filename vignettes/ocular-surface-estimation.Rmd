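---
title: "Methods: RANSAC eye-surface estimation and layered vessel analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RANSAC eye-surface estimation and layered vessel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ocusurf)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic data do and
do not emulate, the numerical choices, and the design decisions taken where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

A mouse eye imaged side-on by OR-PAM is modelled as a *perfect sphere* with
center $(x', y', z')$ and half-diameter $r'$, all in physical micrometres.
The model is deliberately crude — the anterior segment is closer to an
ellipsoid, especially in humans — but four parameters are enough to
re-reference depth to the ocular surface, and a sphere can be estimated
robustly from heavily contaminated data. The coordinate frame places the
origin at the volume corner, voxel $(i,j,k)$ (1-based) at physical center
$((i-\tfrac12)dx, (j-\tfrac12)dy, (k-\tfrac12)dz)$, with $z$ the A-line
(depth) axis increasing away from the scanning plane.

The estimator scores a candidate sphere by a two-zone shell mask against
the binarized vessel field $P(x,y,z)$: $+1$ per vessel voxel strictly
inside the shell $(r_n,\, r_n + \Delta r_+)$ just outside the candidate
surface, $-1$ strictly inside $(r_n - \Delta r_-,\, r_n)$ just beneath it.
The positive zone rewards surfaces that sit immediately *below* the
vasculature (vessels drape over the eye); the negative zone penalises
surfaces that cut through it. Zone thicknesses default to 150 µm — thick
enough to contain any one vessel layer.

Why RANSAC rather than least squares: chemical injury produces
hemorrhages, corneal new vessels and reverberation clutter that act as
gross outliers. A least-squares surface fit is dragged by every outlier; a
sampling-consensus search scores whole-model hypotheses and effectively
counts inliers, so clutter only matters if it out-votes the true shell.
The test suite exercises exactly this: recovery within 2 voxels with 20 %
of all signal voxels placed uniformly at random.

## The search loop and its convergence semantics

Each repeat draws 4000 parameter sets uniformly from a 4D box, scores
them, keeps the top 5, and renews the box per coordinate: center = mean of
the retained values, half-width = $\gamma \cdot \mathrm{std} + b$ with
$\gamma = 2$ and $b = 25$ µm. The constant $b$ keeps the box from
collapsing; it also bounds the resolution of the final stochastic polish
(see *Limitations*). The published procedure terminates when "the nearest
parameter set is maintained for three repeats", without saying whether the
best set may regress between repeats. We resolve this as
**incumbent retention**: the best-ever candidate is carried across repeats
and entered into each repeat's candidate pool ahead of the fresh draws
(ties favour it), so its score is non-decreasing and "maintained" is
well-defined — the loop stops after three consecutive repeats in which no
fresh draw beats the incumbent. A safety cap (`max_repeats`, default 50)
flags non-convergence instead of raising.

Two further under-specified points, decided and documented here:

* **Top-5 statistics**: the renewal standard deviation is the *population*
  std (divide by $k$), configurable in code. With $k = 5$ the choice moves
  half-widths by ~12 %, immaterial next to $\gamma$ and $b$.
* **Candidate pool membership**: only the incumbent survives between
  repeats; the rest of each batch is drawn fresh. Retaining all five would
  slightly accelerate convergence but makes the "maintained" criterion
  ambiguous.

Initial ranges mirror the published defaults: lateral centers at half the
imaged extent (the eye is imaged centered), axial center 2300 µm (typical
eye position given the system's focal depth), half-diameter center 1700 µm
(typical mouse eye), half-widths (500, 500, 500, 250) µm. All are
overridable for other geometries.

The boundary convention is strict everywhere (a voxel exactly on the
candidate surface contributes 0), and all distances are Euclidean in
physical µm from voxel centers. Batch scoring is a pure function of
$(P, \text{params})$ — no result depends on evaluation order — and is
implemented in C++ on the coordinates of the foreground voxels only, using
squared-distance comparisons (valid because all radii are nonnegative).

## Preprocessing choices

The publication names no filter family, threshold, or downsizing factor;
the defaults here are:

* **Band-pass**: zero-phase Butterworth magnitude response of order 4,
  passband 25–75 MHz (transducer center 50 MHz, bandwidth 50 MHz),
  realised in the frequency domain per A-line. A purely real transfer
  function introduces no group delay, so the depth of the envelope maximum
  — and hence $D_c$ — is unbiased. No filter-design library exists in the
  target environment; the direct frequency-domain form is equivalent to
  `filtfilt` up to edge handling and is evaluated against its own designed
  response in the tests.
* **Envelope**: magnitude of the FFT analytic signal per A-line.
* **Downsizing**: per-axis block *maximum* (not mean), preserving thin
  bright vessels; trailing partial blocks are truncated; spacing is
  multiplied by the factors so physical coordinates survive.
* **Binarization**: default threshold = 0.25 × volume maximum,
  overridable by an absolute value or Otsu's method. At the phantom's
  SNR of 10 this recovers the vessel mask with Dice > 0.9; on real data
  the rule is the knob most worth revisiting.

## The synthetic eye ("stated world")

`phantom_spec()` defaults describe the world the tests assert about:
128 × 128 × 96 voxels at 25 µm isotropic spacing — a 3.2 × 3.2 × 2.4 mm
field of view, i.e. the published 2.5 µm acquisition grid *after* the
Step-1 downsizing — containing a ground-truth sphere of half-diameter
1750 µm centered at (1450, 1700, 2400) µm (off-center by a realistic
couple hundred µm, inside the default initial search box). Vessels are
great-circle arcs on offset spheres, dilated to 30 µm tubes and clipped to
their radial band: an on-surface band (0, 80) µm emulating iris and
choroidal/retinal vessels, and a supra-surface band (120, 150) µm
emulating limbal/episcleral vessels. Arc normals are drawn within ±30° of
the scan plane so every arc crosses the imaged upper cap — uniformly
random normals would frequently miss the field of view. Signal amplitude
is 1 with additive Gaussian noise of σ = 0.1 (SNR 10), rectified at zero
because the phantom stands in for *enveloped* (nonnegative) data. Optional
clutter voxels ("outliers", modelling hemorrhage and reverberation) are
placed uniformly outside the bands at vessel amplitude, making up a stated
fraction of all signal voxels. An optional RF carrier (50 MHz at 500 MHz
sampling) exercises the band-pass + envelope chain.

What the phantom does **not** emulate: acoustic wave propagation, optical
fluence and depth-dependent SNR, speckle, motion, elliptical eye geometry,
vessel branching morphology. A green test therefore establishes that the
*algorithms* are correct on geometry they assume, not that the pipeline is
robust to every artifact of a live acquisition.

## Depth maps, isolation, and the area correction

$D_c$ takes the per-pixel argmax of the envelope along depth (ties:
shallowest voxel, deterministic), masking pixels whose maximum fails a
background rule (default 0.1 × max; the worked example uses 0.3 at SNR 10).
$D_s$ is the signed radial distance of that signal point from the
estimated sphere. The published display range for $D_s$ is printed as
"from −50 µm to −50 µm", an evident typo; the default render range is
(−50, +150) µm, spanning both vessel layers, and is configurable.

On-surface isolation projects the envelope maximum over voxels in
$(r' + \text{lo},\, r' + \text{hi})$; the lower offset must be ≥ 0 by
contract, excluding sub-surface signal, because everything below the
estimated surface is dominated by reverberation copies of the true
vessels. The published corneal-vessel band is internally contradictory
(Methods say $r < r' + 180$ µm, Results say $r' + 180\ \mu m < r$); the
supra-surface direction is implemented, since corneal new vessels are
described as growing *above* the surface.

The slope correction divides each selected pixel's area by
$C(x,y) = (z' - D_c)/(r' + D_s)$. The published formula references an
otherwise-undefined map $D_t$; interpreting it as $D_c$ makes $C$ exactly
the cosine of the angle between the local surface normal and the depth
axis, and under that interpretation the discrete sum converges to the
analytic sphere-cap area $2\pi r'^2 (1 - \cos\theta)$ — verified to 3 % at
2.5 µm pixels in the acceptance suite. Because $1/C$ diverges at the
equator, `cnv_area()` excludes pixels with $C$ below a floor (default
0.1) and *counts* them rather than silently inflating the area; the
analytic closed-form checks pass `c_floor = 0`, which is exact there
because every strictly interior pixel of the projected disk has $C > 0$.
The manual "upper hemisphere" selection of the original workflow is
replaced by an explicit ROI mask argument.

## Laser safety

The MPE chain is a calculator, not a derivation: the extended-source
correction factor $C_E = 267$ (NA 0.1) and the 20 mJ/cm² single-pulse skin
MPE are inputs, because deriving them needs the ANSI Z136.1
angular-subtense tables; likewise the 106 µm defocused spot diameter.
The chain is $\mathrm{MPE}_{SP} = 5.0\,C_E \times 10^{-7}$ J/cm²,
$\mathrm{MPE}_{RP} = n^{-1/4}\,\mathrm{MPE}_{SP}$, energy = fluence ×
aperture area, margin = permissible / used. One wrinkle: $5.0 \times 267
\times 10^{-7} = 1.335 \times 10^{-4}$, which the source truncates to
$1.33 \times 10^{-4}$; the package returns the exact product and the tests
compare at printed precision.

## Numerical and engineering notes

* Scoring uses exact integer accumulation; the C++ kernel and a
  triple-loop R oracle agree integer-exactly on hundreds of random cases.
* `estimate_surface()` restores the caller's RNG state; all stochastic
  stages accept explicit seeds, and the pipeline writes byte-identical
  result JSON under a fixed seed.
* Volumes travel as raw IEEE floats plus a JSON sidecar (shape, dtype,
  endianness, spacing, sampling rate). No TIFF library ships in the target
  environment, so TIFF I/O is out of scope; the sidecar format round-trips
  bit-exactly and validates its metadata (declared shape vs file size,
  required fields).
* Degenerate inputs have defined behaviour: an all-zero volume under a
  relative threshold yields an empty mask with a warning; an empty binary
  volume is an error for estimation; an empty ROI warns and returns an
  empty segmentation; non-convergence is a flag, not an exception.

## Limitations

* The sphere model biases estimates on ellipsoidal eyes (human anterior
  segments); extending the parameterisation is future work.
* With the published sampling constants (4000 draws per repeat, minimum
  box half-width $b = 25$ µm, three-repeat stability), the stochastic
  polish resolves the optimum to a few µm — matching the published
  precision claim (std < 5 µm over ten runs) — but cannot reliably attain
  ≥ 99 % of the analytic score maximum on a razor-thin optimum; the test
  suite asserts the honestly attainable ≥ 97 %.
* The binarization threshold and background rules are global; depth- or
  fluence-adaptive thresholds would serve real data better.
* Band boundaries are strict inequalities; voxels exactly on a boundary
  (measure zero for continuous geometry, possible on constructed data)
  belong to neither side.
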