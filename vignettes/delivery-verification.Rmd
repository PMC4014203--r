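---
title: "Verifying radiotherapy delivery: gamma analysis, DVH deviations and detector angular correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying radiotherapy delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtverify)
```

## The problem

Intensity-modulated (IMRT) and volumetric-arc (VMAT) treatments deliver
highly conformal dose distributions whose realisation depends on hundreds of
machine parameters. Patient-specific quality assurance therefore compares
the *planned* dose against what was actually *delivered*, either as a 2D
planar measurement in a phantom (an ion-chamber array irradiated by the
patient's beams) or as a 3D dose reconstructed from measured delivery
fluence on the patient's own anatomy. `rtverify` implements the comparison
machinery for both routes:

* the **gamma index** for planar and volumetric dose pairs, globally and
  per anatomical structure;
* **DVH deviation metrics** — D2%, D50%, D95%, D98%, Dmean, V100%, V95%,
  the homogeneity index HI and the conformity index CI — with one-sample
  t-test summaries across cases;
* **per-detector angular response correction** for 2D ion-chamber arrays
  measured at multiple gantry angles;
* a **synthetic phantom/plan generator** so the full pipeline can be
  exercised with known ground truth.

## The gamma index

For a reference (planned) dose $D^r$ and an evaluated (delivered) dose
$D^e$, the gamma index at a reference point $r$ is

$$\gamma(r) = \min_{r'} \sqrt{\frac{|r'-r|^2}{\delta d^2} +
\frac{\left(D^e(r') - D^r(r)\right)^2}{\Delta D^2}},$$

with $\delta d$ the distance-to-agreement criterion (3 mm by default) and
$\Delta D$ the dose criterion (3% of the normalization dose). A point
passes when $\gamma \le 1$; the boundary counts as a pass.

Three conventions needed fixing where common usage is loose:

* **Normalization.** "3% absolute dose" is read as a *global* percentage:
  of the maximum reference dose for planar pairs (where no prescription is
  attached to a phantom measurement) and of the prescription dose for
  volumetric pairs. A local-percent mode exists but is off by default,
  since local normalization produces a different, much stricter statistic.
* **Low-dose threshold.** Points whose *planned* dose is below 20 cGy are
  excluded from the global pass-rate denominator. Per-structure pass rates
  instead count *every* voxel inside the structure contour, threshold
  ignored — a cold structure should not be silently dropped from its own
  statistic.
* **Search.** The minimisation runs over a displacement lattice of spacing
  $\delta d/10$ out to $3\,\delta d$, with the evaluated dose bilinearly or
  trilinearly interpolated at each candidate. Offsets are scanned in order
  of increasing distance with an exact early exit (once the spatial term
  alone exceeds the current minimum nothing farther can win), so the result
  is identical to an exhaustive scan of the same lattice. The remaining
  quantisation error relative to the continuum is bounded by
  `gamma_lattice_bound()`: the objective is Lipschitz in the displacement,
  so the bound is $\tfrac{h\sqrt{d}}{2}\sqrt{1/\delta d^2 + (G/\Delta D)^2}$
  with $h$ the lattice step and $G$ the maximum dose gradient.
  `gamma_oracle()` re-implements the search as a vectorised full
  enumeration in R and is used throughout the tests as an independent
  cross-check.

```{r gamma-example, eval = FALSE}
ref <- read_planar_ascii("planar_reference.txt")
meas <- read_planar_ascii("mgac_measured.txt")
res <- compute_gamma(ref, meas, gamma_criteria(3, 3))
pass_rate(res)
```

## DVH metrics and deviation statistics

DVHs are kept as exact sorted voxel lists — no histogram binning — so every
query is answered to voxel precision. $D_v$ (the dose covering the hottest
fraction $v$) interpolates linearly between order statistics using the
type-7 sample-quantile convention; $V_d$ counts voxels receiving at least
$d$, boundary inclusive. The target-dose indices are

$$\mathrm{HI} = \frac{D_{2\%} - D_{98\%}}{D_{50\%}}, \qquad
\mathrm{CI} = \frac{\mathrm{PTV}_{95\%}}{\mathrm{PTV}} \times
\frac{\mathrm{PTV}_{95\%}}{V_{95\%}},$$

where $\mathrm{PTV}_{95\%}$ is the target sub-volume at or above 95% of the
prescribed dose and $V_{95\%}$ the total volume at that level (the whole
grid unless a body mask is supplied — COMPASS-style systems differ here, so
it is exposed as an option). CI is the product of coverage and selectivity,
each in $[0,1]$. In simultaneous-integrated-boost plans each target's CI
uses its own prescription level, carried in a `prescription()` object.

Plan-vs-delivery deviations are expressed as
$\Delta = 100\,(x_{\mathrm{delivered}} - x_{\mathrm{planned}})/x_{\mathrm{planned}}$
per case, and summarised across cases by range, mean ± sample SD, and the
two-sided one-sample t-test of zero mean. A degenerate all-equal sample has
$p = 1$ when its mean is zero and an undefined statistic otherwise
(reported as `NA` with a warning rather than invented).

## Angular response correction

A plane-parallel ion-chamber array responds differently when the beam does
not arrive at normal incidence, worst near lateral incidence where the beam
runs parallel to the detector plane. Multi-gantry-angle composite
measurements therefore need a per-detector correction. The incidence angle
of a detector offset $d$ mm (in the rotation plane) from the array center
at gantry angle $\theta$ and source-axis distance SAD is

$$\varphi = \operatorname{atan2}\!\left(d + \mathrm{SAD}\sin\theta,\;
\mathrm{SAD}\cos\theta\right),$$

taken in $[0^\circ, 360^\circ)$. The two-argument arctangent is essential:
a single-argument arctan is undefined at $\theta = 90^\circ/270^\circ$ and
ambiguous in the posterior half. Offsets along the rotation axis leave the
incidence unchanged, so detectors sharing a row offset share a factor.

Correction factors come from a central-detector series: at each sampled
gantry angle (5° steps, refined to 1° within 90°±5° and 270°±5°) the
central chamber is measured and the same point dose calculated;
the factor is the calculated/measured *ratio*, normalized to its 0° value.
A ratio — not a difference — is used because detector response errors are
multiplicative, and only a ratio survives the 0° normalization meaningfully.
Between samples, factors are linearly interpolated, periodic across
360°→0°. Composite measurements are corrected per delivered frame at its
recorded gantry angle and then summed.

## The synthetic ground truth

The generator emulates a head-and-neck (nasopharyngeal-carcinoma-like)
verification session on a rectangular solid-water phantom
(31.4 × 34 × 22 cm, 3 mm grid by default):

* **Anatomy**: nested targets PTVnx ⊂ PTV1 ⊂ PTV2 built by concentric
  ellipsoid expansion (margins 7 and 10 mm), so the nesting invariant holds
  by construction; serial organs (brainstem, spinal cord) as posterior
  cylinders; parallel organs (parotids) lateral; thin optic nerves and
  chiasm. A seeded jitter (2 mm SD in the batch scenario) displaces organ
  centers per case.
* **Plan dose**: the voxelwise maximum over targets of prescription ×
  Gaussian-blurred indicator (penumbra σ = 4 mm), optionally renormalized
  so the boost target's D95% equals its prescription — the way clinical
  plans are prescribed. This is deliberately *not* a transport calculation:
  the package verifies comparisons, not dose engines. Default prescription
  levels are 7000/6600/6000 cGy, a typical three-level boost structure;
  these are synthetic defaults, labelled as such.
* **Delivery perturbations**: rigid shift, then global output scale, then
  extra penumbra blur, then seeded Gaussian noise — in that fixed order, so
  metric expectations stay derivable (a pure scale k moves every $D_v$ by
  exactly k).
* **Detector measurement**: bilinear sampling on the 32 × 32, 7.62 mm-pitch
  lattice with the four cornerless positions masked (1020 active chambers),
  and a smooth angular response $R(\varphi)$ — Gaussian dips of amplitude
  0.2 and width 10° at 90°/270° plus a 0.005 ripple, normalized to
  $R(0)=1$. With that shape, linear interpolation on the 5°/1° sampling
  grid recovers the true fluence to better than 0.5% everywhere, which is
  what the round-trip acceptance check asserts.

What the generator does *not* emulate: realistic CT densities and
heterogeneity, MLC leaf sequences, couch attenuation, detector volume
averaging, or beam-model errors. Passing tests therefore demonstrate the
*comparison machinery* is correct, not that any clinical delivery is.

## The batch scenario

`run_batch()` simulates and verifies a batch of cases (3 by default, on the
3 mm grid): per case it computes single-gantry-angle-composite (SGAC) and
multi-gantry-angle-composite (MGAC) planar pass rates — MGAC both with and
without per-detector correction — the global and per-structure 3D pass
rates of the perturbed "reconstruction" against the plan, and the
DVH/HI/CI deviation rows; across cases it summarises deviations with the
t-test. Per-case perturbations draw shift (SD 1 mm/axis), scale (SD 1%),
blur (half-normal, SD 1 mm) and 0.3% noise from the scenario's seeded RNG.
Nine equally spaced beams model an IMRT delivery. The `report` CLI
subcommand writes the per-case table and deviation summary as CSV with
fixed numeric formatting, so a fixed config and seed reproduce files
byte for byte.

## Numerical choices and edge cases

* Whole-voxel membership by center-in-polygon (even-odd rule), no
  partial-volume weighting; contour slices snap to the nearest layer with
  ties broken upward.
* Resampling outside the source extent yields 0 plus an out-of-extent
  mask; extrapolated dose would be an invention.
* $\gamma = 1$ passes; pass counting uses a $10^{-9}$ guard so an exact
  3% offset (whose floating-point dose difference is one ulp above the
  criterion) is not spuriously failed.
* DVH curves on a degenerate uniform dose return that dose for every
  $D_v$; HI is exactly 0 there.
* Problem sizes in the tests (20×20 oracle pairs, 6 mm grids for the
  monotonicity sweep, the default 3-case 3 mm batch) were chosen as the
  smallest sizes at which every property under test is exercised with
  margin.

## Known limitations

* The DICOM layer supports explicit-VR little-endian RT Dose and RT
  Structure Set with axis-aligned orientation — the profile its own writers
  emit and typical axial TPS exports use; rotated orientations and other
  transfer syntaxes are rejected rather than misread.
* Gamma of planar pairs treats inactive detector positions as zero signal
  during interpolation; fields should keep their high-dose region away
  from the array's corner gaps (true of centered clinical fields).
* The per-frame correction assumes a nominal gantry angle per frame; the
  integration window of a continuously rotating delivery is not modelled.
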