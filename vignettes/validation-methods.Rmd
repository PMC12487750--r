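---
title: "Phantom-based PET scanner validation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based PET scanner validation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petvalid)
```

## What is being validated

A PET scanner used in a quantitative clinical trial must satisfy two
independent requirements. First, *calibration*: a uniform object of known
activity concentration must read correctly in Bq/mL, the native unit of
reconstructed PET. Second, *recovery harmonization*: objects of finite size
are reported at reduced contrast because of the scanner's limited spatial
resolution, and different scanners must be constrained (through their
reconstruction settings) to a common band of this size-dependent behaviour
so that their quantitative outputs are comparable.

Both requirements are tested with phantoms whose ground truth is known from
radionuclide-calibrator assays and volume measurements, never from the
scanner itself. Everything in this package is therefore anchored in the
fill-accounting chain: assay activities, decay corrected exactly as
`A(t) = A_0 \cdot 2^{-\Delta t / t_{1/2}}`, divided by measured aqueous
volumes.

## The measured quantities

With `A` denoting fill-derived (true) and `C` image-derived (measured)
concentrations:

* calibration bias `= C_bkg / A_bkg`, unity for a perfect scanner;
* `CRC_i = [(C_sphere(i) - C_bkg)/C_bkg] / [(A_sphere - A_bkg)/A_bkg]`;
* `RC_i = C_sphere(i) / A_sphere`;
* `CRC_i = (RC_i \cdot contrast / bias - 1) / (contrast - 1)`, an exact
  algebraic identity linking the two, given the achieved contrast
  `A_sphere / A_bkg` and the measured bias.

Two properties of these definitions are load-bearing and are enforced as
tests: CRC is invariant to calibration bias (the bias multiplies `C_sphere`
and `C_bkg` jointly and cancels), whereas RC scales linearly with it. The
contrast entering the identity is always the fill-derived true contrast;
the nominal 8:1 target is only a planning and QC value.

## The simulator

The simulator provides synthetic acquisitions with exact ground truth.

* **Painting.** Phantom compartments (background body, sphere interiors,
  cold inserts, exterior) are rasterized by subvoxel sampling (default
  4 per axis). Sphere subcells use an antialiased coverage term (planar
  approximation of the surface within a subcell) so the painted sphere
  activity matches the analytic volume `(\pi/6) d^3` to well under 0.5%.
* **Resolution.** The partial-volume effect is modelled as a post-hoc
  isotropic Gaussian convolution with `\sigma = FWHM / 2.3548` (default
  FWHM 5 mm, representative of harmonized whole-body reconstructions).
  There is no sinogram, scatter, randoms, attenuation or dead-time
  modelling: the analysis metrics are defined on reconstructed images, for
  which a Gaussian kernel is the standard desk-scale surrogate.
* **Calibration bias** is injected as a multiplicative factor after the
  blur, exactly as a miscalibrated scanner would scale its output.
* **Noise** is Gaussian with variance proportional to the local mean:
  per-voxel `sd = \sigma_0 \sqrt{\max(v,0)/v_{ref}}`. Reconstructed-image
  noise is approximately Gaussian, and this choice keeps the noise-free
  image an exact expectation, which the law-of-large-numbers test uses.
  The reference concentration `v_{ref}` defaults to 5000 Bq/mL (mid-range
  of the recommended 3–7 kBq/mL calibration fill), so "5% noise at the
  background level" is expressed as `\sigma_0 = 0.05 \cdot v_{bkg}` with
  `v_{ref} = v_{bkg}`.
* **Determinism.** One seeded generator per simulated scan; identical
  configurations give bit-identical volumes, and the RNG state of the
  session is restored afterwards.
* **Default grid** is 2.0-mm isotropic, inside the recommended 1.5–2.75-mm
  transaxial reconstruction range.

The generator's defaults are the recommended study conditions: the
quarterly calibration fixture is the 20-cm uniform cylinder at 5 kBq/mL
(mid-range of 3–7), and the annual recovery fixture is the torso
image-quality phantom at 2 kBq/mL background and 8:1 contrast, both with
F-18 and unit injected bias.

What the simulator deliberately does not reproduce: count-rate effects,
scatter/attenuation residuals, reconstruction nonlinearity and
point-response-function (Gibbs) overshoot. The last one matters for
interpretation: a Gaussian model can never produce CRC above 1, while the
harmonized maximum-voxel limits place the lower bound slightly *above* 1
for large spheres precisely because modern reconstructions overshoot.
Passing simulator-based tests therefore demonstrates correctness of the
measurement chain, not that a Gaussian-like scanner would pass
harmonization; boundary behaviour of the criteria engine is exercised with
synthetic curves instead.

## The analytic recovery oracle

For an isolated sphere, the noise-free mean CRC equals the mean over the
sphere of its own indicator convolved with the PSF. `analytic_sphere_mean_rc()`
evaluates this from the closed-form radial profile of a ball convolved with
an isotropic Gaussian, integrated by 0.05-mm radial quadrature. Useful
limits: it tends to 1 as the blur vanishes and to 0 as the sphere shrinks,
and for `R \gg \sigma` the deficit is approximately
`(3/R)\,\sigma/\sqrt{2\pi}` — a surface-layer term. This explains a
behaviour worth knowing: even a 37-mm sphere imaged at 1-mm FWHM reads
about 2.7% low in the *mean* metric (the maximum-voxel metric, by
contrast, does reach 1 there). Convergence of the mean metric to unity in
`diameter/FWHM` is slow, not exponential.

A reconstructed voxel additionally box-averages the continuous field over
its own width, which acts as an extra aperture. `effective_psf_fwhm()`
provides the variance-matched Gaussian equivalent
(`2.3548\sqrt{\sigma^2 + h^2/12}`) for comparing measurements on an
`h`-spaced grid with the continuous oracle; at 2-mm voxels and 5-mm FWHM
the difference is about 1–3% for the smallest spheres and under 1% for the
largest.

## Analysis design choices

* **Calibration ROIs**: per-slice circular ROIs of diameter 2 cm less than
  the phantom diameter, membership by voxel-center inclusion. Slices whose
  centers lie within 10 mm of either phantom end are excluded — the radial
  margin is prescribed, the axial analogue is a package choice (the blur
  reaches `\approx 3\sigma \approx 6.4` mm past the ends at 5-mm FWHM, so
  10 mm keeps end partial-volume out of the estimate); both are
  configurable.
* **Background VOI set** for torso phantoms: twelve 30-mm circular ROIs at
  the sphere-plane axial position on a 95-mm ring, at angles interleaved
  with the sphere positions. The radius/angle choice keeps at least
  ~4 standard deviations of clearance from every sphere wall and from the
  phantom wall at the default PSF; with it, the measured bias on a
  noise-free unbiased simulation is 1.0000 to within a few parts in 10^5.
  The layout is a documented default, not a standard, and any ROI table
  can be supplied instead.
* **Sphere location**: iterated intensity-weighted centroid of
  background-subtracted voxels in a search ball of radius equal to the
  sphere diameter, converging to < 0.01 mm or 20 iterations. CT-based VOI
  placement is not offered: PET–CT coregistration errors of a couple of
  millimetres are common and would corrupt mean measurements.
* **VOI statistics**: the mean uses the exact inner diameter
  (voxel-center membership); the maximum is the largest voxel in that VOI
  with ties resolved in array scan order for determinism; the peak is the
  highest 1-cm^3 spherical average (diameter `(6000/\pi)^{1/3} \approx
  12.407` mm) over centers on a half-voxel lattice constrained to the VOI.
  For 13-mm spheres and smaller the peak VOI necessarily includes
  background, so the `max ≥ peak ≥ mean` ordering is only guaranteed for
  larger spheres.
* **Measurement supersampling** (trilinear refinement before the mean) is
  available and reported in the output, but defaults to off: on synthetic
  data, interpolation acts as additional smoothing and systematically
  lowers small-sphere means by several percent, whereas plain voxel-center
  sampling tracks the aperture-corrected analytic prediction within 2%.
* **Degenerate inputs**: spheres smaller than the voxel raise an error
  that suggests supersampling; empty slice ranges, off-grid ROIs and
  radionuclide mismatches are hard errors; sphere-detection failures mark
  the affected sphere and return the remaining curve with flags.

## The criteria engine

Criteria tables are data, not code: the shipped JSON carries the tiered
calibration tolerances (tier 1: 5% for F-18/Ga-68, 10% otherwise; tier 2:
10% for all), the per-sphere maximum-voxel CRC limits at contrast 8, the
validity frequencies, and the revalidation trigger kinds. Extending the
table (for instance down to smaller spheres) requires no code change.

All bounds are applied inclusively at the printed value; the printed
sources are not perfectly consistent on strictness, inclusive is the
conventional reading, and a strict mode is available in the configuration.
Deviations are rounded to 12 significant digits before comparison so that
binary floating point cannot flip a decision exactly at a boundary
(`1.05 - 1` exceeds `0.05` by `4 \times 10^{-17}`).

Validity windows begin on the scan date: quarterly is implemented as +3
calendar months (configurable; "90 days" is the other defensible reading),
annual as +1 year. Trigger events (software update, major service,
Ge-68 source replacement, calibrator service) truncate the window to the
earliest in-window event. Decisions are pure functions of their inputs and
serialize deterministically; the mandated human review of the phantom
images is represented as a sign-off field on the decision record, pending
by default — it is never automated.

The 7-mm sphere of the anthropomorphic chest phantom is measured and
reported but never judged; it has no harmonized limits and serves
characterization only.

## Problem sizes and runtime

Simulated volumes are about 120–170 voxels per axis at 2-mm spacing
(roughly 2.5 million voxels); rasterization at supersampling 4, blurring,
and a full recovery analysis each run in a few seconds on one core. The
test suite's independent cross-checks use a 0.5-mm brute-force convolution
oracle (0.25-mm for the frozen reference values) and 50-replicate noise
averaging on a reduced grid.

## Known limitations

* NIfTI with a JSON sidecar is the only supported volume format; DICOM
  series are not read.
* The Gaussian simulator cannot produce CRC > 1 (no Gibbs/PRF overshoot)
  and models no count-rate, scatter or attenuation effects; conclusions
  about real scanners' harmonization status cannot be drawn from simulated
  scans.
* SUV is out of scope throughout; all values are Bq/mL.
* Noise metrics, radial uniformity and lesion-detectability statistics are
  not computed; axial uniformity is reported for inspection but carries no
  acceptance criterion.
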