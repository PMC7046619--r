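---
title: "Cherenkov-emission imaging QA for HDR brachytherapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cherenkov-emission imaging QA for HDR brachytherapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherenkovqa)
```

## The QA problem

High-dose-rate (HDR) brachytherapy steps a miniature Ir-192 source through
implanted catheters under remote control; errors of a millimetre in dwell
position or a few percent in source strength translate directly into dose
errors in the patient. Routine quality assurance must therefore verify dose
distribution, source strength and source position — conventionally with three
different tools (film, well chamber, ruler). Imaging the faint Cherenkov
light that the source's gamma rays generate in a water tank offers all three
measurements from a single camera image: the light distribution tracks the
dose distribution, its amplitude tracks source strength, and the profile peak
localizes the dwell.

This package implements that measurement chain end to end on synthetic data:
a TG-43 dose engine, a closed-form Cherenkov emission model, a camera forward
model that renders dwell sequences into 16-bit images, the image-analysis
chain, and the QA metrics.

## Dose model

The dose engine uses the 1D point-source TG-43 form

$$\dot D(r) = S_K \, \Lambda \, \left(\frac{r_0}{r}\right)^2 g(r)\, \phi_{an}(r), \qquad r_0 = 10~\mathrm{mm},$$

with air-kerma strength $S_K$ (U $=$ cGy cm$^2$ h$^{-1}$), dose-rate constant
$\Lambda$ (cGy h$^{-1}$ U$^{-1}$), radial dose function $g(r)$ and 1D
anisotropy factor $\phi_{an}(r)$. The point-source approximation (rather than
the 2D line-source geometry factor) is deliberate: every QA quantity the
package measures is evaluated at $r \geq 7$ mm from a 3.5-mm active core,
where the two forms differ by well under the 5% profile-agreement criterion,
and the point form keeps the projected-field renderer exactly cylindrically
symmetric, which the radial-lookup renderer exploits.

Bundled mHDR-v2 parameters (in `inst/extdata/mhdr_v2.yaml`, versioned as data
rather than code): $\Lambda = 1.109$, $g(r)$ as a fifth-order polynomial in
$r$ (cm) fitted to consensus-style values, renormalised at construction so
$g(1~\mathrm{cm}) = 1$ exactly and clamped to its 0.25–10 cm fitting range
so the high-order terms never extrapolate; $\phi_{an} = 0.98$, constant — a
typical 1-cm value for this source, configurable, including as a function of
$r$. Half-life: 73.83 days. The air-kerma rate constant is bundled as
$\Gamma = 110$ U/GBq, which reproduces the conventional 35,300 U
$\leftrightarrow$ 320 GBq correspondence for Ir-192.

With the bundled parameters, a 32,800-U source gives

```{r}
dose_rate_point(ir192_hdr_source(), r = 10)
```

Gy/min at the reference point, and the dwell time for the standard 6-Gy
reference delivery is `r round(dwell_time_for_dose(ir192_hdr_source(), 6), 1)` s.

## Cherenkov physics

A charged particle radiates Cherenkov light when $\beta n > 1$. The kinetic
threshold $T_{thr} = m_e c^2 (1/\sqrt{1 - n^{-2}} - 1)$ evaluates to 264.1 keV
for water ($n = 1.33$) and 146.3 keV for catheter plastic ($n = 1.59$); those
indices were chosen because they reproduce exactly the thresholds quoted for
the two materials in this QA context — the band-averaged visible index of
water is conventionally 1.33, and 1.59 matches polystyrene-like catheter
plastic.

The electrons come from Compton scattering of the Ir-192 gamma lines
(bundled: 206–885 keV with per-decay intensities; the intensity-weighted mean
of such tables ranges 355–380 keV depending on the compilation, and the
package does not force a particular mean). The per-line electron spectrum is
the Klein–Nishina cross-section differential in electron energy, zero above
the backscatter edge $T_{max} = 2E^2/(m_ec^2 + 2E)$. Notably
$T_{max}(355~\mathrm{keV}) = 206$ keV — below the water threshold — so water
light is generated exclusively by the lines above 423.5 keV, while the
catheter sees electrons from essentially the whole table. This asymmetry, not
any optical subtlety, is why the catheter glows disproportionately.

Photon yield per electron integrates the Frank–Tamm spectral density
$d^2N/dx\,d\lambda = (2\pi\alpha/\lambda^2)(1 - 1/(\beta^2 n^2))$ over a
400–700 nm band (a generic silicon-CCD-compatible choice; the response curve
of any particular camera is not modelled) and along the electron's slowing
path, using the Katz–Penfold CSDA range with a linear energy-versus-
residual-range profile. In the saturated limit this gives 21.35 photons/mm in
water. Electron ranges at these energies are sub-millimetre to ~2.5 mm —
below or near one 0.17-mm pixel after projection — so no lateral electron
transport is modelled.

`light_yield_per_dose()` combines lines, interaction weights (Klein–Nishina
total cross-section relative to Thomson; photoelectric and pair terms are
negligible for water in this range) and Frank–Tamm yields into a relative
per-medium brightness factor. The absolute optical scale (lens, mirror,
quantum efficiency) is folded into a single camera gain.

## The synthetic image generator

The generator is the package's study-conditions definition, not a tuning
knob. It renders a dwell sequence into the emission a camera sees:

- **Projection.** The camera integrates light generated in the ~100-mm water
  layer in front of the source. The renderer sums the TG-43 point dose over
  1-mm z-slices at half-integer offsets ($z = \pm 0.5, \ldots, \pm 49.5$ mm),
  which also keeps the integrand away from the source singularity. For a
  point field this projected emission depends only on in-plane radius, so it
  is evaluated once on a fine radial grid and interpolated onto the
  772 × 580, 0.17 mm/px sensor. Note the projected ("accumulated") value at
  the 10-mm reference point is ~27× the point dose under this convention;
  accumulated-to-point ratios depend on the slab and normalisation
  convention, so both thickness and slice spacing are configuration, and
  profile comparisons always use the same convention on both sides.
- **Catheter light.** An optional component confined to a |y| < 1 mm stripe,
  scaled by a coupling factor (default 2) relative to water light at the same
  position. The factor mixes emission physics with optical coupling of the
  catheter and is exposed as configuration rather than predicted.
- **Fidelity levels.** LEVEL A (default): light strictly proportional to
  dose — the regime the method relies on at $r \geq 7$ mm. LEVEL B adds a
  near-source excess (default 5% of total water light, Gaussian over the
  675-keV beta-endpoint CSDA range ≈ 2.5 mm) emulating capsule-escaped beta
  particles, so the near-source breakdown of dose-light proportionality can
  be exercised. The bundled capsule transmission (3 × 10⁻⁴ of decay
  electrons) and beta dose fraction (5 × 10⁻⁴ of gamma dose) are plumbing
  constants for this component.
- **Camera.** Counts = clip(round(Poisson(gain × emission × exposure) +
  offset + Gaussian read noise), 0, 65535). Default gain 5.37 counts per
  Gy·slice puts the 6-Gy single-dwell peak near 3 × 10⁴ counts, using most of
  the 16-bit range; offset 100, read noise 2 counts. An optional Gaussian PSF
  (default 0: measured optical distortion in this geometry is below one
  pixel) is applied before sampling. In noiseless mode the unrounded
  expectation is returned so additivity and linearity hold exactly; counts
  are quantised only on TIFF export.
- **Determinism.** One base seed; each image derives its own stream and the
  caller's RNG state is restored.

What the generator does *not* emulate: lens vignetting and refraction at the
tank wall, CCD blooming and radiation strikes, frame-rate/summing effects of
long acquisitions, source-capsule asymmetry, and any long-term drift of the
optical chain. Passing tests therefore validate the analysis chain and its
statistical behaviour under the stated noise model — they do not certify a
physical camera, whose hardware-dependent numbers (e.g. measured spatial
resolution, catheter/water ratios, an apparent half-decay a few percent off)
must come from commissioning measurements.

## Analysis chain

Raw pairs go through: signed background subtraction (no clipping at zero, so
noise statistics stay unbiased) → median filter over the radius-2 Euclidean
disc (13 pixels), with mirror-without-edge-repeat reflection padding — the
disc and padding conventions are pinned down so the brute-force oracle test
is exact → 1-pixel-wide profile extraction (`width_px` is configurable
because "1 pixel in both directions" can also be read as ±1-px averaging;
default 1 line) → calibration and normalisation.

Calibration divides by the slope of the intensity-versus-dose line at
$r = 10$ mm; the fitted intercept is treated as residual background and
subtracted first, since background subtraction should already have removed
the offset and the calibration factor is defined as a slope. Values at
non-pixel radii are linearly interpolated.

## QA metrics

- **Localization**: the global profile maximum, half-maximum crossings found
  by linear interpolation between bracketing samples on each flank, position
  = midpoint of the crossings. Sub-pixel by construction; exact on symmetric
  peaks; requires the peak to clear 5× the background spread.
- **Intervals** are differences of positions from *separately exposed*
  single-dwell images: at a 2.5-mm preset the two dwells of a 4.5-mm capsule
  would merge into one peak in a single exposure, and imaging the two points
  independently matches how per-point film comparisons are done. (Single-image
  two-peak analysis would need a deconvolution step that is out of scope.)
- **Half-life** is fitted log-linearly by default (ordinary least squares on
  log intensity — variance-stabilising under multiplicative noise, and exact
  on noiseless data); weighted nonlinear least squares is available via
  `method = "nls"`. A non-negative fitted slope is flagged as "no decay
  detected" rather than returning a negative half-life.
- **Profile agreement** resamples the reference onto the measured positions
  (linear interpolation), takes per-point percent differences with the
  reference in the denominator, pools both sides of the peak, and reports
  mean and max |%diff| over a radial region (default 7–30 mm, where
  dose-light proportionality holds).
- Repeatability (percent s.d./mean per dose) and dose-rate independence
  (max group-mean deviation from the grand mean) follow the standard
  definitions. Default pass tolerances: position 0.2 mm, strength 3%, dose
  difference 3% — all configurable in `run_config()`.

One practical convention inside `qa_suite()`: the strength-tracking section
uses a long 240-s dwell, which at the reference gain would saturate the
16-bit sensor, so that section scales the gain down by the ratio of the 6-Gy
dwell time to 240 s — the physical analogue of stopping the lens down for a
brighter protocol. Strength readings are relative, so the common factor
cancels in the decay fit.

## Problem sizes and reproducibility

The packaged tests run the full chain on full-frame 772 × 580 images for the
end-to-end checks (4 localization replicates, 4 replicate pairs per interval
preset, 8 dose levels for linearity, 13-point decay series) and on 240 × 240
frames for unit-level properties; these sizes make the suite complete in a
few minutes on a single core while leaving the statistical conclusions
unchanged, since every estimator involved concentrates with pixel count and
replicate count. `scripts/acceptance.R` recomputes the headline quantities
from scratch at the full frame size under a caller-supplied seed.

## Known limitations

- The point-source TG-43 form under-structures the dose within a few mm of
  the capsule; combined with the LEVEL B beta excess this reproduces the
  *pattern* of near-source disagreement, not its exact magnitude.
- $g(r)$ beyond 10 cm is held at its 10-cm value; profile tails beyond the
  clamp contribute negligibly to any metric evaluated within 30 mm.
- The catheter/water brightness ratio is configuration, not prediction.
- Dwell-time resolution is not modelled: the generator integrates a dwell
  into a single exposure, as the measurement method itself cannot resolve
  intra-exposure timing.
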