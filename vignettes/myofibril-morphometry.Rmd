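---
title: "Measuring sarcomeres and myofibrils: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sarcomeres and myofibrils: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofq)
```

## What the package measures

Fibrillar flight muscle is built from hundreds of individual myofibrils,
each a chain of sarcomeres. Two fluorescence views carry the morphometry:

* **lengthwise** (longitudinal) images show periodic striations — the
  Z-discs repeat along each fibril at the sarcomere length;
* **crosswise** (transverse) images show each myofibril as a bright disk.

`analyze_lengthwise()` returns the sarcomere repeat and the myofibril
width; `analyze_crosswise()` returns the number of cross-sections, their
density per unit area and the fibril diameter. All estimators operate on
an `image2d` — an intensity matrix plus the physical pixel size in µm —
and every output is in physical units. The measurement conventions
correspond to confocal imaging of actin-stained flight muscle at 50 nm
pixels, where sarcomere lengths run from about 1.8 µm in early pupae to
about 3.2 µm in adults and fibril diameters from about 0.46 µm to about
1.43 µm.

## Lengthwise analysis

**Sarcomere repeat.** The striation is periodic along the fibril axis, so
the repeat is read in the frequency domain: the image is mean-subtracted,
each row is Hann-windowed, and the 2-D power spectrum is averaged over all
vertical frequencies to give one power value per horizontal spatial
frequency (`horizontal_power_spectrum()`). The repeat is the reciprocal of
the dominant peak within a period search band (`band_um`, default
1–5 µm — this brackets every sarcomere length the tool is meant for while
excluding the DC region and single-pixel artefacts). Peak position is
refined below one frequency bin by (a) 4× horizontal zero-padding and
(b) parabolic interpolation over the log-power of the three bins around
the maximum. The combination resolves period changes of ~0.01 µm at
3.2 µm on a ~300-pixel-wide ROI, which pixel-quantized peak picking could
not. A prominence score (peak power / median in-band power) and an
at-band-edge flag accompany every estimate.

**Myofibril width.** The width is the lag of the first local minimum of
the vertical intensity profile of the image autocorrelation
(`estimate_width()`). For parallel fibrils of width *w* repeating every
*s* across the image, the vertical ACF of the stripe pattern dips first at
lag *w* when the duty cycle *w/s* is 50%. At other duty cycles the first
minimum tracks min(*w*, *s − w*)-like geometry rather than the width
alone; the estimator is therefore exact at 50% duty and biased otherwise,
which the test suite documents explicitly with a duty-cycle sweep. The
minimum is refined by parabolic interpolation; an ROI whose vertical ACF
is monotone (e.g. a single fibril filling the ROI) is flagged
`minimum_found = FALSE` rather than forced to a number.

**Orientation and tiling.** The estimators assume horizontal fibrils.
`orient_and_tile()` automates the rotation: the principal axis of the
second-moment tensor of in-band 2-D spectral power gives the direction of
strongest periodic variation, which for parallel fibrils is the
cross-fibril (spacing) direction; the fibril axis is perpendicular to it.
The image is rotated by bilinear interpolation, the largest centred
rectangle free of out-of-frame samples is computed analytically, and its
central 90% is tiled into a 3×3 grid of non-overlapping ROIs (minimum
64 px per side). Nine ROIs per image is the protocol the summary
statistics are defined over; a manual `rotate_deg` override is available.
When the spectrum has no dominant direction (eigenvalue ratio < 1.2) the
rotation is left at 0° and flagged. Per-ROI failures are recorded in the
result table; the analysis errors out only when fewer than 5 ROIs yield a
repeat.

Each ROI must hold at least ~3 periods of the structure being measured:
with a 3×3 grid, measuring a 3.2 µm repeat needs an image at least
~1000 px (50 µm) wide after rotation cropping. Small rotated frames fail
softly (low prominence, band-edge flags), which is the intended QC signal.

## Crosswise analysis

The pipeline has four stages.

1. **Scale calibration** (`initial_diameter()`): the first minimum of the
   radial average of the image autocorrelation, searched only at lags
   below a quarter of the field so the circular wrap-around of the FFT
   autocorrelation cannot masquerade as structure. This `d0` mixes disk
   size with packing geometry — it is deliberately used only to set
   scales, never reported as the diameter. With no minimum (a lone disk),
   a configurable fallback (1 µm) is used and flagged.
2. **Detection** (`detect_cross_sections()`): Gaussian smoothing with
   σ = d0/4, 8-neighbour local maxima above `median + k·MAD`, greedy
   brightest-first suppression of peaks closer than 0.8·d0, and removal
   of peaks within one crop half-width of a border. The threshold factor
   defaults to **k = 5**: on megapixel fields the MAD of the smoothed
   background equals the local noise sd, and a 3-sd cut admits a few
   background maxima per image, whereas real sections at the photon
   budgets of confocal imaging sit more than 10 noise-sd above the
   background — k = 5 keeps the false-positive rate negligible without
   costing sensitivity. All parameters are exposed in the configuration.
3. **Template averaging** (`average_cross_section()`): square crops of
   side `crop_factor · d0` (factor 2 by default) are re-centred on their
   background-subtracted intensity centroid (evaluated within d0/2,
   rounded to a pixel) and averaged. Re-centring removes the ±1 px
   detection jitter that would otherwise blur the average; the residual
   template noise falls like 1/√N, which the tests verify.
4. **Diameter readout** (`diameter_from_template()`): the radial
   intensity profile of the template is thresholded at
   `min + 0.26 · (max − min)` and the diameter is twice the radius of
   the first downward crossing (linear interpolation between 1-px radial
   bins). "Range" is anchored at the profile minimum; the alternative
   reading (26% of the maximum) is available as
   `range_anchor = "zero"`.

**A deliberate caveat: optical widening of the 26% readout.** For a
step-edged object blurred by a Gaussian PSF of width σ, the radius at
which the profile falls to a fraction *q* of its range is
`r(q) ≈ a + Φ⁻¹(1 − q)·σ`. The unbiased fraction is 50%; at 26% the
readout is wider than the underlying object by about
`2·Φ⁻¹(0.74)·σ ≈ 1.29·σ` — +0.13 µm at σ = 0.10 µm. The low fraction
makes the measurement robust on real, soft-profiled fibrils (it reads the
outer skirt rather than the steep flank), at the price of this optical
bias on sharp objects. The package implements the convention literally
and the test suite measures the bias quantitatively: top-hat phantoms are
recovered within one pixel under near-ideal optics (σ = 0.02 µm) and are
over-read by ≈1.29σ under realistic blur. Deconvolution is out of scope,
so comparisons across conditions should hold the PSF constant.

The density denominator is the border-margin-excluded search area (the
region in which peaks were actually accepted), not the full frame, so
border exclusion does not bias densities downward. Derived quantities are
exact arithmetic: `sarcomeres_per_fibril()` (fiber length / sarcomere
length), `fibrils_per_fiber()` (density × fiber cross-section area),
`bead_normalized_intensity()` (mean of three fiber ROIs / mean of three
bead ROIs), and `box_summary()` (type-7 linear-interpolation quartiles
with Tukey 1.5·IQR whiskers — the quartile convention is fixed and
documented because plotting packages differ).

## The phantom generator

Every estimator is validated by parameter recovery on synthetic phantoms
with known ground truth (`make_lengthwise_phantom()`,
`make_crosswise_phantom()`, `make_stage_series()`).

*Lengthwise phantoms* render parallel fibril bodies (top-hat or Gaussian
cross-profile) carrying 2-px bright Z-lines at the chosen repeat,
optionally rotated, then convolved with a Gaussian PSF, scaled to a peak
photon count, offset by a constant background and Poisson-sampled.
*Crosswise phantoms* place non-overlapping top-hat disks by dart throwing
with a minimum separation and a border margin, then apply the same
PSF/noise model. The top-hat edge is the reference rendering because it
is the only profile whose ground-truth diameter is unambiguous — a
recovery test needs that, even though real fibrils have softer profiles.

Defaults state the imaging conditions the package targets: 0.05 µm
pixels; PSF σ 0.15 µm for longitudinal views (roughly a high-NA confocal
at this sampling) and 0.10 µm for the cross-section views taken at higher
zoom; photon peak 50; background 5. Geometry is computed in pixel units
so that integer-pixel periods render exactly periodic patterns. All
randomness is seeded: regeneration with the same record is bit-identical,
and the caller's RNG stream is left untouched.

What the phantoms do **not** emulate: sarcomere substructure (M-lines,
thick/thin filament overlap texture), fibril curvature and branching,
size variability within a field, out-of-focus haze, detector read noise
and anisotropic PSFs. Passing recovery tests therefore demonstrates the
estimators' correctness under the stated noise and blur model, not
robustness to every property of real micrographs — the QC outputs
(prominence, flags, overlay figures) exist because real data needs visual
inspection.

## Numerical conventions

* Autocorrelation is circular (computed via the power spectrum), zero lag
  at the central sample, unit-normalized; images are mean-subtracted
  first so the DC term cannot mask minima or peaks. Consequence: all
  outputs are invariant under affine intensity rescaling `a·I + b`.
* Radial profiles bin by `floor(r / b)` with axis at bin centres; empty
  bins are dropped, never interpolated. Default bin width 1 px.
* First-minimum search takes the smallest lag with
  `v[k] ≤ v[k−1]` and `v[k] < v[k+1]` (ties toward smaller lag);
  spectral argmax ties break toward lower frequency. Parabolic offsets
  are clamped to ±0.5 samples.
* Degenerate inputs (constant images, flat templates, monotone profiles,
  empty detections) raise typed conditions (`myofq_degenerate_input`,
  `myofq_no_minimum`, `myofq_empty_set`, ...) rather than returning
  numbers.
* Coordinates are 0-based (row, col) with pixel centres at integer
  coordinates, stated once and used everywhere, including CSV output.

## Validation problem sizes

The recovery suite uses 512×1024 px lengthwise phantoms (9 ROIs of
~150×300 px) and 2048×2048 px crosswise phantoms with 300 disks for the
stage-value recoveries, with parameter grids and oracle comparisons on
smaller fields (16×16 to 1024×1024). These sizes give each ROI several
periods of structure and each template hundreds of averaged sections —
the regimes the measurement protocol itself prescribes — while keeping
the full validation run in the minutes range on a single CPU.

## Known limitations

* The width estimator is exact only at 50% duty cycle (see above).
* The 26%-of-range diameter carries the ≈1.29σ optical widening; small
  (< 0.5 µm) structures under a 0.10 µm PSF are over-read by ~25%.
* The orientation estimator assumes one dominant fibril direction;
  crossing fibril populations yield a flagged 0° rotation.
* Circular autocorrelation assumes approximate stationarity across the
  ROI; strong illumination gradients should be corrected upstream.
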