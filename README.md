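# myofq — quantitative morphometry of myofibrils

`myofq` measures the architecture of fibrillar flight muscle from 2-D
fluorescence micrographs: **sarcomere repeat length** and **myofibril
width** from longitudinal views, and **myofibril diameter, count and
density** from transverse cross-sections. It is aimed at muscle
developmental biologists who need automated, reproducible morphometry
across developmental stages and genotypes, plus the derived quantities
those studies report (sarcomeres per fibril, fibrils per fiber,
bead-normalised fluorescence, Tukey box summaries).

Because raw micrographs are rarely shareable, the package ships a
synthetic **phantom generator** with exact ground truth, so every
estimator is validated by parameter recovery rather than by eye.

## Methods in brief

For an image `I(x, y)` with fibrils horizontal and pixel size Δ (µm/px):

* **Sarcomere repeat** — from the horizontal power spectrum
  `P(f_x) = ⟨|F{I − Ī}|²⟩_{f_y}` (Hann window per row): the repeat is
  `1 / f*`, where `f*` is the dominant peak in the period band 1–5 µm,
  refined to sub-bin precision by parabolic interpolation of log power.
* **Myofibril width** — the lag of the first local minimum of the
  vertical profile `C(0, Δy)` of the normalised autocorrelation
  `C = F⁻¹|F{I − Ī}|² / C(0,0)`.
* **Myofibril diameter** — detect cross-sections as local intensity
  peaks (scales calibrated by the first minimum of the radial ACF
  profile), average all detected sections into a noise-free template,
  and report the full width where the template's radial profile falls to
  26% of its max–min range.
* Nine non-overlapping ROIs per lengthwise image (after automatic
  rotation to horizontal fibrils) define the summary statistics.

The methods vignette (`vignettes/myofibril-morphometry.Rmd`) documents
every tunable parameter, the noise model of the phantoms, and the known
estimator properties (duty-cycle dependence of the width, the ≈1.29·σ_PSF
optical widening of the 26% diameter readout).

## Worked example

```r
library(myofq)

# an adult-stage longitudinal phantom: repeat 3.2 um, fibril width 1 um
ph <- make_lengthwise_phantom(shape_px = c(512, 1024), repeat_um = 3.2,
                              fibril_width_um = 1.0,
                              fibril_spacing_um = 2.0, seed = 3)
analyze_lengthwise(ph$image)
#> <lengthwise_result> 9/9 ROIs ok, rotation 0.04 deg
#>   repeat: mean 3.188 um (median 3.190, sd 0.0278, n 9)
#>   width : mean 0.962 um (median 0.963, sd 0.00524, n 9)
```

The repeat (3.188 µm) recovers the planted 3.2 µm sarcomere length within
one pixel (0.05 µm); the width reads the 1 µm fibril at 0.96 µm. A
transverse field works the same way:

```r
pc <- make_crosswise_phantom(shape_px = c(1024, 1024),
                             disk_diameter_um = 1.43, n_disks = 80,
                             seed = 3)
analyze_crosswise(pc$image)
#> <crosswise_result> 80 fibrils, diameter 1.559 um
#>   d0 2.673 um, density 0.03797 /um^2 over 2106.8 um^2
```

All 80 planted sections are found; the diameter readout (1.559 µm) is the
planted 1.43 µm plus the documented ≈1.29·σ_PSF optical widening
(+0.13 µm at the default 0.10 µm PSF). Derived morphometry is exact
arithmetic on these outputs:

```r
sarcomeres_per_fibril(480, 3.188)   # fiber length / sarcomere length
#> 150.5646
fibrils_per_fiber(0.03797, 6970)    # density x fiber cross-section area
#> 264.6655
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/myofq.R", package = "myofq"))')
Rscript $CLI phantom lengthwise --out out/ --seed 3
Rscript $CLI lengthwise out/phantom_lengthwise_seed3.tif \
        --pixel-size 0.05 --out out/results.csv --qc
Rscript $CLI morpho out/results.csv --fiber-length 480
```

Results are long-format CSV (one row per ROI per metric plus summary
rows); `--qc` adds overlay PNGs (spectrum with the detected peak, centres
over the image, radial profile with the 26% crossing). Every run writes a
JSON echo of the full configuration.

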