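# acrcnr

Automatic contrast-to-noise ratio (CNR) measurement on images of the ACR CT
accreditation phantom's low-contrast module, for medical physicists running
CT quality-control programs. Manual CNR measurement — placing circular ROIs
by hand on a low-contrast insert a few HU above background — is slow and
subjective; `acrcnr` implements the statistical rotating-ROI method that
localizes the insert automatically and computes the CNR reproducibly, plus a
synthetic phantom-slice generator so the whole pipeline can be validated
against known ground truth without scanner data.

## Method

The low-contrast module of the ACR phantom contains a 25 mm reference
cylinder whose centre lies at a fixed radial distance of 55 mm from the
phantom centre, at an unknown angle (and the phantom itself may be
misaligned in the gantry). The measurement proceeds in four steps:

1. **Segment** the phantom body from air (threshold at −300 HU, largest
   connected component, holes filled) and take its binary **centroid**.
2. **Rotate** a 25 mm circular ROI clockwise around the centroid at a radius
   of 55 mm in 2° steps, recording the mean CT number at each of the 180
   positions — the angular profile.
3. **Localize** the object at the angle of maximum mean CT number.
4. **Measure** with two ROIs — one on the object, one at the centroid — and
   compute

   CNR = (CT̄_object − CT̄_background) / SD_background

   where CT̄ are ROI mean CT numbers (HU) and SD_background is the sample
   standard deviation of the background ROI. The ACR program requires
   CNR ≥ 1.0 for the low-contrast module.

Because the search is anchored on the measured centroid rather than the
image centre, the method tolerates phantom misalignment of at least 10 mm.

## Worked example

```r
library(acrcnr)

cfg <- phantom_config(contrast_hu = 6, noise_sd_hu = 3,
                      object_angle_deg = 134, n_slices = 3, seed = 42)
stack <- generate_stack(cfg)
results <- lapply(stack, function(s) auto_cnr(s$image))
results[[1]]
#> <cnr_result> contrast 5.9 HU, noise 3.0 HU, CNR 2.0
#>   object at 134 deg, (156.83, 155.48) mm; phantom centroid (117.27, 117.27) mm

series <- summarize_cnr(results, label = "synthetic 120 kV")
series
#> <cnr_series> synthetic 120 kV (n = 3)
#>   contrast 5.9 ± 0.1 HU, noise 3.0 ± 0.0 HU, CNR 2.0 ± 0.0
acr_tolerance_check(series)
#> ACR low-contrast CNR check: mean CNR 1.98 vs tolerance 1.0 -> PASS
```

The detected angle (134°) matches the configured ground truth; the mean CNR
of 1.98 recovers the configured contrast/noise ratio 6/3 = 2 up to the small
loss from partially covered rim pixels of the object ROI. For scanner data,
replace the generator with `read_dicom_stack("path/to/series")` and feed the
slices to `auto_cnr()`; `compare_series()` then tests automatic against
manual measurements (percent difference and Mann–Whitney U).

A command-line interface with `measure`, `simulate` and `compare`
subcommands is installed at `inst/cli/acrcnr.R`:

```sh
Rscript inst/cli/acrcnr.R simulate --config sim.cfg --out simdir
Rscript inst/cli/acrcnr.R measure simdir --out results.csv
Rscript inst/cli/acrcnr.R compare auto.csv manual.csv --field cnr
```

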