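# mtbarcode

Digital information can be written onto individual gliding microtubules by
photobleaching: a stationary pulsed laser bleaches dark lines across a
fluorescently labeled filament as kinesin-1 motors propel it over a
coverslip at velocity *v<sub>x</sub>*. Firing the laser at time intervals
*t<sub>x</sub> = x<sub>b</sub> / v<sub>x</sub>* converts a temporal pulse
train into a spatial period *x<sub>b</sub>* along the filament, and
superposing several pulse trains writes several spatial periods into the
same ~12 µm stretch. Each period carries one bit; with periods 857, 1000,
1200 and 1500 nm (tolerance bins 800–857, 930–1000, 1120–1200 and
1400–1500 nm, shortest period = most significant bit), the 4-bit numbers
0001₂–1111₂ are encoded and later read back from ordinary fluorescence
time-lapse stacks by Fourier analysis — no start marker and no path
tracking required.

`mtbarcode` implements the full method for anyone studying or extending
filament barcoding:

* **Codec** — bit ↔ period maps, tolerance bins, and bleach-pulse
  schedules (`barcode_scheme()`, `periods_for_code()`,
  `code_for_detections()`, `make_schedule()`), plus a Monte Carlo
  `design_sweep()` over candidate period sets.
* **Synthetic data** — a gliding-assay simulator producing 16-bit EMCCD
  stacks with ground truth: Poisson dye speckling, white velocity jitter,
  pulsed Gaussian-beam bleaching, diffraction-limited imaging and
  Gamma-amplified EM readout (`simulate_barcode_stack()` and the
  underlying `generate_filament()`, `simulate_motion()`,
  `apply_bleaching()`, `render_frames()`).
* **Readout** — intensity profiles extracted along a tracked centerline
  on a 3× interpolated grid with 3-pixel transverse averaging,
  cross-correlation alignment and averaging, smoothing-spline detection
  of the bleached region, and an amplitude spectrum with a robust dynamic
  baseline, bootstrap 95% confidence intervals and significance calls
  (`extract_profiles()`, `align_and_average()`, `find_bleached_region()`,
  `amplitude_spectrum()`, `fit_baseline()`, `bootstrap_detections()`,
  `read_barcode()`).

A detection at period *p* is significant when the lower bound of its
bootstrap confidence interval exceeds the local threshold; the threshold
is the larger of *k* × baseline (with *k* = 3.8 calibrated so white noise
exceeds it in ≤ 1% of bins) and 10% of the strongest detected line (which
rejects the phase-noise sidebands that velocity jitter spreads around a
dominant peak). The decoded integer is the sum of the bit weights of the
bins containing the significant periods.

## Worked example

Simulate a filament encoding 1001₂ (= 9) at the default conditions
(1000 nm/s with 3% velocity jitter, fully labeled tubulin, EM gain 300,
25 × 50 ms exposures) and decode it:

```r
library(mtbarcode)
sc  <- barcode_scheme()
sim <- simulate_barcode_stack(9, sc, seed = 7)
ro  <- read_barcode(sim$stack, sim$track, sc, decode_config(seed = 2))
print(ro)
#> <barcode_readout> code 9 (binary 1001)
#> <bleached_region> 4053..16053 nm (12.0 um, automatic)
#>   period amplitude ci_low ci_high baseline threshold   snr significant
#> 1    857      7157   7113    7204      238       905 7.906        TRUE
#> 2   1200       287    228     345      238       905 0.317       FALSE
#> 3   1500      8788   8722    8854      238       905 9.708        TRUE
```

The bleached region (4.1–16.1 µm of arc length) is found automatically;
the 857 nm and 1500 nm periods are significant — signal-to-noise ratios
7.9 and 9.7, amplitude divided by threshold — and map to bits 1000₂ and
0001₂, giving 1001₂ = 9. The weak 1200 nm candidate stays far below
threshold and is discarded.

The same pipeline runs from the shell
(`inst/cli/mtbarcode`): `schedule` prints a pulse table, `simulate`
writes `stack.tif` + `track.tsv` + `truth.json`, `decode` reads them back
(exit 2 when no bleached region exists, 3 when fewer than two frames are
usable), and `validate` sweeps all 15 codes.

Real data can be decoded by supplying the TIFF stack plus a track table
(tab-separated `frame  index  x_nm  y_nm`, one centerline point per
pixel, leading end first) converted from any filament tracker.

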