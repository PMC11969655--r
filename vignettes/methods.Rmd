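---
title: "Photobleaching barcodes on gliding microtubules: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photobleaching barcodes on gliding microtubules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbarcode)
```

## The encoding model

A microtubule glides across a kinesin-coated surface at mean velocity
$v_x$ (default 1000 nm/s) and crosses a stationary focused laser line.
Pulsing the laser at intervals $t_x = x_b / v_x$ writes a bleached line
every $x_b$ nanometres of arc length. Superposing one pulse train per
coded period writes several spatial frequencies into the same stretch.
Each period is one bit: present = 1, absent = 0.

The default scheme uses $x_b \in \{857, 1000, 1200, 1500\}$ nm over a
12 µm region, assigned to bits in descending order (857 nm is the most
significant bit; `bit_order = "lsb_shortest"` selects the reversed
assignment). These four periods are not arbitrary: they are
$6000/7, 6000/6, 6000/5, 6000/4$ nm, i.e. four *consecutive harmonics*
of a 6000 nm base, and the 12 µm region holds an integer number of
cycles of every one of them. Two consequences drive the whole readout
design:

* on the discrete Fourier grid of the cropped region the coded lines
  fall exactly on bins spaced two bins apart, so a rectangular window
  resolves them with zero mutual leakage;
* every intermodulation product that the nonlinear bleaching response
  generates (see below) also lands on a harmonic of 1/6000 — on a coded
  or maskable bin rather than smeared between bins.

All pulse trains share the event at $t = 0$, the moment the leading edge
of the encoded region crosses the line (the relative phase between
trains is not physically constrained; a shared origin maximises the
depth of the first minimum). Events from different trains that coincide
within one pulse duration (5 ms) are merged into a single schedule entry
that **keeps the pulse count as its dose weight**. This matters: the
trains collide at $t = 3, 6, 9, 12$ s for multi-bit codes, and treating
a collision as a single unit dose would carve a periodic "missing dose"
comb into the pattern whose harmonics fall exactly on the 1500 nm code
line, corrupting the code. Physically the galvo sweeps the line once per
pulse, back to back, so the summed dose is the faithful model.

## The synthetic-data generator

`simulate_barcode_stack()` emulates the full experiment. Its defaults
are the package's study conditions; each was fixed once, as follows.

| parameter | default | rationale |
|---|---|---|
| `v_x` | 1000 nm/s | typical kinesin-1 gliding speed |
| `jitter_fraction` | 0.03 | white per-step velocity noise; stepping noise of many motors largely averages out |
| `dt` | 5 ms | one pulse duration |
| `lead_in` | 4000 nm | encoding starts after ~4 µm of filament has passed the line |
| `labeling_density` | 6.5 dyes/nm | fully labeled tubulin: ~1.6 dimers/nm of lattice, up to 4 amine-reactive sites per dimer |
| `psf_sigma` | 90 nm | diffraction-limited 1.49 NA at ~520 nm emission ($\sigma \approx 0.21\lambda/\mathrm{NA}$) |
| `beam_sigma` | 180 nm | a ~0.6 µm focused spot (FWHM 0.42 µm, 99% of dose within 0.9 µm); gives an effective bleaching resolution near 500 nm |
| `pixel_size` | 160 nm | 16 µm EMCCD pixel / 100× objective |
| `exposure`, `em_gain` | 50 ms, 300 | camera settings of the assay |
| `read_noise`, `offset`, `e_per_adu` | 2 ADU, 100 ADU, 16 | typical EMCCD readout chain |
| `photons_per_fluorophore` | 5 / exposure | dim 1%-power TIRF imaging |
| `dose` | 0.7 e-foldings/pulse | see below |
| filament length | 20 µm | long filaments are selected so the 12 µm region plus lead-in fits with unbleached plateaus on both sides |

**Dye speckling.** Fluorophore count is Poisson(density × length) with
uniform positions. Speckle is the dominant noise floor of the readout:
it is a *fixed pattern* of the filament, so frame averaging does not
reduce it — only labeling density does (floor ∝ $1/\sqrt{\rho}$
relative to signal).

**Motion.** Arc-length offset $x(t)$ accumulates independent Gaussian
increments of mean $v_x\,dt$ and SD `jitter_fraction`·$v_x\,dt$,
clamped at zero (the filament never slides backwards). Over one pulse
interval the accumulated position noise is a few nanometres; its main
observable effect is a phase-noise pedestal around strong spectral
lines (see *Sideband floor* below).

**Bleaching.** Each event multiplies every dye's survival probability
by $\exp(-w\,d\,e^{-\Delta^2/2\sigma_b^2})$, where $\Delta$ is the
dye's distance from the line at the event midpoint, $d$ the peak dose
and $w$ the merged-pulse weight. The dose is the one genuinely free
calibration (the assay quotes irradiance but no bleaching
cross-section). $d = 0.7$ (50% of dyes bleached at line centre per
pulse) was chosen by the decode-reliability criterion: the bleach
response is exponential, so superposed combs intermodulate, and
third-order products ($2f_i - f_j$, $f_i + f_j - f_k$) land exactly on
*other code lines* with relative amplitude $\sim m^2/4$. At $d = 0.7$
these stay near 6% of the fundamentals — below the sideband floor of
the decoder — while single-line contrast remains strong. At
$d \gtrsim 1$ they cross 9% and begin to forge bits; much lower doses
starve the weakest lines.

**Imaging.** Each surviving dye contributes a 2-D Gaussian of expected
`photons_per_fluorophore`, broadened along the gliding axis by motion
blur over the exposure. Shot noise is Poisson per pixel; the EM
register multiplies $n$ photo-electrons by a Gamma($n$, gain) draw
(reproducing the EMCCD excess-noise factor $\sqrt 2$); read noise and
offset are added and frames are quantized to 16 bits. With
`noise = FALSE` the expected-value image is returned unquantized, which
makes conservation and linearity properties exact.

What the generator does **not** model: filament curvature and crossing
(filaments are straight and perpendicular to the line, as selected in
the assay), dye blinking and triplet states, background fluorescence,
tracking error beyond the exact simulated centerline, and lattice-
correlated labeling (sites are a continuum, not an 8 nm lattice). A
passing test suite therefore demonstrates the method's behaviour under
idealized but realistically parameterized conditions, not performance
on arbitrary real micrographs.

## Readout pipeline

**Profiles.** The frame is sampled by separable cubic (Keys)
interpolation at stations spaced `pixel_size/3` along the tracked
centerline, averaging 3 transverse samples on the interpolated grid
(about one original pixel across). Arc length 0 is the leading end.

**Alignment.** Profiles are aligned by the argmax of their Pearson
cross-correlation against the first frame, refined by parabolic
interpolation of the correlation peak, then re-aligned once against the
running mean (with the mean extra shift removed, so the common frame is
preserved). Three numerical choices matter: the search window (default
±500 nm) must stay below the shortest coded period, because the
bleached pattern is periodic and a wider search can lock onto a
whole-period offset; ties in the correlation peak resolve to the
smallest shift; and sub-grid refinement is skipped when the discrete
peak is already a perfect match, so noiseless on-grid shifts are
recovered exactly. Because the initial reference is the first frame,
averaging is order-invariant only up to the reference choice; permuting
the remaining frames leaves the result unchanged to rounding.
Non-overlapping edges are trimmed, not zero-filled, before averaging,
to avoid spectral leakage from artificial steps.

**Bleached region.** The border search works at two scales, mirroring
the semi-automated procedure of fitting a smoothing spline and taking
its derivative extrema, with the manual "starts and ends at the first
and last bleached minimum" step automated. A moving average over
3000 nm (applied twice; the residual ripple of every coded period is
squared away, and a 1500 nm modulation is nulled exactly) gives the
well envelope; its steepest descent and subsequent steepest ascent in
the interior 90% of the profile bracket the well. A smoothing spline
whose parameter is chosen so its residual SD matches the
high-frequency noise estimate (robust successive differences) then
supplies the bleached minima — local minima dipping below the plateau
by at least a quarter of the well depth — and the first and last of
them are the borders. A region is rejected (`NoBleachedRegion`) for
flat or monotone profiles, or wells shallower than both 3× the noise
and 5% of the plateau; regions shorter than the longest coded period
raise `RegionTooShort`. `override_region()` preserves the manual path.

**Spectrum.** The averaged profile is cropped to the region
*right-exclusively* — $n$ samples of spacing $h$ give a transform of
period $nh$, so $[{\rm left}, {\rm right})$ makes the transform length
equal the border-to-border distance, an integer number of coded cycles
— mean-subtracted and transformed with 8-fold zero padding.
Amplitudes are normalized so a unit sinusoid reads 1. The window is
rectangular by default: a Hann window's mainlobe (4/T null-to-null) is
wider than the two-bin line spacing and merges adjacent coded peaks.
Because the detected borders can each sit one sample inside the true
bleach-line centres, the crop is refined over ±1 sample per border,
keeping the crop that concentrates the most ROI energy onto the
natural bins.

**Candidates on natural bins.** Peaks are detected on the *natural*
(unpadded) bins, where on-bin lines leak nothing; on the padded grid
the slowly decaying rectangular-window sidelobes tilt peak maxima by
several padded bins and spawn spurious local maxima between lines.
Candidates are local maxima above the baseline inside the 850–1500 nm
ROI (extended by one natural bin so a line sitting exactly on the ROI
boundary is not lost), merged within 60 nm to the larger.

**Dynamic baseline and threshold.** A quadratic in log-period is fit
to the natural-bin amplitudes outside the ROI (support 500–4000 nm) by
a 50%-breakdown MM-estimator — up to half the support bins carry the
pattern's real harmonic and difference-frequency lines and must be
rejected as outliers, not averaged in. Once candidates are known,
their predicted harmonics and mixing products
($2f, 3f, f_i \pm f_j, 2f_i \pm f_j$) are masked from the support and
the baseline refit; without this masking the baseline of 3–4-bit codes
inflates several-fold. The detection threshold at a candidate is

$$\mathrm{thr}(p) = \max\bigl(k\,\mathrm{baseline}(p),\;
  0.10 \cdot \max_i A_i\bigr)$$

with $k = 3.8$ frozen from `calibrate_threshold_factor()`: the factor
at which white-noise profiles exceed the threshold in at most 1% of
ROI bins. The second term is a *sideband floor*: velocity jitter
phase-modulates every written line, spreading a few percent of a
dominant line's amplitude into neighbouring bins, and deep bleaching
adds intermodulation at up to ~6%; genuine bits are written at
comparable dose and stay above ~25% relative amplitude, so a floor at
10% of the largest candidate rejects forged bits without touching real
ones. (It also caps the reportable signal-to-noise ratio at 10.)

**Significance and code assembly.** Frames are resampled with
replacement (whole frames, preserving within-frame correlation;
alignment shifts are reused) `n_boot` = 1000 times; the percentile
interval of each candidate's amplitude forms its 95% CI, widened if
necessary to contain the point estimate. A candidate is significant
iff its lower CI bound exceeds the threshold. Significant periods are
quantized into the tolerance bins with an upward allowance of half a
natural-bin step — the candidate grid $T/k$ is coarser than the bins,
whose upper edge is the nominal period itself — and out-of-band
detections are flagged in the diagnostics, never counted into the
code.

## Open choices decided here

* Whether the bootstrap resamples frames or profile segments is not
  constrained by the measurement model; frames are resampled because
  they are the independent replicates.
* The "3 pixel values perpendicular" are interpreted as samples on the
  3× interpolated grid (spanning ≈ 1 original pixel).
* The relative phase of superposed pulse trains is a shared origin.
* Code 0 is representable (an unbleached filament) but undecodable by
  construction: the analysis requires a bleached region, and
  `read_barcode()` raises `NoBleachedRegion` for it.

## Problem sizes

The test suite and acceptance script run desk-scale versions of every
experiment: 20 µm filaments at 6.5 dyes/nm (~130k dyes), 20–25 frames
of ~170 × 15 px, bootstrap sizes 50–500 in tests and 500–1000 in the
acceptance script, 200 outer replications for the CI-coverage check,
and 10 seeds per code for the noise ensembles. The full suite completes
in a few minutes on one CPU.

## Known limitations

* The decoder assumes one bleached region per filament; multiple
  disjoint regions are out of scope.
* Tolerance-bin decoding presumes the operator-entered velocity is an
  upper bound on the realized mean velocity (bins extend downward
  from the nominal period); a filament gliding *faster* than assumed
  by more than the quantization allowance decodes as out-of-band.
* The sideband floor makes the weakest decodable bit depend on the
  strongest one; codes written with strongly unequal per-period doses
  would need `rel_min` lowered accordingly.
* Speckle is the irreducible noise floor: a speckle fluctuation in a
  code bin of an otherwise weakly-modulated filament can still forge a
  bit in rare draws; the false-positive design point is ~1% per bin.
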