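---
title: "Methods: planar microwave imaging for aneurysm phantom detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar microwave imaging for aneurysm phantom detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planarmwi)
```

## The measurement model

`planarmwi` models a monostatic ultra-wideband radar built from M = 16
planar monopole antennas mounted on a 300 x 300 mm sheet above a torso
phantom. A vector network analyzer sweeps each antenna's complex
reflection coefficient S11 over 10 MHz-6 GHz in 5001 points (0 dBm source
power); a switching network selects one antenna at a time, so every
acquisition is a set of 16 single-port frequency sweeps. Internally all
lengths are millimetres, times nanoseconds and frequencies gigahertz; the
coordinate origin sits at a sheet corner with x/y in-plane and z pointing
down into the phantom.

Echo formation follows a linear superposition model: the loaded response
of antenna m is

    S_m(f) = sum_k a_k g(d_mk) exp(-j 2 pi f d_mk / v),

summed over point reflectors k, with round-trip distance `d_mk`, in-medium
speed `v = c / sqrt(eps_r)`, and geometric spreading
`g(d) = (d_ref / d)^2` (`d_ref` = 100 mm; the exponent is configurable).
Fixed clutter reflectors (setup hardware) appear identically in the
empty-reference and the loaded acquisition, so background subtraction
cancels them exactly under this model. Frequency dispersion is
deliberately not modeled — the propagation path is free air and the
nuisance echoes come from small rigid parts — and the aggregate of
everything the linear model misses is treated as complex additive white
Gaussian noise, scaled so the reconstructed echo peak sits 28 dB above the
noise floor by default (the hardware figure; `echo_snr_db` overrides it).

### Rendering extended bodies

`discretize_scatterer()` renders extended phantoms as point-facet clouds:
a plane sheet becomes a regular facet grid, a cylinder or ellipsoid a
sampling of its antenna-facing surface, each facet carrying amplitude
proportional to reflectivity and surface area. One exception is made on
physical grounds: a *large flat sheet parallel to the antenna plane*
reflects specularly, and image theory gives its exact return — a single
echo at twice the perpendicular distance. A facet-cloud quadrature of the
physical-optics integral instead acquires a spurious 1/f spectral tail
(the sweep starts at 10 MHz, where the product of wavenumber and distance
is small), which drags the envelope peak several millimetres late and
would break the sub-3.8% distance-calibration bound at 40 mm. The
simulator therefore uses the specular image-theory term for sheets
whenever the antenna's foot of perpendicular lies on the sheet, and falls
back to facets otherwise. Curved bodies keep their facet clouds: their
role in the pipeline is to contribute reference-plane amplitudes, not
millimetre-accurate ranging.

Water-phantom reflectivity defaults to 0.8 (the sheet reflector to 1.0).
The air-water amplitude contrast is not quantified in the source material;
these placeholders are exposed as configuration and all acceptance
quantities are ratios or positions that do not depend on their absolute
scale.

## Signal chain

Reconstruction uses the inverse chirp-Z transform restricted to the swept
band, evaluated on an arbitrary time grid:

    x(t) = scale * sum_k w_k S_k exp(+j 2 pi f_k t).

A Tukey window (alpha = 0.25) suppresses band-edge ringing; the default
`scale = 1/sum(w)` calibrates a unit echo to unit envelope peak. The
default output grid step is 0.01 ns — much finer than the ~0.167 ns
Rayleigh limit of a 6 GHz band — because envelope-*peak* localization for
an isolated echo is not resolution-limited, and the sub-4% distance errors
at 40 mm require it. Requesting a window longer than the unambiguous range
`1/delta_f` is an error. The Hilbert envelope (magnitude of the analytic
signal) carries a one-way distance axis `d = v t / 2`; `detect_distance()`
reports the global envelope maximum, breaking ties toward the earlier
sample so the nearest target wins. Time-of-flight extraction
cross-correlates the background-subtracted trace against the band-limited
transmitted pulse (flat Tukey-windowed spectrum over the band — the
hardware pulse is not tabulated) and keeps local maxima above a prominence
fraction of the global peak.

## Beamforming

DAS forms, for each focal point `r0` on a fixed-depth grid,

    I(r0) = int_0^Twin [ sum_m x_m(t + tau_m(r0)) ]^2 dt,
    tau_m(r0) = round((d_m / v) fs),

with `d_m` the 3-D round-trip distance. Delays are rounded to the nearest
sample (the dense grids make the rounding error negligible); delayed
samples outside a trace's support read as zero. IDAS multiplies the DAS
raster by a coherence factor. As printed, the coherence factor
`(sum_m x_m)^2 / (sum_m x_m^2)` reaches M for identical channels; the
package normalizes it by 1/M so CF lies in [0, 1] — consistent with the
standard coherence-factor literature and with thresholding images on a
bounded scale — and keeps the literal form behind
`cf_normalized = FALSE`. Whether CF should be applied per-sample inside
the integration window or after integration is ambiguous in the source
description; the package averages per-sample CF over the window, which
reduces to the same value whenever the channels keep constant proportions
across the window.

### The plane-constrained variant and the pulse-width question

The planar variant images a known reference depth: per antenna, the
background-subtracted sweep is reconstructed, its Hilbert envelope sampled
at the reference-plane distance, and a Gaussian pulse regenerated at that
fixed distance with the sampled amplitude; the pulses are then beamformed
with the full 3-D delays. Each antenna's pulse peaks where the delay
matches the reference distance — directly beneath that antenna — so the
image is a superposition of amplitude-weighted antenna footprints, and the
footprint radius is set by the pulse width.

The published width of the regenerated pulses is "14 ns" (FWHM). Taken on
the round-trip time axis this is ~80x the whole array's delay spread
(~2 ns at 180 mm depth): every pixel then integrates essentially the same
value, the image is constant to within a few percent, thresholding at 0.6
keeps the entire grid and the centroid collapses to the grid center. That
reading is also inconsistent with the description of the pulses as
*narrower* than the reconstructed echoes (whose width is c/2B ~ 25 mm
one-way, ~0.17 ns round-trip). The package therefore interprets the width
on the reconstruction's native round-trip *distance* axis — the axis the
reference figures are plotted on — as 14 mm (~0.047 ns), selectable via
`fwhm_axis = "time"` for the literal reading. The value was fixed by a
calibration sweep over widths on the synthetic proof-of-concept scenes,
mirroring the source system's own "experimentally adjusted for the current
setup" procedure; scene geometry, noise level, reflectivities, the 0.6
threshold and all seeds were left untouched by that calibration.
`regen_plane_pulse()` itself keeps the published surface: a Gaussian with
FWHM given in ns, default 14.

The integration window defaults to three band-limited pulse widths
(0.5 ns) for raw-trace beamforming and to the regenerated pulse's own FWHM
in planar mode. Images are max-normalized before thresholding, matching
presentation on a unit color scale.

## Detection and evaluation

Thresholding keeps pixels at or above 0.6 of the image maximum (the
experimentally adjusted setting, kept constant across cases); the centroid
is intensity-weighted over the mask (binary centroid available).
Positioning errors are reported per axis as absolute differences and as
percentages of the *real* coordinate — verified cell-by-cell against the
published nine-case evaluation table, with half-up rounding to one
decimal. The bundled `poc_reference_cases()` carries those printed
real/detected coordinate pairs.

System metrics: the fidelity factor is the peak normalized
cross-correlation magnitude between transmitted and received pulses (in
percent, delay- and scale-invariant); the published hardware values
(97.5%/96.3%) depend on the physical antenna transfer function and are not
reproduced. The SNR estimator reconstructs repeated empty sweeps, takes
the repetition-to-repetition variance as noise power and the loaded
trace's peak envelope power as signal. Note one boundary case: with no
echo present the estimator reports the *peak-to-mean* ratio of the noise
itself, which is positive (about +10 dB for a 400-sample trace), not
<= 0 dB; the tests assert instead that a no-echo estimate falls at least
10 dB below an echo-bearing one. Penetration depth uses the exact
plane-wave attenuation constant (infinite for lossless media) and is
validated against the low-loss closed form, not against the published
18.8/3.2 mm figures, whose blood dielectric inputs are not printed.
Spatial resolution uses the range-resolution convention v/(2B), documented
as convention-dependent.

## What the synthetic world does and does not establish

The generator reproduces the acquisition geometry, sweep settings, linear
echo superposition, clutter-consistent empty/loaded pairs, and an
echo-referenced 28 dB noise floor. It does not model antenna transfer
functions or dispersion, mutual coupling, multiple scattering or shadowing
(the aorta below the aneurysm is fully visible to the simulator, unlike
water in reality), or tissue losses. A green localization test therefore
establishes that the *pipeline* — reconstruction, reference-plane
sampling, planar IDAS, thresholding, centroid — recovers positions under
the stated model; it does not certify hardware performance. The
positioning-error medians land in the same range as the published
evaluation (errors below 10 mm and 5% in most cases), with the caveat that
placements beyond the outermost antenna row remain the hardest cases in
both worlds.

## Numerical choices

* ICZT grids: 0.01 ns for ranging; 401 points over 0-4 ns for
  reference-plane amplitude sampling; regenerated pulses at 100 GHz.
* Facet pitch 10 mm (well under the ~25 mm range resolution); sheet facets
  at 5 mm where used.
* Delay rounding to the nearest sample; out-of-support samples are zero.
* Global-maximum ties break toward the earlier sample.
* Default antenna layout: 4 rows of 4 on a 300 x 300 mm sheet, alternate
  rows staggered 30 mm, alternating orthogonal orientations, all pairwise
  spacings >= 25 mm, numbered column-major. The physical coordinates of
  the reference hardware are not published; measured layouts load via
  `read_array_layout()`.

## Known limitations

* The linear model omits shadowing, so deep structures are over-visible
  relative to a real water phantom.
* Reference-plane sampling conflates any scatterer whose slant range
  equals the reference distance with on-plane targets; real element
  directivity would attenuate these, the isotropic model does not.
* The CLI's Touchstone writer emits the Hz/RI dialect only (the reader
  accepts RI/MA/DB and all four frequency units).
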