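---
title: "Mirror-swept plane-wave 3-D ultrasound: model, scheduling and reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-swept plane-wave 3-D ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planesweep)
```

## The imaging problem

A 1-D linear array produces excellent 2-D plane-wave images at tens of
kilohertz of frame rate, but only in one plane. `planesweep` models a 3-D
acquisition scheme in which a small water-immersible mirror, resonating about
a hinge parallel to the array, reflects each transmitted plane wave into a
different elevational direction. Because the beam — not the transducer — is
swept, the volume rate is set by the mirror's tilting frequency rather than
by a mechanical translation stage, and a wedge-shaped 3-D field of view is
sampled hundreds of times per second.

The package contains everything needed to study this scheme on a desk:
transmit scheduling against the tilting mirror, a point-scatterer pulse-echo
simulator, delay-and-sum beamforming with coherent compounding, polar-to-
Cartesian scan conversion of the wedge, parameter recovery from synthetic
calibration sweeps, and image-quality metrics. A mechanical-translation mode
(the classic "wobbler"-style benchmark) is included for paired comparisons.

## Timing and kinematics

The pulse repetition frequency of a pulse-echo system is bounded by the
round-trip travel time, `PRF = c / (2 d)`. Compounding over `na` steering
angles reduces the per-frame rate to the effective PRF, `PRFe = PRF / na`.
With a sinusoidal drive, the mirror tilt at the `n`-th transmission
(`t_n = n / PRFe`, `n = 1, 2, ...`) is

```
theta_n = A sin(2 pi Fm t_n + phi) + gamma,
```

with half-side amplitude `A`, tilting frequency `Fm`, initial phase `phi`
and offset `gamma`; the reflected scan angle is `alpha_n = 2 theta_n` by the
law of reflection. Everything about the volume rate follows from the ratio
`r = PRFe / Fm`:

* **Condition 1** — `r` is an even integer and `(r / pi) phi` is an integer.
  The sampled phases are then symmetric about the sweep extrema, every
  elevational location is visited twice per tilting cycle, and each
  monotonic half-sweep is a complete volume: `Fv = 2 Fm`.
* **Condition 2** — otherwise the sampled-angle sequence only repeats after
  `m` mirror cycles, where `m` is the smallest positive integer making
  `m r` an integer, and `Fv = Fm / m`.

The planes per volume are `Np = PRFe / Fv`, plus one under condition 1 when
a transmission lands exactly on a sweep extremum — that extremal plane is
shared by the two adjacent half-sweep volumes, which is the only assignment
that reproduces the documented three positions at `r = 4`.

```{r rates}
kin <- mirror_kinematics(half_range_deg = 11.95, tilt_freq_hz = 250)
volume_rate(20000, kin)   # the full experimental operating point
volume_rate(1062.5, kin)  # deliberately non-integer ratio: m = 4
```

The phase clause is typeset ambiguously in its source; it is implemented
literally as `(r / pi) * phi` being an integer. For even integer `r` this is
exactly the reflection symmetry of the sampled phases about the extrema, so
it agrees with brute-force enumeration of the schedule; the test suite
checks that equivalence on 200 random rational ratios at phases 0, pi/7 and
pi/4. Classifications that rely on a nonzero phase are flagged with a
warning rather than silently accepted. Integer and evenness tests use a
relative tolerance of 1e-9 so that ratios such as 1062.5/250 classify
robustly, and the multiplier search is capped (default 64) so that
near-irrational ratios fail loudly as "non-repeating" instead of producing
absurd schedules.

Two multiplexed variants trade in-plane image quality against the sweep:
*compounding* transmits the steering angles back-to-back at full PRF, so the
volume rate is preserved but the distinct elevational positions drop by the
number of angles; *line-by-line* scanning gives each focused beam a full
sweep, dividing the volume rate by the number of lines while leaving the
sampled positions untouched.

## Acoustic model

The mirror was shown experimentally (hydrophone field maps and reflection
spectra) to act as a nearly ideal reflector, so the fold is modelled as a
rigid rotation of the scene about the hinge axis: ranges are measured from
the mirror plate centre, and the fixed 2.1-mm transducer-to-mirror path is
added to every delay. A scatterer lying on the imaging plane at scan angle
`alpha` maps to elevational offset zero with its range preserved.

Echoes are single-scattering Gaussian-enveloped tone bursts (default 3
cycles at 15.625 MHz): the transmit delay is the steered plane-wave arrival,
the receive delay the per-element Euclidean path. Elevational selectivity —
the only way the sweep direction enters a 1-D array's data — is a Gaussian
amplitude weight whose FWHM follows a Gaussian-beam law
`w(z) = w0 sqrt(1 + ((z - zf) / zR)^2)` with the lens focus at `zf = 6` mm.
The waist FWHM `w0` is a free model parameter (no numeric beamwidth is
available to copy); it defaults to 0.5 mm, and nothing quantitative is
asserted about it beyond its qualitative consequences (widths grow with
distance from the focus, so elevational resolution deteriorates with depth).
There is no attenuation, no multiple scattering and no element directivity;
these are deliberate omissions — the simulator exists to validate geometry,
scheduling and contrast, not to predict absolute pressures.

Beamforming is standard delay-and-sum on the analytic signal (FFT Hilbert
transform along time), with linear interpolation of channel samples,
all-element receive aperture and rectangular apodization by default (Hann
optional). The pixel grid defaults to half a wavelength axially and one
pitch laterally. Compounding sums the complex beamformed planes before
envelope detection.

## Scan conversion

Each beamformed plane lives in polar coordinates `(d, alpha)`; scan
conversion places a pixel at depth `d` on the plane with scan angle `alpha`
at `(y, z) = (d sin alpha, d cos alpha)`, with the lateral coordinate
unchanged. The Cartesian grid (default 0.1-mm isotropic voxels, about one
wavelength) is filled by linear interpolation *in the scan angle* and
linearly in depth. Interpolating in angle rather than in sample index
matters: the sinusoidal drive makes plane position a nonlinear function of
time, so index-linear interpolation would warp the wedge. Voxels outside the
sampled wedge carry an explicit validity mask (serialised alongside every
volume) rather than zeros, so that contrast statistics can never silently
ingest padding. Under condition 1 the same angles are visited on the up- and
down-sweep; co-located planes are averaged by default (`first`/`last` are
available and reversible).

## Calibration

The mirror parameters used for reconstruction must be measured, not assumed
— in particular the resonance and tilt range change substantially underwater.
The calibration module mirrors that workflow on synthetic data:

1. `simulate_sweep_map()` forward-models the acoustic measurement — the
   elevational beam intensity recorded at fixed depth while the mirror
   sweeps — with configurable angular noise and dropout columns;
2. `track_beam_angle()` locates the per-column intensity peak (three-point
   parabolic refinement), converts it to a scan angle through `atan2`
   against the receiver depth, and halves it; dropout columns are flagged
   missing, never interpolated;
3. `fit_sinusoid()` recovers `A`, `phi`, `gamma` by linear least squares in
   the sin/cos/constant basis. When the frequency is unknown it is scanned
   on a 1-Hz grid over the configured band (default 100-350 Hz, the band
   used for the physical frequency sweeps) and refined with
   `stats::optimize()`; the coarse-grid-then-refine structure avoids the
   divergence of a free nonlinear fit. Amplitudes are reported non-negative
   with the phase adjusted.

Asymmetric measured ranges such as +12.6/-11.3 degrees are mapped to the
symmetric model as `A = (upper + lower) / 2`, `gamma = (upper - lower) / 2`
by `range_to_kinematics()` — the only representation consistent with a pure
sinusoid. The shipped default profile nevertheless uses `gamma = 0`, since
that is what the reference configuration reports; both representations are
available and neither is asserted. `fit_voltage_angle()` (ordinary least
squares) and `resonance_peak()` (argmax with parabolic refinement, boundary
peaks returned with a warning) cover the voltage-linearity and resonance
studies.

The test suite closes the loop end-to-end: with 0.2 degrees of angular noise
over ten mirror periods, 100 seeded trials must recover `A` within 0.1
degree, `Fm` within 0.5 Hz and `gamma` within 0.1 degree at least 95 times.

## Synthetic phantoms

`make_wire_phantom()` builds parallel wires along the lateral axis —
by default four wires 3 mm apart, a dense line of point scatterers every
quarter wavelength so the wire appears continuous, with optional per-wire
depth jitter (real wire phantoms are never perfectly coplanar).
`make_cyst_phantom()` fills a block with uniformly placed scatterers whose
amplitudes are Rayleigh-distributed with unit mean — fully developed
speckle — and carves out spherical anechoic cavities (defaults at 17- and
23-mm depth). The default density of 200 scatterers/mm^3 keeps at least
roughly four scatterers per resolution cell at the default transducer
geometry, the usual rule of thumb for speckle statistics.

What the generator does *not* emulate: attenuation and aberration, sound
speed heterogeneity, reverberation, electronic noise spectra, and the real
elevational beam of a lens-focused array (replaced by the parametric
Gaussian-beam weight). Passing tests therefore demonstrate the internal
consistency and geometric accuracy of the scheduling/reconstruction chain
under an idealised acoustic model — not performance on tissue.

## Image quality metrics

`cnr()` computes `|St - Sb| / sqrt(vt + vb)` between a target and a
background region. All statistics are evaluated on linear (pre-log)
envelope intensities; the variance in the denominator is meaningless on dB
data, and since the convention is not universal the choice is stated here
prominently. Contrast is additionally reported as
`20 log10(max(St, Sb) / min(St, Sb))` — a convention choice, flagged as
such, that keeps the value positive for anechoic targets. ROIs must lie
entirely inside valid (unmasked) voxels and must not overlap; violations
are errors, not warnings. `fwhm()` measures widths between half-maximum
crossings with linear interpolation, using the highest peak when sidelobes
exist, and refuses profiles that never cross half maximum ("unresolved").

## Problem sizes and numerical choices

The package-level validation uses desk-scale configurations chosen to
exercise every code path with adequate statistics: the wire-accuracy check
runs the full 128-element aperture over one 41-plane volume; resolution and
contrast checks use reduced apertures (32-80 elements) since neither metric
depends on the lateral aperture extent being full; the contrast comparison
uses a single 1.5-mm cavity at 17-mm depth in a 8 x 6 x 6-mm speckle block
against a 13-position, 0.5-mm-step translation benchmark of the identical
phantom. Tie-breaks and degenerate inputs are handled explicitly: flat
tracking columns are missing data; monotone resonance curves return the
band edge with a warning; empty phantoms yield silent frames; schedules
shorter than one volume refuse to partition. Angles are degrees at every
interface and radians internally; the initial phase is normalised to
[0, 2 pi).

## Known limitations

* The acoustic model is kinematic: no diffraction-accurate field
  simulation, so absolute amplitudes, speckle texture fine structure and
  aberration effects are out of scope.
* Elevational resolution inherits the parametric beam model; measured
  beamwidth curves cannot be reproduced numerically, only their shape.
* The condition-1 phase clause at exotic phases is implemented literally
  and flagged; phases other than 0 are untested territory experimentally.
* No motion or flow: scenes are static within a volume.
* Reconstruction is CPU-bound R with compiled inner loops; real-time rates
  are not a goal.
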