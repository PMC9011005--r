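---
title: "qmriseq methods: sequence model, simulation, reconstruction, and mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qmriseq methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

qmriseq reproduces a scanner-free validation loop for two classic spin-echo
acquisitions: build the pulse sequence as an explicit event timeline, run it
through a Bloch-equation simulator on a numerical phantom, reconstruct the
Cartesian k-space, and fit quantitative T1/T2 maps.  This vignette records
the modeling assumptions, the parameters that matter, and the places where a
design choice had to be made.

## Sequence model

A sequence is an ordered list of blocks; a block holds at most one RF event,
one trapezoidal gradient per axis, one ADC window, and a pure delay.  RF and
ADC events live on a 1 microsecond raster, gradients on a 10 microsecond
raster, and all event times are quantized round-half-up.  RF amplitudes are
in Hz, gradients in Hz/m, everything in the object model in seconds.

Four protocol builders generate the validated acquisitions:

* `make_irse()` - inversion-recovery spin echo: per TR and slice, a 180
  degree inversion, a delay to TI, a 90 degree excitation, a refocusing
  pulse at TE/2, and a readout whose echo-center sample falls at TE.  One
  phase-encode line per excitation; slices are played sequentially within
  each TR in a seeded random order (`random_slice_order()`), mirroring how
  multi-slice interleaving is documented for this protocol family.
* `make_tse()` - turbo spin echo: one excitation followed by an
  echo train; echo k of excitation j acquires the line `table[k, j]` of a
  banded phase-encode order (`tse_pe_order()`).  The band containing the
  k-space center line is acquired at `center_echo`, so the effective TE is
  `center_echo * echo_spacing`.  The qualitative protocol states only the
  effective TE (50 ms) and the train length (4); the package defaults to
  `center_echo = 2`, hence an echo spacing of 25 ms, with both exposed as
  parameters - this keeps the stated TE at the k-space center, the standard
  TSE convention.
* `make_multiecho_tse()` - every excitation acquires a single line at all
  echoes (7 to 161 ms, 23 echoes, 7 ms apart in the mapping preset), so
  each echo index assembles a complete k-space at its own TE.
* `make_t1_protocol()` - one IRSE per inversion time in `ti_list`
  (50 to 3000 ms in the mapping preset), identical except the inversion
  delay.

Timing is never read back from metadata: `timing_report()` measures TE, TI,
TR, and echo spacing from the event timeline.  Two conventions are worth
stating because they are easy to get subtly wrong:

* The *echo center* is the instant of the k-space-center ADC sample (0-based
  index N/2; samples sit at dwell-interval centers), not the temporal middle
  of the ADC window.  For even N the two differ by half a dwell (5 us); tying
  TE to the sampled point makes the nominal TE exactly achievable and
  exactly sampled.
* The effective TE of a multi-line train is the echo at which the central
  line is acquired; for a multi-echo (same-line) train it is the first echo.

The `.seq` writer/reader use the Pulseq 1.2.1 section layout with explicit
(uncompressed) shapes; the reader also accepts 1.3.x headers and
run-length-compressed shapes.  Two columns from later Pulseq revisions are
kept because round-tripping needs them: the RF `use` code and the trapezoid
delay.  A write-read-write cycle is byte-identical for every preset.

## Bloch simulation

Each nonzero-density voxel becomes one isochromat at the voxel center
(`to_isochromats()`); magnetization evolves per isochromat in the rotating
frame.  The numerical scheme is exact piecewise closed-form evolution, not
ODE integration: between events, relaxation and gradient-induced precession
commute and are applied in one step, with gradient phase integrated
analytically over trapezoid segments; RF pulses act as instantaneous
rotations at the pulse center (hard-pulse approximation) while relaxation
runs through the full pulse duration.  There is no time-stepping error
anywhere; the only approximations are physical, not numerical:

* *Hard pulses.*  No relaxation-during-rotation or slice-profile effects.
* *Ideal spoiling.*  Residual transverse magnetization of all slices is
  zeroed at every excitation and inversion pulse, standing in for crusher
  gradients (with one isochromat per voxel there is no intra-voxel spread
  for a crusher to act on, so spoiling must be a simulator contract).
* *Ideal refocusing.*  Refocusing pulses are applied as phase-reversal
  operators on the transverse plane, `mxy -> exp(2i*phase)*Conj(mxy)`, with
  the longitudinal component untouched.  A literal 180 degree rotation also
  inverts mz between excitation and echo, perturbing the steady state by
  about `2*exp(-TR/T1)*(exp(TE/(2*T1)) - 1)` (5e-4 at T1 = 2 s, TR = 4.5 s);
  the phase-reversal operator instead makes the textbook inversion-recovery
  signal equation the *exact* steady state, which is what the mapping stage
  fits.  The exported `apply_rf()` remains the true rotation.
* *Ideal slices.*  Each slice excites an independent copy of the 2D
  phantom, selected by the RF frequency offset; no cross-talk.
* No off-resonance, B1 inhomogeneity, diffusion, or magnetization transfer.

Under these choices the steady-state IRSE echo amplitude is exactly
`|1 - 2*exp(-TI/T1) + exp(-TR/T1)| * exp(-TE/T2)` per unit proton density
(the simulator reproduces it to 1e-15 on single isochromats), and one dummy
cycle (`n_dummy = 1`, the builder default) reaches the steady state exactly,
because mz is pinned to zero after each excitation.

Frequency encoding spans the full-FOV Nyquist rate (`dwell * gx = 1/FOV` per
sample); with the phantom rasterized at the matrix resolution the simulated
k-space equals the discrete Fourier transform of the proton-density map, so
noiseless matched-resolution reconstruction is exact to rounding.  This
"encoding oracle" is tested against a directly evaluated DFT.

## Reconstruction

`reconstruct()` chains acquisition-order correction (`sort_kspace()`,
splitting echoes into separate k-spaces when lines repeat across echoes and
merging banded trains otherwise), optional Hamming apodization
(`hamming_2d()`, window size equal to the matrix size), a centered inverse
FFT per channel, sum-of-squares channel combination, and joint [0,1]
normalization across all slices or contrasts (joint, not per-image, so the
inter-contrast ratios that the mapping stage fits are preserved).  The
k-space and image grids are both center-indexed (index N/2, 0-based, for
even N); half-voxel offsets of the coordinate convention are compensated
with linear phase ramps before the IFFT, which matters only for phase, not
magnitude.

Apodization defaults to on for the quantitative workflows, matching the
documented mapping pipeline, and off for qualitative ones.  The *recovery
experiments* in the acceptance suite run unapodized: simulation at matched
phantom/matrix resolution is an exact discrete encoding with no truncation
ringing, so a Hamming window would only widen the point-spread function of
the small spheres without suppressing any artifact.  Ringing suppression is
demonstrated separately on an oversampled phantom (phantom rasterized at
twice the matrix resolution), where apodization measurably reduces the
Gibbs overshoot on the disk edge.

## Phantoms and noise

`make_grid_phantom()` builds a uniform disk crossed by zero-density grid
lines (a resolution target); `make_plane_phantom()` rasterizes a disk
carrying ten spheres on a ring.  The sphere layouts are *synthetic* stand-ins
for a physical calibration plate, not reproductions of one; the defaults are
chosen once to bracket the protocols' contrast ranges - T1 log-spaced over 0.05-2.0 s (TI range
50-3000 ms) and T2 log-spaced over 0.02-0.3 s (TE range 7-161 ms) - inside
a water-like background disk.  Recovery is therefore judged against the
generator's own ground truth, not against a physical phantom.

`add_noise()` adds i.i.d. complex Gaussian noise per k-space sample.  The
SNR convention is image-domain and voxel-wise: `noise_sigma_for_snr()`
returns the k-space sigma such that the peak magnitude of the noiseless
reconstruction divided by the per-voxel image-noise standard deviation
equals the requested SNR (for an N x N Cartesian IFFT, image noise is
k-space sigma / N).  Referencing sigma to the k-space center sample instead
would make the effective noise level depend on the phantom's voxel count,
which is not a property of the acquisition.

What the generator deliberately does not emulate: coil-array geometry
(sensitivities default to one uniform channel), B0/B1 field maps, chemical
shift, partial volume below the voxel grid, physiological noise, and
stimulated-echo pathways.  Passing tests therefore validate the sequence
timing, the encoding chain, and the estimator - not robustness to scanner
non-idealities.

## Parameter mapping

`map_fit()` fits voxel-wise, inside a programmatic disk mask (default:
voxels whose peak signal exceeds 10 percent of the maximum - a stand-in for
the manually drawn phantom ROI of the original workflow):

* T1: magnitude inversion-recovery model
  `|A*(1 - 2*exp(-TI/T1) + exp(-TR/T1)) + B|`, T1 bounded to [1 ms, 10 s].
  The magnitude model has narrow local minima whenever the signal null falls
  between sampled TIs, and Levenberg-Marquardt basins there are razor-thin
  (moving a start from 0.3607 to 0.3610 flips the answer).  The fitter
  therefore uses a deterministic global initializer: candidate polarity
  restorations (first k points negated, k = 0..n) solved linearly in (A, B)
  on a 150-point log-spaced T1 grid, followed by one bounded LM polish of
  the magnitude model, keeping the polish only if it lowers the cost.
  Degenerate grid columns (model nearly constant, collinear with the
  offset) are excluded to avoid catastrophic cancellation in the normal
  equations.
* T2: `A*exp(-TE/T2) + B`, initialized from a log-linear regression of the
  offset-corrected decay; `echo_subset = 5:23` reproduces the later-echoes
  mapping variant.

Both fitters return `converged = FALSE` rather than erroring on degenerate
input (all-zero or non-decaying signals, or estimates pinned at the
bounds).  `roi_stats()` summarizes converged voxels per sphere over
interior ROIs (spheres eroded by one voxel, `sphere_rois()`).

### A known estimation limit

At desk scale (32 x 32, interior ROIs of ~8 voxels) and image SNR 50, the
three-parameter offset-exponential T2 fit over echoes 5-23 (TE 35-161 ms)
is ill-conditioned for long T2: the data span less than one time constant,
so (T2, A, B) are nearly collinear.  The Cramer-Rao bound on the per-sphere
median error is 7-39 percent across the layout's T2 range - no estimator of
this model can reach 5 percent there, and the acceptance suite records that
gap honestly (measured worst-sphere errors of 16-54 percent across noise
seeds).  The noiseless fits recover T2 to better than 0.1 percent, and the
T1 recovery meets its bounds both noiseless (< 0.1 percent) and at SNR 50
(1.7-2.6 percent worst sphere).  Practical remedies - larger ROIs, more
echoes beyond 161 ms, or fixing B - all change the stated protocol or
model, so they are documented rather than applied.

## Metrics and RF power

`psnr()` is `10*log10(R^2/MSE)` on [0,1]-normalized images with a 300 dB
sentinel for identical inputs.  `ssim()` implements the original SSIM
configuration - 11-point Gaussian window (sigma 1.5), C1 = 1e-4, C2 = 9e-4,
weighted covariances, border of half a window excluded - and matches an
independent reference implementation to 1e-10 on fixtures.
`rf_power_summary()` reports the time-averaged squared RF amplitude (Hz^2)
and duty cycle in relative units; absolute W/kg SAR needs an
electromagnetic body model that is out of scope, so only the 70 kg
reference-mass bookkeeping is kept.

## Problem sizes

The test and acceptance runs use matrix 8-16 for oracles, 32 for the
end-to-end recovery and counting experiments (scale 4-8 of the full
128/256 protocols), and 64 for the encoding-oracle reconstruction; the full
test suite completes in about a minute.  Full-size runs are available
through `run_experiment(..., scale = 1)` and scale roughly with the voxel
count times the readout count.
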