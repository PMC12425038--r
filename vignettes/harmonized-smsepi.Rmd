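---
title: "A harmonized SMS-EPI fMRI protocol: sequence model, simulation, reconstruction and QA"
author: "smsepi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A harmonized SMS-EPI fMRI protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why a vendor-neutral pipeline

Multi-site fMRI studies suffer when each scanner runs its own opaque
acquisition and reconstruction software: differences in slice profiles,
fat suppression, parallel-imaging algorithms and even flip-angle
calibration masquerade as biological variance. The remedy implemented
here is to make every software-defined element explicit: the pulse
sequence is expressed in a vendor-neutral block/event representation
(serializable to a Pulseq-style `.seq` text file), and the image
reconstruction operates on raw multi-coil k-space in a fully specified
way, so the whole chain from RF waveform to 4-D NIfTI is reproducible
bit for bit.

The package covers five layers:

1. **Sequence model** (`pulseSequence`, `addBlock`, `validateSequence`,
   `writeSeq`/`readSeq`, `computeKspace`): sequences are ordered,
   non-overlapping blocks holding at most one RF pulse, one gradient per
   axis and one ADC window. Gradients must be continuous across block
   boundaries (tolerance `1e-6 * maxGrad`); every event is checked
   against a hardware profile (amplitudes, slew rates, raster times,
   dead times). A design is portable to a scanner whenever its profile
   is weaker than the scanner's capabilities.
2. **RF design** (`designSlrPulse`, `makeFatsatPulse`,
   `synthesizeSmsPulse`, `rfSpoilingPhase`, `blochSimulate`):
   Shinnar-Le Roux pulses, multiband synthesis, and a rotation-operator
   Bloch simulator used throughout the tests as the excitation oracle.
3. **Protocol assembly** (`designEpiReadout`, `buildProtocol`,
   `protocolReport`): the ABCD-matched SMS-EPI protocol.
4. **Simulation** (`makeBallPhantom`, `makeCoilMaps`,
   `simulateAcquisition`): a forward model producing multi-coil raw
   k-space plus single-band calibration data.
5. **Reconstruction and QA** (`reconstructTimeseries` and the
   `runQa` battery).

## The acquisition protocol

Defaults follow the published ABCD-style target: 2.4 mm isotropic
voxels, 90 x 90 matrix, 60 contiguous slices, SMS factor 6, TR 0.8 s,
partial Fourier 0.8, FOV 21.6 x 21.6 x 14.4 cm. Each shot excites 6
slices 24 mm apart; 10 shots tile the slab per TR (80 ms per shot). A
shot consists of:

* **Fat saturation**: a minimum-phase SLR saturation pulse centered at
  -3.45 ppm (about -441 Hz at 3 T), flip 90 degrees, followed in-block
  by a slice-axis spoiler of at least 4 pi dephasing per slice
  thickness. The bandwidth is 70% of the fat-water separation (about
  308 Hz, 6.5 ms at time-bandwidth 2): wide enough transition for a
  practical pulse length, narrow enough that the Bloch-simulated water
  magnetization stays above 0.95 (asserted in the tests).
* **Multiband excitation**: a linear-phase SLR base pulse (default
  3.2 ms, time-bandwidth 4, flip 52 degrees) replicated at the six band
  frequencies with per-band phase offsets from the stored peak-reducing
  schedule; for band counts without a stored entry a bounded
  random-restart minimization of the synthesized peak is used. Peak
  amplitude with the optimized phases is far below the all-equal-phase
  synthesis (roughly the square-root-of-bands ideal), which is what the
  RF amplitude budget relies on. The excitation flip angle and pulse
  duration are package defaults - the printed protocol does not pin
  them - and are therefore *reported* by `protocolReport`, never
  asserted.
* **Navigators**: three readout echoes with phase-encode blips disabled
  (ky = 0), alternating polarity, from which the odd/even phase error is
  estimated once per dataset (from the reference segment) and applied to
  all volumes.
* **CAIPI-blipped ramp-sampled EPI train**: 72 echoes (the late 80% of
  the 90 ky lines; the early lines are omitted, i.e. an asymmetric
  echo). Readout lobes are triangles whose exact area is nx/FOV;
  phase-encode blips step ky by exactly 1/FOV; slice-axis blips cycle kz
  over three values spaced 1/(3 x band separation) to realize the
  FOV/3 interslice shift. Blips are shallow triangles filling a short
  dedicated block between echoes, so the ADC windows see a constant ky
  and kz - this keeps the reconstruction model exact.
* **Crusher and TR fill**: an end-of-shot slice-axis crusher and a delay
  block padding the shot to exactly TR / 10, so each volume lasts
  exactly one TR (an invariant the tests check to 1e-12 s).

A single-band 2D reference segment (one EPI shot per slice, identical
readout, no CAIPI blips, interleaved slice order) precedes the SMS
segment and provides ghost calibration, slice-GRAPPA calibration and
coil maps. Two dummy SMS volumes precede the stored time series. All
excitations and receivers follow the quadratic RF-spoiling schedule with
the community-standard 117-degree increment.

### CAIPI phase referencing

The kz blip pattern gives band *b* (at slice offset `b * bandSep` within
its group) the per-line phase `-2 pi kz(e) z_b`. Referenced to absolute
slice positions this phase is *not* an exact linear ramp across ky (the
group's center offset contributes a residual with period 3), which would
break the shift-invariance that slice-GRAPPA kernels assume. The
package therefore references the receiver phase to each group's first
band - standard practice on scanners - so the residual inter-band phase
is an exactly linear ramp and band *b* aliases as a clean
`(b-1) * FOV / 3` shift. The simulator, the `.seq` ADC phase offsets
and the reconstruction all share this convention.

### PNS-derated readout

The readout slew rate is derated iteratively (4% steps of the hardware
slew) until the predicted peripheral nerve stimulation of one shot's
exact gradient waveforms stays below `pnsDerate` (default 80%) of the
stimulation limit. Prediction uses the nerve impulse-response
convolution model: each axis' slew rate (T/m/s) is convolved with the
normalized response `c/(c+t)^2` and axes combine root-sum-of-squares;
100% corresponds to a sustained slew at the rheobase. Defaults are
chronaxie 334 us and an effective gradient-coil rheobase of 70 T/m/s.
The rheobase deserves a comment: stimulation thresholds expressed in
gradient units depend strongly on coil geometry, and the classical
whole-body electric-field-derived value (about 20 T/m/s) is far below
what actual gradient coils reach - with it, no EPI train dense enough
for a 0.8 s TR at this resolution could pass an 80% bound. The
70 T/m/s default represents a modern whole-body gradient set, makes the
80% design ceiling and the printed TR simultaneously satisfiable, and
is configurable (`pnsParams`); every report states the parameters used.
With the defaults the shipped protocol derates to half the hardware
slew and predicts a 78% peak. A SAFE-style three-branch low-pass
cascade on the rectified slew is provided as a second, independently
implemented model; its threshold default is calibrated so the two
models agree on EPI-like alternating trains (the rectified cascade sees
a sustained slew where the signed convolution partially cancels), and a
test holds them within 25% on the protocol's train.

Non-readout "service" gradients (spoilers, crushers, rephasers,
prewinders) use a moderate fixed slew (45 T/m/s) so their isolated
transients stay well below the limit.

## The forward model

`simulateAcquisition` evaluates a discrete-voxel DFT of
phantom x coil-sensitivity at the exact trajectory points: per-sample kx
(including ramp samples, computed analytically from the triangle
geometry), per-echo ky, per-(echo, band) CAIPI phase. This choice - no
continuous-object analytic transform, no intra-echo kz motion - makes
the noiseless reconstruction oracle exact: with SMS 1, full Fourier and
flat-top-only sampling the chain inverts to machine precision, which the
tests assert. T2* decay along the train, motion and B0 inhomogeneity
are deliberately absent (extension points); passing tests therefore
certify the *encoding and unaliasing algebra*, not robustness to those
physical effects.

Instabilities that the QA battery must detect are modeled: complex
Gaussian noise per sample and coil (`sigma` is the SD of the real and
imaginary parts), a constant/linear odd-echo phase error (the N/2 ghost
mechanism), and a multiplicative linear drift across volumes. A single
seed fixes all randomness; identical seeds give bit-identical raw data.

Coil maps are Gaussian lobes on a ring with mild random polynomial and
phase modulation, normalized to unit root-sum-of-squares everywhere;
the ball phantom has a supersampled anti-aliased boundary so its
integrated volume matches the analytic sphere to better than 1%.

## The reconstruction chain

Per volume and shot, deterministically:

1. **Odd/even phase correction.** Opposite-polarity navigators sample
   mirrored kx positions, so odd x conj(reversed even) isolates the
   inter-polarity phase; a magnitude-weighted linear fit over shots,
   coils and pairs gives `theta0, theta1`, estimated once from the
   reference segment and applied to all volumes.
2. **Ramp regridding** by least squares: the non-uniform samples of an
   echo are explained by an nx-voxel object and re-evaluated on the
   uniform kx grid (`C %*% pinv(B)`), exact for noiseless
   support-limited data; odd-polarity echoes get their own mirrored
   operator.
3. **Unaliasing.** *Slice GRAPPA*: per group and band, 5 x 5 x coils
   kernels are fit by Tikhonov-regularized least squares on a synthetic
   collapse of the phased single-band calibration; applied by k-space
   convolution, then the CAIPI phase is removed per band. *SENSE*: in
   image space, the periodic per-line phase decomposes into
   FOV/caipiShift-shifted copies with computable weights, and a joint
   linear system over bands x shift cosets (3D SENSE in effect) is
   solved per voxel by SVD pseudoinverse, with the g-factor map emitted
   and rank-deficient voxels flagged and zero-filled.
4. **Partial Fourier zero-fill** (deliberately plain; homodyne is out of
   scope), unitary inverse FFT, root-sum-of-squares coil combination,
   and a 1/sqrt(nx ny) scale that makes the simulate-reconstruct chain
   unit-gain. Dummy volumes are dropped; the result is written as
   NIfTI-1 with correct voxel size and TR.

SENSE coil maps default to ratio maps (coil image / RSS) from the
reference segment; supplying the simulator's true maps makes the
noiseless SENSE reconstruction exact to machine precision, which the
tests use to pin the coset algebra. Zero-filled partial Fourier blurs
edges (the truncated-Fourier point-spread broadening is itself verified
against the analytic Dirichlet-kernel oracle), so phantom-edge error in
a partial-Fourier reconstruction is physics, not an unaliasing defect;
the tight end-to-end oracles run at full ky coverage.

## QA metrics (fBIRN/ABCD conventions)

On the center slice with a center-of-mass-centered square ROI (21 x 21
for matrices of 64 and larger): signal = temporal mean; fluctuation
noise = SD of residuals after 2nd-order polynomial detrending per voxel;
SFNR = ROI mean of mean/SD; SNR = ROI mean signal over the odd/even
volume-sum difference noise estimate; RMS residual percent and a
quadratic-fit drift percent; the Weisskoff plot F(N) for N = 1..21 with
RDC = F(1)/F(Nmax) clipped to [1, Nmax]; per-axis Gaussian-equivalent
FWHM from lag-1 autocorrelation of the detrended residuals
(`FWHM = dx sqrt(-2 ln 2 / ln r1)`, sub-voxel floor flagged when
r1 <= 0); and the ghost-to-signal ratio with the ghost ROI at FOV/2
along the phase encode and a four-corner background. The report labels
these conventions so numbers are not conflated with pipelines using
different ROI rules. Constructed-ground-truth recoveries (SFNR =
mean/sigma within 5% at 200 time points, RDC at both extremes, a
tenfold ghost reduction by the phase correction on seeded injections)
are part of the acceptance tests.

## Numerical choices and conventions

* Gradients are gamma-normalized (Hz/m) with gamma = 42.576 MHz/T;
  converters `mTmToHz`/`slewToHz` sit at the user boundary.
* Rasters: RF 1 us, gradient 10 us, ADC 100 ns, block duration 10 us.
* `.seq` dialect: v1.4 sections with run-length-compressed shapes;
  arbitrary-gradient entries carry explicit first/last boundary samples;
  event libraries are content-deduplicated, and serialization is
  byte-deterministic. Files without a signature section are accepted;
  unknown sections are preserved and reported.
* Trapezoid areas are met exactly after raster rounding (amplitude is
  solved last), so ky and kz steps are exact by construction.
* k-space origin resets at the RF peak sample; for a multiband
  waveform the peak can sit a few samples from the base-envelope
  isodelay, leaving a through-slice kz offset below one CAIPI blip.
* FFTs are unitary and centered (DC at index n/2, 0-based); the
  reduced test geometry uses a FOV/4 CAIPI shift because the coset
  solve requires the shift to divide the 32-line matrix (the full-size
  90-line protocol uses FOV/3).
* SLR design: Parks-McClellan equiripple beta filter at 256 hard
  pulses, minimum-phase variants by cepstral spectral factorization,
  inverse-SLR recursion, then resampling onto the hardware raster.
* Problem sizes: unit tests run on a 32 x 32 x 12, SMS 3, 6-coil
  geometry; the acceptance suite additionally simulates and
  reconstructs five volumes of the full 90 x 90 x 60, SMS 6, 8-coil
  protocol.

## Known limitations

No in-plane (ky) parallel-imaging undersampling - the protocol
accelerates through SMS only. No homodyne/POCS partial Fourier, no
iterative or regularized reconstruction, no distortion/motion
correction, no DICOM, no absolute SAR (only relative RF energy against
a named 1 ms 180-degree reference pulse). The Bloch simulator ignores
relaxation during RF. The PNS percentages are only as meaningful as
the rheobase they are referenced to; for deployment decisions the
vendor's coil-specific model is authoritative. Real multi-coil data
differ from the simulator in coil geometry, B0/B1 nonuniformity and
physiological noise, so QA values from real phantoms should be compared
against scanner-specific normative ranges rather than the synthetic
values produced here.
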