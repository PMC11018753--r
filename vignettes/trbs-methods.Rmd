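---
title: "Time-resolved Brillouin scattering: simulation and depth-resolved analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved Brillouin scattering: simulation and depth-resolved analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbs)
```

## The measurement being modelled

A fibre-tip opto-acoustic transducer absorbs a pump laser pulse and launches
a coherent longitudinal acoustic phonon into the specimen. A time-delayed
probe pulse partially reflects from the transducer and partially Brillouin
scatters from the propagating acoustic wavefront; the two reflections
interfere, so the recorded reflectivity oscillates as the path difference
grows. With optical wavenumber $k = 2\pi n/\lambda_{probe}$ and wavefront
depth $z = vt$, the interference phase is $\Delta\phi = 2kvt$ and the
oscillation frequency is the Brillouin frequency shift at normal incidence,

$$f_B = \frac{2 n v}{\lambda_{probe}}.$$

Because the time axis of the trace *is* the depth axis (through $z = vt$),
local changes in sound velocity -- and hence stiffness -- appear as changes
in the instantaneous frequency of the signal. That is what makes
depth-resolved elastography possible from a single trace, without confocal
scanning. When density $\rho$ and attenuation $\alpha$ are known, the
complex longitudinal modulus follows as

$$M^*(f_B) = M' + iM'' = v^2\rho + i\,\frac{\alpha\rho v^3}{\pi f_B}.$$

At sub-micrometre scales the refractive index and density of tissue
constituents are generally uncharacterised, so the package (like the
instrument protocol it models) reports the *relative* Brillouin shift
$\Delta f_B(z) = f_B(z) - f_B^0(z)$ against a control-medium reference and
uses $100\,\Delta f_B / f_B^0$ as a velocity-proxy percent stiffness.

## The signal model

`simulate_trace()` composes, on the acquisition time base (0--12.5 ns,
3 ps sampling by default):

1. a **coincidence peak** at $t = 0$: a narrow Gaussian (10 ps FWHM by
   default). The instrument literature names the component but not its
   shape; any narrow pulse confined to the exclusion window behaves
   identically downstream.
2. a **thermal background**: one decaying exponential (5 ns default). Again
   only "slow-decaying" is physically constrained; the polynomial detrend
   removes any smooth variant.
3. the **Brillouin oscillation**
   $B(t) = s(z)\, e^{-\int_0^{z(t)}\alpha\,dz'} \cos\phi(t)$ with
   $\phi(t) = \int_0^t 2\pi f_B(z(t'))\,dt'$, where the wavefront depth
   $z(t)$ advances at the local sound velocity. The phase is accumulated
   exactly (piecewise linearly) across layer boundaries, so it is
   continuous and the synthetic signal has no spurious broadband
   transients at interfaces.
4. **additive white Gaussian noise**, optionally averaged over `n_average`
   repeat acquisitions.

Acoustic transmission across interfaces is treated as total: no partial
reflections or echoes. This matches the single-propagating-wavefront
assumption behind the $f_B = 2nv/\lambda$ analysis; per-medium
`scatter_strength` models photoelastic amplitude differences instead.

### Generator defaults and why

| parameter | default | rationale |
|---|---|---|
| probe wavelength | 830 nm | near-infrared single-mode fibre probe |
| sweep / sampling | 12.5 ns / 3 ps | asynchronous-optical-sampling time base |
| control medium | water/PBS: n 1.33, v 1497 m/s, rho 1000 kg/m^3 | literature values at room temperature |
| water attenuation | 5e5 1/m | classical f^2 scaling of water's acoustic absorption evaluated near 4.8 GHz; gives the observed ~6 um usable depth |
| tissue index / density | 1.38 / 1200 kg/m^3 | standard soft-tissue constants |
| noise sigma | 0.1 per acquisition | calibrated so single-trace ridge scatter at the 520 nm window lies in the tens-of-MHz range across the usable depth, matching reported instrument precision |
| cuticle layers | +300, +60, +300, -200 MHz; 320/400/320/1500 nm | nematode cuticle stack: cortical, medial, basal, hypodermis; strut variant +600 MHz |

The cuticle phantom derives layer sound velocities by inverting the
Brillouin relation at the tissue index around the control baseline, so each
layer produces its configured relative shift exactly.

What the generator does *not* emulate: acoustic impedance-mismatch echoes,
laser intensity noise (noise is purely additive), refractive-index
dispersion, temperature drift within a single trace (drift enters only
through the reference mechanism), and lateral acoustic diffraction (each
lateral position is an independent 1D column). Passing recovery tests on
synthetic scans therefore demonstrates the correctness and calibration of
the *analysis chain*, not robustness to every instrumental artefact.

## The analysis chain

**Detrending.** Samples before a 50 ps coincidence-exclusion window are
dropped and a least-squares polynomial (order 5 by default) is subtracted.
The order is unstated in the instrument literature; order 5 removes any
plausible smooth background over 12.5 ns while leaving GHz oscillations
untouched (a >=10-period cosine survives with <2% amplitude error).

**Whole-trace shift.** The FFT magnitude peak inside a search band,
refined by three-point parabolic interpolation on the log-magnitude.
Sub-bin refinement is essential: the raw $1/T$ grid at 12.5 ns is 80 MHz,
far coarser than the few-MHz precision the measurement supports. Ties
between equal peaks resolve to the lower frequency, for determinism.

**Depth resolution.** The complex Morlet wavelet

$$\Psi(f, t) = \frac{1}{\sqrt{\pi f_b}}\exp\!\left(2\pi i f t - \frac{t^2}{f_b}\right)$$

is correlated with the trace over a frequency grid, giving coefficients
$C(f,t)$. The transform is evaluated in the Fourier domain, where the
Morlet kernel is exactly the unit-peak Gaussian
$e^{-\pi^2 f_b(\nu - f)^2}$ -- no wavelet truncation error. The analysis
window is parameterised by its depth FWHM $z_{win}$, with
$f_b = (z_{win}/v_{ref})^2/(4\ln 2)$; 520 nm is the sub-micrometre-layer
setting and 1.28 um the whole-cell setting (nominal axial resolutions
$z_{win}/2$: 260 nm and 640 nm). A window width stated in acoustic
wavelengths $N_\lambda$ is accepted and converted as
$z_{win} = N_\lambda\,\lambda_{probe}/2n$. The per-depth ridge is the grid
argmax refined parabolically on the log-magnitude; samples within one
window FWHM of either trace end are flagged invalid rather than
zero-padded, and the usable depth is capped at 6 um by default.

**Reference compensation.** The depth-resolved reference $f_B^0(z)$ is the
pointwise mean ridge of control-medium acquisitions (mean, not median --
the estimator is linear so averaging commutes with the noise model; ~100
acquisitions typical, 50 used in the validation studies below). Since slow
thermo-optic/thermo-acoustic drifts enter specimen and reference alike,
$\Delta f_B = f_B - f_B^0$ cancels them exactly.

**Depth mapping.** $z = v_{med}t$ with the control velocity throughout, the
convention of the surface-position relation; an optional two-pass mode
re-maps depth with ridge-derived velocities via left-Riemann accumulation.

## Surface profilometry

The amplitude channel is the wavelet magnitude at the grid frequency
nearest $f_B^0$, averaged over one grid step either side. After dividing
out control-medium attenuation ($\hat A\hat C$ with
$A = e^{\alpha_{med} v_{med} t}$, each factor normalised by its own
maximum), the surface is the depth where the normalised channel falls
through $\tfrac12(1 + \hat C'_{min})$ on its descending roll-off,
interpolated linearly.

One refinement proved necessary: beyond the surface the wavefront travels
at the *specimen* velocity, so the control-matched compensation
over- or under-corrects and the channel keeps drifting after the
transition. Taking $\hat C'_{min}$ at the far end of the record then sets
the half-level too low and biases the crossing late -- by up to ~200 nm at
shallow stand-offs in the step-phantom studies. The default estimator
therefore re-measures the roll-off floor in a one-window-wide band just
past the first-pass crossing and re-solves the crossing; step-phantom
surface errors drop below ~90 nm, comfortably within half an acoustic
wavelength (156 nm). The amplitude-derivative centroid variant is
available behind `method = "centroid"`. Detections with total contrast
below 0.2 are reported as "no specimen in range".

## Quantifying sub-window layers

With a 520 nm window, 320--400 nm layers are thinner than the analysis
resolution cell: the ridge through them is, to good approximation, the
true piecewise-constant $\Delta f_B(z)$ smoothed by the wavelet's Gaussian
amplitude envelope. Reading plateau values straight off the ridge then
underestimates thin-layer contrast (the medial dip, for instance, bottoms
out near +150 MHz for a +60 MHz layer). `layer_plateaus()` therefore
treats the ridge as a linear mixture of per-region *window-coverage
kernels* (Gaussian-envelope integrals over each region, boundaries mapped
to apparent depth) and solves for the per-layer shifts by least squares,
weighted by ridge amplitude squared -- an inverse-variance weighting, since
frequency-estimate variance scales with inverse SNR squared, which also
suppresses the low-SNR deep samples. Because region boundaries depend on
the layer velocities, the geometry is refined once from first-pass
estimates.

The smoothing model is an approximation (the argmax of a coherent mixture
is not exactly its centroid), leaving a residual bias of a few to tens of
MHz. The estimator removes it by parametric bootstrap: synthetic traces
are regenerated at the estimated layer values with the same acquisition
settings, the estimator is re-applied, and its own offset on the model is
subtracted (`nboot = 6` replicates by default). In the 20-seed validation
study this brings all five layer types (including the +600 MHz strut
variant) within two standard errors of their configured values.

Layer *thickness* is read from Gaussian fits to isolated peaks in
$\Delta f_B(z)$ (`fit_layers()`), reported as FWHM. A layer of true width
$w$ observed through a window of FWHM $z_{win}$ fits to approximately
$\sqrt{w^2 + z_{win}^2}$ (slightly less in practice, since a top-hat
convolved with a Gaussian is not Gaussian): a 320 nm basal layer under the
520 nm window fits to ~570 nm, within 15% of the quadrature expectation.

## Numerical and design choices

- **Internal units are SI** (s, Hz, m, Pa) everywhere; conversions happen
  only at presentation (tidiers, plots, CLI).
- **Percent stiffness** uses the velocity proxy $\Delta f_B/f_B^0$, not the
  modulus ratio; the modulus route stays available via
  `longitudinal_modulus()`.
- **Attenuation estimation** fits a straight line to the log of the
  quadrature (analytic-signal) envelope, averaged across reference traces,
  over 0.2--4 um -- clear of detrending edge effects and still within
  usable signal. The analytic-signal primitive is implemented in-package
  (FFT half-spectrum method).
- **Ties and degenerate inputs**: spectral ties resolve to the lower
  frequency; all-zero ridge columns are marked missing rather than
  interpolated; multi-crossing roll-offs take the first descending
  crossing with quality halved; non-decaying envelopes return zero
  attenuation with a warning.
- **Binning** for segmentation maps uses half-open intervals
  $[e_i, e_{i+1})$ with the top edge closed.
- **Determinism**: every stochastic step takes a seed; lateral scans draw
  per-position sub-streams from one parent seed, so scans are reproducible
  bit-exactly while positions stay independent.
- **Scan container**: a directory bundle of CSV payloads with JSON
  sidecars (raw traces, configs, ground truth, analysed voxels, surfaces,
  provenance), readable by any toolchain; lateral maps export to 32-bit
  float TIFF and CSV.

## Validation study sizes

The recovery studies shipped in the test suite and acceptance script use:
20 seeds for the cuticle plateau and basal-FWHM studies (with 4-fold
acquisition averaging per trace, emulating on-instrument voxel averaging),
a 50-trace reference, 50 seeds for the precision-versus-depth study, five
stand-offs spanning 1--5 um for profilometry, and a 4.3--5.7 GHz analysis
grid in 5 MHz steps. These sizes give standard errors comfortably below
the effects being tested while keeping a full run in the tens of seconds.

## Known limitations

- The mixture model behind `layer_plateaus()` needs the layer geometry
  (boundaries) as input; it quantifies known stacks rather than blindly
  segmenting unknown ones. Geometry errors propagate into the recovered
  shifts.
- Ridge precision degrades roughly exponentially with depth under
  attenuation; beyond ~5 um at water-like attenuation the ridge is
  noise-dominated at realistic noise levels.
- The simulator's no-echo assumption means strongly mismatched interfaces
  (e.g. glass substrates) are kinematically but not amplitudically
  faithful.
- Two-pass depth re-mapping trusts the ridge; in low-SNR regions it can
  distort the deep axis and is off by default.
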