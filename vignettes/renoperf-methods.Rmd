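---
title: "Models and methods behind renoperf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind renoperf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`renoperf` quantifies what happens to a kidney's perfusion and to an
injected dose when drug-carrier microcapsules are administered through the
renal artery. This vignette explains the models behind each module, the
parameters that matter, what the synthetic generators do and do not
emulate, and the numerical decisions taken where the underlying
experimental protocol leaves the choice open.

## 1. Dynamic speckle: the generator's physics

### Field model

`simulate_speckle_movie()` builds each instantaneous speckle field as a
complex circular-Gaussian process: independent complex-normal coefficients
on the points of a circular pupil in the 2-D Fourier plane, transformed to
the image plane. This is the textbook model of fully developed speckle:
single-field intensity is negative-exponentially distributed, so the
spatial contrast $K = \sigma_I / \mu_I$ of one frozen field is 1.

The pupil radius sets the speckle grain. We place the first zero of the
field autocorrelation (the Airy radius, the conventional "speckle size")
at `speckle_grain_px` pixels; the default of 2 px is the Nyquist-sampling
choice that LSCI instruments tune their lens aperture for. The field is
band-limited on the grid, so grid samples are exact point samples of the
continuous field and spatial statistics are unbiased.

### Temporal evolution and exposure integration

Moving scatterers decorrelate the field. We evolve the pupil coefficients
as a first-order autoregressive process,
$a(t+\Delta t) = \rho\, a(t) + \sqrt{1-\rho^2}\, \xi$, with
$\rho = e^{-\Delta t / \tau_c}$, which gives an exponential field
autocorrelation $g_1(t) = e^{-t/\tau_c}$. A camera frame integrates the
intensity over the exposure $T$; we approximate the integral by the mean
of `n_subframes` instantaneous fields spread across the exposure, and keep
evolving the field through the dead time between exposures so consecutive
frames are correctly correlated.

For this model the time-integrated contrast obeys the classic
finite-exposure curve
$$K^2 \;=\; \beta\,\frac{e^{-2x} - 1 + 2x}{2x^2},
  \qquad x = T/\tau_c,$$
which doubles as the analytic oracle of the test suite (checked both
against the closed form and against numerical quadrature of
$2\int_0^1 (1-u)\,|g_1(xu)|^2\,du$). The discrete sub-frame average biases
$K^2$ upward by $O(1/n)$; the automatic rule
`n_subframes = max(8, ceiling(8 T / tau_c))` (capped at 256) keeps that
bias below about 2% up to $x = 10$, which is why it is the default. A
static field (`tau_c_ms = Inf`) needs a single sub-frame.

### Coherence factor

The factor $\beta \in (0,1]$ models coherence losses (polarization, pixel
integration). It is applied as a variance scaling about the mean,
$I \mapsto \sqrt{\beta}(I - \bar I) + \bar I$, which leaves intensities
non-negative for fully developed speckle and multiplies measured $K^2$ by
exactly $\beta$. The default is the ideal $\beta = 1$: the generators are
meant to be tight oracles, so no detector noise is added by default
either (no shot noise, no read noise).

### Flow mapping

Relative flow enters only through
$\tau_c = \tau_{c,\mathrm{baseline}} / \mathrm{flow}$, the standard
single-scattering LSCI assumption that decorrelation rate is proportional
to scatterer speed. LSCI is treated throughout as a *relative* modality:
nothing in the package converts the flow index into a velocity.

## 2. The LSCI processing chain

`lsci_pipeline()` fixes the processing order as: per-frame sliding-window
contrast → average of 25 contrast frames → conversion to flow index →
Gaussian smoothing → ROI statistics. The acquisition narrative that the
chain mirrors lists the steps in this order but does not state whether
conversion precedes smoothing; we convert first so that the smoothing acts
on the quantity being reported, and we document rather than assert that
choice.

* **Contrast window.** 5 × 5 (odd sizes only), sample ($n-1$) standard
  deviation — the estimator convention is unstated upstream, so the
  unbiased-variance form is used in both the window statistic and the ROI
  SD. Edges are handled by symmetric (edge-duplicating) reflective
  padding so contrast maps keep the frame geometry. Windows whose mean
  falls below a guard of $10^{-12} \times$ the frame maximum are masked;
  an all-zero frame yields a fully masked map and a warning.
* **Flow index.** $1/K^2$, the conventional choice; whether the original
  instrument reported $1/K$, $1/K^2$ or contrast itself is not stated in
  the protocol we mirror, so only $1/K^2$ is implemented. Zero-contrast
  pixels cannot be inverted; they are masked, counted and reported.
  Percent-of-baseline is computed on the flow index, not on $K$.
* **Smoothing.** Separable Gaussian, default $\sigma = 7$ px, kernel
  truncated at $4\sigma$, reflective boundaries — with a unit-sum kernel
  this conserves the total of an unmasked map to machine precision (the
  suite checks $10^{-6}$ relative). Masked pixels are handled by
  normalized convolution so they neither leak zeros nor receive values.
* **ROI.** 1-based top-left corner plus extents, default 200 × 200. ROI
  placement on a real kidney image was a manual step in the original
  workflow; here it must always be supplied explicitly for frames smaller
  than the default.
* **Classification.** With threshold $t$ (default 20%), a series is
  physiological if every timepoint is at least $(100-t)\%$ of baseline,
  reversible if only intermediate points fall below, irreversible if the
  final point is below. The boundary is inclusive: exactly 80% of
  baseline still counts as normal, because the rule's premise is that
  changes *up to* 20% occur spontaneously.

A useful property worth stating explicitly: the 5 × 5 window underestimates
contrast slightly because neighbouring pixels of Nyquist-sampled speckle
are correlated (static ROI-mean windowed $K$ comes out near 0.91 rather
than 1.0). The factor is a property of the optics/window geometry, not of
$\tau_c$, so it cancels in every percent-of-baseline ratio — which is why
end-to-end flow recovery is accurate to a couple of percentage points even
though the raw windowed $K$ is biased. The whole-frame contrast
(`global_contrast()`) has no such bias and is the statistic checked
against the closed-form curve.

## 3. Optoacoustic band analysis

The transducer band (11–99 MHz) is split into low (11–33 MHz, large
vessels) and high (33–99 MHz, capillaries) ranges. Because the original
processing lived in vendor software, two conventions had to be fixed here:

* **"Intensity" is mean power** (mean squared amplitude) of the
  band-limited component. An amplitude convention would be equally
  defensible; power is chosen because it makes Parseval bookkeeping exact
  and testable: for a signal confined to [11, 99] MHz the band intensities
  sum to the total mean power.
* **Band splitting is an ideal spectral mask**, not an IIR filter. DFT
  bins are assigned by their effective (folded) frequency; a bin exactly
  on the shared 33 MHz edge belongs to the low band, so interior energy is
  never counted twice.

The alteration is $A = 100\, I_t / I_0$ per band, with the pre-injection
timepoint as reference ($A = 100\%$ there by construction); a band missing
at some timepoint is reported absent, never as zero. `simulate_pa_signal()`
synthesizes each band as spectrally masked Gaussian noise scaled to an
exact RMS, so injected power ratios are recovered exactly and out-of-band
leakage is identically zero.

`depth_band_profile()` averages each band per z layer of a reconstructed
two-channel volume (tomographic reconstruction itself is out of scope) and
reports the low-band extinction depth: the depth of the first layer at
which the low-band mean falls to at most `surface_fraction` (default 0.05)
of its surface value. For energy confined above a plane this lands exactly
on the confinement boundary, within one layer otherwise.

## 4. Biodistribution and calibration

The autofluorescence correction is parsed as
$TRE_{organ} = TRE_{exp} - (TRE_{ctrl}/Area_{ctrl})\cdot Area_{exp}$:
the control organ contributes an autofluorescence *surface density* that
is rescaled to the experimental organ's imaged area. Negative corrected
values (autofluorescence estimate exceeding the measurement) are clamped
to zero and flagged, not propagated; %ID is then each organ's share of the
corrected total, which sums to 100 by construction. An experimental table
that is *exactly* per-area-scaled control autofluorescence leaves nothing
to normalize — that case raises an error rather than fabricating shares.

The digest assay inverts a linear calibration at the 785 nm emission peak.
The five replicate wells of a sample are averaged *before* inversion
(mean-of-wells, then one inversion) — with a linear curve the order is
immaterial for the estimate, but averaging first is the convention the
uncertainty bound $3\,\sigma_{noise}/\mathrm{slope}$ is stated for, and it
is what the package does everywhere. Negative inverted masses clamp to
zero with a flag; an intensity numerically at the intercept is mass zero,
not a flagged negative.

### The organ-table generator

`simulate_organ_tables()` writes each experimental organ's TRE as
`signal_total * trueID/100` plus `autofl_per_area * area`, each term
multiplied by independent log-normal noise of the given CV (fluorescence
intensities are positive and right-skewed, so multiplicative log-normal
noise with unit mean is the natural model; the CV default is 5%). The
control animal carries the autofluorescence term only. `signal_total`
defaults to five times the summed autofluorescence — a realistic ex vivo
signal-to-background for a near-infrared dye — because only
"proportional to %ID" is specified upstream; the constant was chosen once
on that reasoning and is exposed as a parameter. Control and experimental
organs share the same nominal areas; the correction still exercises the
area scaling because it divides and re-multiplies by them.

What the generator does *not* emulate: depth-dependent photon loss inside
organs (the imaging protocol itself lists it as a limitation), detector
background drift, inter-animal anatomical variation beyond the noise CV,
and any kinetic model linking timepoints — the kinetics table is purely
descriptive. Passing recovery tests therefore demonstrates correctness of
the arithmetic chain under the stated noise model, not robustness to every
artefact of real IVIS data.

## 5. Problem sizes and reproducibility

All stochastic functions take an explicit integer seed and are
bit-reproducible under it; `run_pipeline()` hashes its config into the
report and writes byte-identical outputs for identical configs. The test
and acceptance workloads use sizes chosen to make the statistical checks
sharp while staying desk-scale: 256² px, 20-frame movies for the contrast
physics (the grid $T/\tau_c \in \{0.1, 1, 10\}$ spans the regimes from
frozen to strongly averaged speckle); 128² px, 25-frame movies with a 64²
ROI for end-to-end flow recovery (baseline $\tau_c = 0.4$ ms at 10 ms
exposure puts the system at $x = 25$, where the flow index is close to
proportional to flow and a true 50% drop reads back within ±5 points);
1000 replicate organ tables for the %ID Monte-Carlo. The brute-force
contrast oracle — an explicit per-window double loop — is run on 100
random 64 × 64 frames.

## 6. Known limitations

* Single-exposure spatial-contrast LSCI only: no temporal-contrast or
  multi-exposure variants, no absolute velocimetry, no motion
  registration. The pipeline assumes the instrument mirrors the modelled
  one (10 ms exposure, 30 fps defaults).
* The speckle generator models fully developed speckle from a uniform
  circular pupil; no laser or polarizer physics, no vessel geometry, no
  capsule transport — flow changes are spatially uniform within a movie.
* Optoacoustic reconstruction and ROI drawing are upstream of the
  package; it consumes either raw A-lines or already-reconstructed
  two-channel volumes.
* %ID from imaging is a *share* of the dissected-organ total: dose still
  circulating outside the organ panel inflates every share, which is the
  known reason imaging-based %ID exceeds digest-based %ID at the earliest
  timepoints. The package reports both routes and leaves the comparison
  to the analyst.
* Group-level statistics (n = 3 animals in the emulated design) are
  descriptive; the package deliberately performs no hypothesis testing
  across dose groups.
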