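---
title: "Simulated CT reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated CT reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Filtered back projection (FBP) is the classical analytic CT
reconstruction: it is fast and exact in the noiseless limit, but its ramp
filter amplifies high-frequency photon noise, so low-dose acquisitions
come out grainy. Iterative algebraic reconstruction instead treats the
scan as a large sparse linear system and repeatedly corrects a candidate
image by the mismatch between its simulated projections and the measured
ones. Clinically, adaptive statistical iterative reconstruction (ASIR) is
reported to cut abdominal image noise roughly in half at matched or even
reduced dose relative to FBP, without shifting mean CT values.

`ctrecon` makes that comparison reproducible on simulated data: it
generates a labelled abdominal phantom, simulates a parallel-beam
acquisition with seeded photon noise, reconstructs the *same* noisy
sinogram with FBP and with the iterative algorithm, and scores both with
the objective metrics used on clinical workstations — ROI mean CT value
(HU), ROI standard deviation (the noise measure, HU), and their ratio
SNR = CT/SD.

## Forward model

The image is a square grid of linear attenuation values $\mu_k$ (1/mm),
related to Hounsfield units by $\mathrm{HU} = 1000(\mu - \mu_w)/\mu_w$
with $\mu_w = 0.02\,\mathrm{mm}^{-1}$ for water (the effective energy of
a ~120 kVp abdominal beam). A parallel-beam geometry with view angles
uniform over $[0^\circ, 180^\circ)$ and centred detector bins defines a
set of rays; ray $c$ measures the line integral

$$Y_c = \sum_k Z_{kc}\, \mu_k,$$

where $Z_{kc}$ is the exact intersection length (mm) of ray $c$ with
pixel $k$. The weights are computed by Siddon-style incremental ray
traversal (implemented in C++) and stored as a sparse matrix; row sums
equal chord lengths through the grid, which the test suite verifies
against an independent line-clipping oracle.

The scanner's actual fan/cone geometry is deliberately not modelled: the
algebraic formulation is geometry-agnostic, and parallel beam keeps the
FBP comparator standard and the oracles exact.

## Noise model and the noise index

Photon noise is simulated in the transmission domain: counts
$N_c \sim \mathrm{Poisson}(I_0 e^{-Y_c})$ with a seeded generator, then
$Y_c^{\mathrm{noisy}} = -\log(\max(N_c, 1)/I_0)$. Zero-count bins are
clamped to one count before the logarithm (the standard guard against
infinities); expected counts below 10 trigger a photon-starvation
warning.

Clinical dose control is expressed as a *noise index* (NI). The scanner
literature does not define NI algorithmically, so the package adopts the
operational clinical meaning: **NI is the target standard deviation, in
HU, of a water-equivalent background region in the FBP reconstruction.**
`calibrate_counts()` inverts this definition — it reconstructs noisy
flat-field (water cylinder) acquisitions and searches $I_0$ by bisection
on $\log I_0$ (warm-started from the $SD \propto 1/\sqrt{I_0}$ power
law, 3 seeded realisations per step, 2% stopping tolerance) until the
measured background SD matches NI. The calibration reproduces the target
within a few percent; the test suite requires 20%.

## FBP implementation

* Views are filtered in the frequency domain with the discrete
  band-limited ramp kernel ($h_0 = 1/4\tau^2$,
  $h_n = -1/(n\pi\tau)^2$ for odd $n$, 0 otherwise, $\tau$ = detector
  spacing), zero-padded to the next power of two $\ge 2\times$ the
  detector count to avoid circular-convolution wrap-around.
* The default apodization is a Hann window (the common clinical
  soft-tissue choice; `ramp` and `hamming` are available). The kernel's
  zero-frequency response is $O(1/N)$ and is left as is: forcing it to
  exactly zero shifts every filtered view by the kernel mean and biases
  reconstructed CT values several HU low, which the analytic disk oracle
  exposes immediately.
* Back projection accumulates linearly interpolated filtered values at
  each pixel's detector coordinate and scales by $\pi/n_{\mathrm{views}}$.

On a noiseless 360-view sinogram of a 60 HU disk (closed-form
projections, 256² grid) this pipeline recovers the interior to well
under 1 HU RMSE; the acceptance suite asserts the looser bounds of ±5 HU
on the central mean and 10 HU RMSE.

## The iterative algorithm

Starting from an image $R^0$, each iteration computes all estimated
projections $Y^*_c = \sum_k Z_{kc} R_k$, the residuals
$\Phi_c = Y_c - Y^*_c$, and a simultaneous per-pixel correction

$$E_k \;=\; \lambda\,
\frac{\sum_{c \ni k} Z_{kc}\,\bigl(\Phi_c / \sum_j Z_{jc}\bigr)}
     {\sum_{c \ni k} Z_{kc}},$$

then updates $R_k \leftarrow \max(R_k + E_k,\, 0)$. This is the SART
normalisation: a ray's residual is first spread along the ray in
proportion to intersection length, and each pixel averages the
contributions of all rays crossing it. The published description of the
correction step mixes its indices (the same symbol serves as geometric
weight and "relaxation parameter", and the reciprocal-weight reading is
dimensionally unstable as weights approach zero); the ray-averaged form
above is the reading consistent with its own gloss — *all rays crossing
a pixel are summed, and averaging over projection bands reduces the
error* — and is the standard, provably convergent choice. Pixels crossed
by no ray receive a zero correction.

Properties the test suite pins down:

* zero residuals are a fixed point for any relaxation, blend or
  initialisation;
* on consistent systems with $\lambda \in (0, 1]$ the residual norm
  $\|\Phi\|_2$ is non-increasing;
* on consistent full-column-rank systems the converged image matches an
  explicit pseudoinverse least-squares oracle to better than $10^{-3}$
  relative error;
* the loop contains no randomness — identical inputs give bit-identical
  images.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `relaxation` ($\lambda$) | 1.0 | step size on $E_k$, in (0, 2); the source names the parameter but no value |
| `tolerance` | $10^{-4}$ | relative $L_2$ image change that stops the loop ("iterate until the image stops moving" made quantitative) |
| `max_iterations` | 50 | iteration cap |
| `init_mode` | `"zero"` | starting image: cold start, `"fbp"`, or `"uniform"` |
| `blend_fraction` | 1.0 | final image = blend × iterative + (1 − blend) × FBP, emulating commercial "%-iterative" levels; 1 = pure iterative |
| `nonneg` | `TRUE` | clamp attenuation at 0 after each update (physical non-negativity) |

### Why the comparison pipeline cold-starts

Commercial ASIR is described as starting from the FBP image. That option
is implemented (`init_mode = "fbp"`), but it is *not* the default for
the noise comparison, for a measurable reason: the purely algebraic
update can only move the image toward agreement with the (noisy)
measured projections — it has no statistical noise model — so noise
already present in the start image simply persists in the
slowly-converging high-frequency components. At the study condition
(256², 180 views, NI 24) FBP-initialised iteration leaves organ-ROI SD
at or slightly above FBP's. A cold start recovers the smooth components
of the image first; stopping at the default tolerance/cap yields organ
CT values within a few HU of truth at roughly 40% lower SD than FBP,
which is exactly the regularisation-by-early-stopping mechanism that
makes the FBP-vs-iterative noise comparison meaningful in this
framework. Where proprietary ASIR denoises via its statistical model and
FBP blend, this package realises the same *direction* of effect through
early-stopped algebraic iteration; it does not claim to reproduce the
commercial algorithm itself.

## The phantom and what it does (not) emulate

`default_abdomen_spec()` is a four-region layered-ellipse slice on a
220 mm field of view: subcutaneous fat oval (−90 HU) forming an 18 mm
annulus around a soft-tissue body oval (40 HU), a liver ellipse (77 HU)
and a gallbladder ellipse (55 HU), on air (−1000 HU). Organ values were
chosen so noiseless ROI means land near typical portal-phase abdominal
values (liver high 70s, gallbladder mid 50s HU). Rasterisation is by
pixel-centre containment with later ellipses overwriting earlier ones
(the Shepp–Logan convention), making rendering exact, deterministic and
directly testable against analytic areas.

The phantom emulates only first-order organ statistics: uniform organs,
sharp boundaries, no texture, no anatomy beyond four regions, and a 2-D
slice rather than a volume. Passing tests therefore demonstrate the
*algorithmic* contrast between the reconstructions under controlled
noise; they say nothing about lesion conspicuity or texture fidelity in
real patients.

## ROI metrics

CT value is the ROI mean in HU; SD is the sample standard deviation
(n − 1, the scanner-console convention — the estimator is not specified
in the clinical protocol); SNR = CT/SD, reported to 2 decimals with full
precision retained internally. The clinical practice of measuring each
ROI three times and averaging is modelled as seeded integer-pixel jitter
of the ROI mask (`measure_roi_repeated()`, default 3 repeats, ±1 px):
manual re-measurement has no algorithmic definition, and jitter is its
smallest reproducible analogue.

The comparison pipeline measures ROIs on region masks eroded by a 4 mm
margin (`roi_margin_mm`). This mirrors how a radiologist places an ROI
well inside an organ: boundary pixels carry partial-volume and Gibbs
edge effects that are structural, not noise, and without the margin they
dominate the SD of thin regions (most visibly the fat annulus) for
reasons unrelated to the reconstruction's noise behaviour. Whether the
clinical "SD value" refers to the organ ROI or the fat background is
ambiguous in the source protocol, so the default comparison reports
both, labelled distinctly.

## Numerical choices and degenerate inputs

* Pixel-centre containment (no anti-aliasing) decides phantom
  membership; ties at an ellipse boundary use the closed interior.
* Ray/pixel indexing is fixed package-wide: ray
  $c = (\text{angle} - 1) \cdot n_{\mathrm{det}} + \text{detector}$,
  pixels in column-major order of the image matrix, origin at the grid
  centre, x right, y up, row 1 at the top.
* Rays missing the grid have empty system-matrix rows; their residuals
  are ignored by the correction (0/0 guarded to 0).
* Zero-count detector bins clamp to 1 count before the log.
* Non-finite values inside the iterative loop abort with an error naming
  the iteration.
* The relative image-change denominator is guarded by machine epsilon,
  so a cold start's first iteration (change from an all-zero image)
  never spuriously triggers the stopping rule.

## Problem sizes

The package's simulated study condition is a 256² grid with 180 views
(detector pitch matched to the pixel pitch, detector array spanning the
grid diagonal), where a full paired comparison — calibration included —
runs in well under a minute. Unit tests use 32–128² grids; the analytic
disk oracle for FBP uses 360 views at 256². The 512² matrix of the
clinical acquisition is supported (`size = 512`) but not the default, as
the system matrix grows with size² × views.

## Known limitations

* Parallel-beam only: no fan/helical geometry, scatter, beam hardening,
  detector cross-talk or tube-current modulation.
* The noise index calibration is a stated operational stand-in; the
  source protocol gives kV/mAs but no dose-to-noise physics, so tube
  settings are carried as metadata only.
* The iterative method is plain relaxed SART with optional FBP blending,
  not the proprietary statistical ASIR model or model-based IR.
* DICOM support is read-only and minimal (uncompressed single-frame
  little-endian CT slices); TIFF export quantizes to whole HU with a
  +1024 offset.
* Subjective (observer-score) image quality and any clinical statistics
  are out of scope.
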