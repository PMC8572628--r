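# ctrecon

Simulated parallel-beam CT reconstruction in R: a labelled abdominal
phantom generator, exact Siddon ray tracing, a seeded noise-index-driven
photon noise model, filtered back projection (FBP), a SART-style
iterative reconstructor, and workstation-style ROI metrics
(CT value, SD, SNR = CT/SD) — everything needed to run a paired
FBP-versus-iterative image-quality comparison end to end on synthetic
data.

## Why

FBP amplifies photon noise through its ramp filter; iterative algebraic
reconstruction suppresses it by correcting an image estimate against the
measured projections and stopping before the noise is fitted. Clinical
studies report the pattern: unchanged mean CT values, roughly halved
noise SD, and correspondingly higher SNR for iterative reconstruction of
the liver and gallbladder. Patient images behind such studies are not
public, so `ctrecon` provides the controlled stand-in: a phantom with
known organ values, a calibrated noise model, and both reconstructions
run on the *same* noisy sinogram.

## The algorithms

Forward model: ray `c` measures `Y_c = Σ_k Z_kc μ_k`, with `Z_kc` the
exact ray/pixel intersection length (sparse, built by Siddon traversal
in C++). Noise: transmission counts `N_c ~ Poisson(I0 · exp(−Y_c))`,
with `I0` calibrated so the FBP water-background SD equals a clinical
noise index (NI).

FBP: band-limited ramp kernel, Hann apodization by default,
zero-padded FFT filtering, linear-interpolation back projection.

Iterative (SART-type) update, from image `R⁰`, residuals
`Φ_c = Y_c − Σ_k Z_kc R_k`:

    E_k = λ · [ Σ_{c∋k} Z_kc · (Φ_c / Σ_j Z_jc) ] / [ Σ_{c∋k} Z_kc ]
    R_k ← max(R_k + E_k, 0)

iterated until the relative L2 image change drops below `1e-4` or 50
iterations, with an optional final blend
`blend · iterative + (1 − blend) · FBP`. Metrics: ROI mean (CT value,
HU), sample SD (noise, HU), SNR = CT/SD, with triplicate jittered
measurement emulating clinical re-measurement.

## Worked example

```r
library(ctrecon)
cfg <- run_config(noise = list(noise_index = 24, seed = 1))
res <- run_comparison(cfg)
print(res)
```

```
[ctrecon] phantom: 4 region(s), FOV 220 mm, grid 256^2
[ctrecon] projecting: 180 views x 365 detectors
[ctrecon] calibrating incident counts to noise index 24
[ctrecon] calibrated incident counts: 5.466e+04 photons/bin
[ctrecon] reconstructing: FBP (hann window)
[ctrecon] reconstructing: iterative (zero init, lambda 1, <= 50 iterations)
[ctrecon] iterative reconstruction: 50 iteration(s), cap reached
<comparison_result> config 064a0ad0, seed 1
 method         roi  ct_hu sd_hu   snr
    fbp       liver  77.87 28.80  2.70
    fbp gallbladder  55.51 29.75  1.87
    fbp         fat -89.89 20.80 -4.32
   asir       liver  77.54 17.82  4.35
   asir gallbladder  54.43 18.28  2.98
   asir         fat -90.00 17.56 -5.13
```

Reading the table: both methods recover the phantom's organ CT values
(liver 77 HU, gallbladder 55 HU, fat −90 HU) to within a couple of HU —
mean density is preserved. The iterative rows show organ noise SD
roughly 40% below FBP's at the same dose, and SNR correspondingly
higher: the direction and rough magnitude of the clinical
FBP-vs-iterative comparison, now on data whose ground truth is known.
Setting `output_dir` additionally writes the comparison CSV, both
reconstructions, the noisy sinogram, a convergence trace and a full
parameter log, each stamped with the configuration hash and seed.

A command-line front end over the same functions ships in
`inst/cli/ctrecon.R` with subcommands `phantom-render`, `project`,
`reconstruct --method {fbp,asir}`, `measure` and `compare`; run
configurations are plain YAML (see `?load_config`).

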